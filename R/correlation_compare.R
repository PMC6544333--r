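#' Pearson correlation network over taxon pairs
#'
#' Correlates every unordered taxon pair on the same processed
#' (standardized, differenced) series the Granger model consumes, so the
#' comparison is like-for-like; `substrate = "undifferenced"` instead
#' correlates the standardized series before differencing is emulated by
#' cumulative reconstruction — callers wanting that should pass the
#' matching series. Two-sided t-tests at `alpha`, unadjusted.
#'
#' @param series a `processed_series` (or any list with `taxa` and a
#'   taxa x time `values` matrix with >= 3 columns).
#' @param alpha significance level.
#' @return data.frame `taxon_a`, `taxon_b`, `r`, `p`, `significant`,
#'   `sign` (+1/-1/0 where 0 means not significant).
#' @export
pearson_network <- function(series, alpha = 0.05) {
  v <- series$values
  if (ncol(v) < 3) stop("need at least 3 time points")
  sds <- apply(v, 1, sd)
  if (any(sds == 0))
    stop("constant series for taxon '", series$taxa[which(sds == 0)[1]], "'")
  n <- nrow(v)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  r <- cor(t(v))[idx]
  df <- ncol(v) - 2
  tval <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), df)
  sig <- p < alpha
  data.frame(taxon_a = series$taxa[idx[, 1]], taxon_b = series$taxa[idx[, 2]],
             r = r, p = p, significant = sig,
             sign = ifelse(sig, ifelse(r > 0, 1L, -1L), 0L),
             stringsAsFactors = FALSE)
}

#' 3x3 sign contingency table: Pearson versus Granger
#'
#' Each eligible ordered interspecific pair contributes one count, indexed
#' by its Pearson class (positive / negative / insignificant, shared by
#' both orders of the pair) and its Granger class in the requested
#' timescale window (`none` maps to insignificant). Pairs whose window
#' call is `conflicting` are excluded.
#'
#' @param pearson result of [pearson_network()].
#' @param calls result of [classify_timescales()] on the site's strong (or
#'   all) edges.
#' @param timescale `"short"` or `"long"`.
#' @param site optional label.
#' @return an object of class `sign_contingency`: list with `counts` (3x3
#'   integer matrix), `timescale`, `site`, and the chi-square test fields
#'   filled by [chi_square_independence()].
#' @export
sign_contingency <- function(pearson, calls, timescale = c("short", "long"),
                             site = NULL) {
  timescale <- match.arg(timescale)
  lev <- c("positive", "negative", "insignificant")
  counts <- matrix(0L, 3, 3, dimnames = list(pearson = lev, granger = lev))
  taxa <- unique(c(pearson$taxon_a, pearson$taxon_b))
  pkey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  psign <- setNames(pearson$sign, pkey(pearson$taxon_a, pearson$taxon_b))
  sign_col <- paste0(timescale, "_sign")
  gkey <- paste(calls$cause, calls$effect, sep = "\r")
  for (a in taxa) for (b in taxa) {
    if (a == b) next
    g <- calls[[sign_col]][match(paste(a, b, sep = "\r"), gkey)]
    if (is.na(g)) g <- "none"
    if (g == "conflicting") next
    gcls <- if (g == "none") "insignificant" else g
    ps <- psign[pkey(a, b)]
    pcls <- if (is.na(ps) || ps == 0) "insignificant"
            else if (ps > 0) "positive" else "negative"
    counts[pcls, gcls] <- counts[pcls, gcls] + 1L
  }
  out <- structure(list(site = site, timescale = timescale, counts = counts),
                   class = "sign_contingency")
  test <- chi_square_independence(counts)
  out[names(test)] <- test
  out
}

#' Classical chi-square test of independence
#'
#' Pearson statistic `sum((O - E)^2 / E)` with expected counts from the
#' margins; degrees of freedom `(r-1)(c-1)` (4 for the 3x3 sign tables).
#' Cells whose expected count is zero (empty row or column) contribute
#' nothing. Warns when any expected count is below 5.
#'
#' @param table a `sign_contingency` or a plain count matrix.
#' @return list with `statistic`, `dof`, `p_value`, `expected`.
#' @export
chi_square_independence <- function(table) {
  counts <- if (inherits(table, "sign_contingency")) table$counts else table
  counts <- as.matrix(counts)
  N <- sum(counts)
  if (N <= 0) stop("contingency table has zero grand total")
  expected <- outer(rowSums(counts), colSums(counts)) / N
  ok <- expected > 0
  stat <- sum((counts[ok] - expected[ok])^2 / expected[ok])
  dof <- (nrow(counts) - 1) * (ncol(counts) - 1)
  if (any(expected[ok] < 5))
    warning("expected count below 5; chi-square approximation is rough")
  list(statistic = stat, dof = dof,
       p_value = pchisq(stat, dof, lower.tail = FALSE), expected = expected)
}

#' @export
print.sign_contingency <- function(x, ...) {
  cat("sign_contingency (", x$timescale, " timescale",
      if (!is.null(x$site)) paste0(", site '", x$site, "'"), "):\n", sep = "")
  print(x$counts)
  cat("chi-square =", signif(x$statistic, 5), "on", x$dof,
      "df, p =", signif(x$p_value, 4), "\n")
  invisible(x)
}

#' Paired causality-versus-correlation records
#'
#' One record per ordered interspecific pair that is significant under
#' Pearson correlation and carries at least one retained Granger
#' coefficient: the correlation alongside the pair's extreme positive and
#' negative coefficients. The summary rank correlation (Spearman) pools,
#' per record, the correlation against each available extreme.
#'
#' @param pearson result of [pearson_network()].
#' @param extremes result of [pair_extremes()].
#' @return list with `records` (data.frame `cause`, `effect`, `r`,
#'   `max_positive`, `min_negative`) and `rank_correlation`.
#' @export
causality_vs_correlation_scatter <- function(pearson, extremes) {
  pkey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  sig <- pearson[pearson$significant, , drop = FALSE]
  skey <- pkey(sig$taxon_a, sig$taxon_b)
  ex <- extremes[!extremes$intraspecific, , drop = FALSE]
  m <- match(pkey(ex$cause, ex$effect), skey)
  keep <- !is.na(m)
  rec <- data.frame(cause = ex$cause[keep], effect = ex$effect[keep],
                    r = sig$r[m[keep]],
                    max_positive = ex$max_positive[keep],
                    min_negative = ex$min_negative[keep],
                    stringsAsFactors = FALSE)
  gc <- c(rec$max_positive, rec$min_negative)
  rr <- c(rec$r, rec$r)
  ok <- !is.na(gc)
  rho <- if (sum(ok) >= 3) cor(rr[ok], gc[ok], method = "spearman")
         else NA_real_
  list(records = rec, rank_correlation = rho)
}
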