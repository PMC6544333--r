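#' Materialize causal edges from a coefficient tensor
#'
#' One edge per nonzero tensor entry: a (cause, effect, lag) triple with
#' its signed coefficient. Intraspecific edges are self-effects
#' (cause == effect). Deterministic ordering by (effect, cause, lag).
#'
#' @param tensor a `coef_tensor` from [fit_all_responses()].
#' @return data.frame with columns `cause`, `effect`, `lag`, `coefficient`,
#'   `sign` (+1/-1), `intraspecific`, `strong` (initially `FALSE`).
#' @export
extract_edges <- function(tensor) {
  idx <- which(tensor$B != 0, arr.ind = TRUE)
  taxa <- tensor$taxa
  df <- data.frame(cause = taxa[idx[, 2]], effect = taxa[idx[, 1]],
                   lag = as.integer(idx[, 3]),
                   coefficient = tensor$B[idx],
                   stringsAsFactors = FALSE)
  df$sign <- ifelse(df$coefficient > 0, 1L, -1L)
  df$intraspecific <- df$cause == df$effect
  df$strong <- rep(FALSE, nrow(df))
  df <- df[order(match(df$effect, taxa), match(df$cause, taxa), df$lag), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Flag strong coefficients (top percentile within each sign)
#'
#' Positive edges at or above the (100 - percentile)-th percentile of the
#' positive coefficients, and negative edges at or below the percentile-th
#' percentile of the negative coefficients, are flagged strong. Percentiles
#' use linear interpolation between order statistics; ties with the cut are
#' kept. When a sign class is empty its cut is undefined (`NA`) and no edge
#' of that sign is flagged.
#'
#' @param edges edge data.frame from [extract_edges()].
#' @param percentile percent defining the tail, default 5.
#' @param site optional site label stored on the thresholds.
#' @return list with `edges` (strong flags filled) and `thresholds`
#'   (`positive_cut`, `negative_cut`, `site`, `n_strong`).
#' @export
mark_strong <- function(edges, percentile = 5, site = NULL) {
  pos <- edges$coefficient[edges$coefficient > 0]
  neg <- edges$coefficient[edges$coefficient < 0]
  pcut <- if (length(pos)) unname(quantile(pos, 1 - percentile / 100)) else NA_real_
  ncut <- if (length(neg)) unname(quantile(neg, percentile / 100)) else NA_real_
  edges$strong <- apply_strong_cut(edges$coefficient, pcut, ncut)
  thr <- structure(list(site = site, positive_cut = pcut, negative_cut = ncut,
                        n_strong = sum(edges$strong)),
                   class = "strong_thresholds")
  list(edges = edges, thresholds = thr)
}

# strong flags for arbitrary coefficients under fixed cuts (used verbatim
# by the null run so actual-data thresholds carry over)
apply_strong_cut <- function(coefficient, positive_cut, negative_cut) {
  s <- rep(FALSE, length(coefficient))
  if (!is.na(positive_cut))
    s <- s | (coefficient > 0 & coefficient >= positive_cut)
  if (!is.na(negative_cut))
    s <- s | (coefficient < 0 & coefficient <= negative_cut)
  s
}

#' Qualitative short/long timescale call per ordered taxon pair
#'
#' A pair's sign within a lag window is `"positive"`/`"negative"` when all
#' its in-window edges agree, `"conflicting"` when signs mix (such pairs
#' are excluded from downstream sign comparisons), and `"none"` without an
#' in-window edge. Lags outside both windows are ignored.
#'
#' @param edges edge data.frame.
#' @param short_range,long_range inclusive lag windows, disjoint.
#' @return data.frame `cause`, `effect`, `intraspecific`, `short_sign`,
#'   `long_sign`, one row per ordered pair appearing in `edges`.
#' @export
classify_timescales <- function(edges, short_range = c(1L, 5L),
                                long_range = c(15L, 20L)) {
  if (short_range[2] >= long_range[1] && long_range[2] >= short_range[1])
    stop("timescale windows must be disjoint")
  window_sign <- function(signs) {
    if (!length(signs)) return("none")
    if (all(signs > 0)) return("positive")
    if (all(signs < 0)) return("negative")
    "conflicting"
  }
  key <- paste(edges$cause, edges$effect, sep = "\r")
  pairs <- !duplicated(key)
  out <- data.frame(cause = edges$cause[pairs], effect = edges$effect[pairs],
                    intraspecific = edges$intraspecific[pairs],
                    stringsAsFactors = FALSE)
  out <- out[order(out$effect, out$cause), , drop = FALSE]
  okey <- paste(out$cause, out$effect, sep = "\r")
  out$short_sign <- out$long_sign <- NA_character_
  for (i in seq_len(nrow(out))) {
    e <- edges[key == okey[i], ]
    out$short_sign[i] <- window_sign(
      e$sign[e$lag >= short_range[1] & e$lag <= short_range[2]])
    out$long_sign[i] <- window_sign(
      e$sign[e$lag >= long_range[1] & e$lag <= long_range[2]])
  }
  rownames(out) <- NULL
  out
}

#' Extreme coefficients per ordered taxon pair
#'
#' For every ordered pair, the largest positive and smallest negative
#' coefficient across all its lags (`NA` when a sign is absent).
#'
#' @param edges edge data.frame.
#' @return data.frame `cause`, `effect`, `intraspecific`, `max_positive`,
#'   `min_negative`.
#' @export
pair_extremes <- function(edges) {
  key <- paste(edges$cause, edges$effect, sep = "\r")
  pairs <- !duplicated(key)
  out <- data.frame(cause = edges$cause[pairs], effect = edges$effect[pairs],
                    intraspecific = edges$intraspecific[pairs],
                    stringsAsFactors = FALSE)
  okey <- paste(out$cause, out$effect, sep = "\r")
  out$max_positive <- out$min_negative <- NA_real_
  for (i in seq_len(nrow(out))) {
    co <- edges$coefficient[key == okey[i]]
    if (any(co > 0)) out$max_positive[i] <- max(co[co > 0])
    if (any(co < 0)) out$min_negative[i] <- min(co[co < 0])
  }
  rownames(out) <- NULL
  out
}

#' Per-pair coefficient count summary
#'
#' For each ordered (predictor, effect) pair with at least one retained
#' coefficient, counts the distinct-lag coefficients; returns the count
#' histogram split interspecific/intraspecific, the share of pairs in each
#' class, and the fraction of effect taxa with at least one interspecific
#' predictor.
#'
#' @param edges edge data.frame.
#' @param scope `"all"` retained coefficients or only `"strong"` ones.
#' @return list with `pair_counts` (data.frame `cause`, `effect`,
#'   `intraspecific`, `n_coefficients`), `histogram` (count frequency per
#'   class), `class_fractions`, `frac_effects_with_interspecific_predictor`.
#' @export
coefficient_count_summary <- function(edges, scope = c("all", "strong")) {
  scope <- match.arg(scope)
  if (scope == "strong") edges <- edges[edges$strong, , drop = FALSE]
  key <- paste(edges$cause, edges$effect, sep = "\r")
  tab <- table(key)
  pairs <- !duplicated(key)
  pc <- data.frame(cause = edges$cause[pairs], effect = edges$effect[pairs],
                   intraspecific = edges$intraspecific[pairs],
                   stringsAsFactors = FALSE)
  pc$n_coefficients <- as.integer(tab[paste(pc$cause, pc$effect, sep = "\r")])
  pc <- pc[order(pc$effect, pc$cause), , drop = FALSE]
  rownames(pc) <- NULL
  hist <- table(class = ifelse(pc$intraspecific, "intraspecific",
                               "interspecific"),
                n_coefficients = pc$n_coefficients)
  effs <- unique(edges$effect)
  with_inter <- unique(edges$effect[!edges$intraspecific])
  list(pair_counts = pc, histogram = hist,
       class_fractions = c(
         interspecific = if (nrow(pc)) mean(!pc$intraspecific) else NA_real_,
         intraspecific = if (nrow(pc)) mean(pc$intraspecific) else NA_real_),
       frac_effects_with_interspecific_predictor =
         if (length(effs)) length(with_inter) / length(effs) else NA_real_)
}

#' Sign-by-lag spectrum of coefficients
#'
#' Counts positive and negative coefficients at every lag 1..L, separately
#' for interspecific and intraspecific edges; spectrum totals equal the
#' number of in-scope edges.
#'
#' @param edges edge data.frame.
#' @param L maximum lag of the table (defaults to the largest lag present).
#' @param scope `"strong"` (default) or `"all"`.
#' @return list with `spectrum` (data.frame `lag`, `class`, `positive`,
#'   `negative`) and `totals` (positive/negative counts per class).
#' @export
lag_sign_spectrum <- function(edges, L = max(edges$lag, 1L),
                              scope = c("strong", "all")) {
  scope <- match.arg(scope)
  if (scope == "strong") edges <- edges[edges$strong, , drop = FALSE]
  cls <- c("interspecific", "intraspecific")
  spec <- expand.grid(lag = seq_len(L), class = cls,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  spec$positive <- spec$negative <- 0L
  for (i in seq_len(nrow(spec))) {
    m <- edges$lag == spec$lag[i] &
      (edges$intraspecific == (spec$class[i] == "intraspecific"))
    spec$positive[i] <- sum(m & edges$sign > 0)
    spec$negative[i] <- sum(m & edges$sign < 0)
  }
  totals <- stats::aggregate(cbind(positive, negative) ~ class, spec, sum)
  list(spectrum = spec, totals = totals)
}

#' Per-genus cause/effect counts and mean lags
#'
#' For every genus participating in at least one in-scope edge: counts of
#' positive and negative interspecific edges where the genus is the cause
#' and where it is the effect, plus the mean lag of its interspecific
#' edges (as cause, switchable) and of its intraspecific self-edges.
#'
#' @param edges edge data.frame.
#' @param scope `"strong"` (default) or `"all"`.
#' @param lag_role compute the interspecific mean lag over edges where the
#'   genus is the `"cause"` (default) or the `"effect"`.
#' @return data.frame, one row per participating genus.
#' @export
genus_summary <- function(edges, scope = c("strong", "all"),
                          lag_role = c("cause", "effect")) {
  scope <- match.arg(scope)
  lag_role <- match.arg(lag_role)
  if (scope == "strong") edges <- edges[edges$strong, , drop = FALSE]
  genera <- sort(unique(c(edges$cause, edges$effect)))
  inter <- edges[!edges$intraspecific, , drop = FALSE]
  intra <- edges[edges$intraspecific, , drop = FALSE]
  out <- data.frame(genus = genera,
                    cause_positive = 0L, cause_negative = 0L,
                    effect_positive = 0L, effect_negative = 0L,
                    mean_lag_interspecific = NA_real_,
                    mean_lag_intraspecific = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(genera)) {
    g <- genera[i]
    out$cause_positive[i] <- sum(inter$cause == g & inter$sign > 0)
    out$cause_negative[i] <- sum(inter$cause == g & inter$sign < 0)
    out$effect_positive[i] <- sum(inter$effect == g & inter$sign > 0)
    out$effect_negative[i] <- sum(inter$effect == g & inter$sign < 0)
    il <- inter$lag[inter[[lag_role]] == g]
    out$mean_lag_interspecific[i] <- if (length(il)) mean(il) else NA_real_
    sl <- intra$lag[intra$cause == g]
    out$mean_lag_intraspecific[i] <- if (length(sl)) mean(sl) else NA_real_
  }
  out
}
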