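#' Reshuffle a processed series to destroy temporal structure
#'
#' Each taxon's series is independently permuted over time (default),
#' preserving the per-taxon value multiset — and hence mean and variance —
#' exactly, while removing autocorrelation and cross-lag structure. The
#' `"columns"` mode instead applies one shared permutation of time points,
#' preserving same-day cross-correlations.
#'
#' @param series a `processed_series`.
#' @param seed integer seed.
#' @param mode `"per_taxon"` (default) or `"columns"`.
#' @return a reshuffled `processed_series` (provenance records the shuffle).
#' @export
reshuffle_table <- function(series, seed = 1L,
                            mode = c("per_taxon", "columns")) {
  mode <- match.arg(mode)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  v <- series$values
  if (mode == "columns") {
    v <- v[, sample.int(ncol(v)), drop = FALSE]
  } else {
    for (i in seq_len(nrow(v))) v[i, ] <- v[i, sample.int(ncol(v))]
  }
  out <- series
  out$values <- v
  out$provenance <- c(series$provenance, paste0("reshuffle_", mode))
  out
}

#' Fit the model on reshuffled data and compare strong-edge yields
#'
#' The full per-genus lasso fit is repeated on a reshuffled copy of the
#' series; strong flags on the null edges use the ACTUAL data's
#' sign-specific cuts, not cuts recomputed from the null fit. The report
#' compares strong-pair counts and lists ordered pairs strong in both runs
#' (candidates for removal by [overlap_filter()]).
#'
#' @param series the actual `processed_series` of the site.
#' @param config a [run_config()]; the reshuffle seed derives from its
#'   master seed.
#' @param actual result of [mark_strong()] on the actual-data edges of the
#'   same site (supplies thresholds, strong count and strong pairs).
#' @return an object of class `null_report`: list with `site`,
#'   `n_strong_actual`, `n_strong_null`, `null_fraction` (`NA` when the
#'   actual count is 0), `overlapping_pairs`, `null_edges`, `seed`.
#' @export
null_run <- function(series, config = run_config(), actual) {
  if (missing(actual) || is.null(actual$thresholds))
    stop("actual-data strong thresholds are required")
  seed <- derive_seed(config, "reshuffle")
  shuf <- reshuffle_table(series, seed = seed)
  tensor <- fit_all_responses(shuf, config)
  nedges <- extract_edges(tensor)
  thr <- actual$thresholds
  nedges$strong <- apply_strong_cut(nedges$coefficient, thr$positive_cut,
                                    thr$negative_cut)
  a_strong <- actual$edges[actual$edges$strong, , drop = FALSE]
  n_strong <- nedges[nedges$strong, , drop = FALSE]
  a_pairs <- unique(paste(a_strong$cause, a_strong$effect, sep = "\r"))
  n_pairs <- unique(paste(n_strong$cause, n_strong$effect, sep = "\r"))
  overlap <- intersect(a_pairs, n_pairs)
  ov <- if (length(overlap)) {
    parts <- strsplit(overlap, "\r", fixed = TRUE)
    data.frame(cause = vapply(parts, `[`, "", 1),
               effect = vapply(parts, `[`, "", 2),
               stringsAsFactors = FALSE)
  } else data.frame(cause = character(), effect = character(),
                    stringsAsFactors = FALSE)
  structure(list(site = series$site,
                 n_strong_actual = nrow(a_strong),
                 n_strong_null = nrow(n_strong),
                 null_fraction = if (nrow(a_strong) > 0)
                   nrow(n_strong) / nrow(a_strong) else NA_real_,
                 overlapping_pairs = ov, null_edges = nedges, seed = seed),
            class = "null_report")
}

#' @export
print.null_report <- function(x, ...) {
  cat("null_report: site '", x$site, "': ", x$n_strong_null,
      " strong null edges vs ", x$n_strong_actual, " actual (fraction ",
      if (is.na(x$null_fraction)) "undefined"
      else round(x$null_fraction, 3),
      "); ", nrow(x$overlapping_pairs), " overlapping pair(s)\n", sep = "")
  invisible(x)
}

#' Remove taxa-pairs that are strong in both the actual and null runs
#'
#' Removal is at the ordered-pair level: every actual strong edge whose
#' (cause, effect) pair is strong in the null run is dropped, at all lags.
#'
#' @param actual_strong actual strong-edge data.frame.
#' @param null_strong null strong-edge data.frame.
#' @return `actual_strong` with overlapping pairs removed.
#' @export
overlap_filter <- function(actual_strong, null_strong) {
  npairs <- unique(paste(null_strong$cause, null_strong$effect, sep = "\r"))
  keep <- !(paste(actual_strong$cause, actual_strong$effect,
                  sep = "\r") %in% npairs)
  out <- actual_strong[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
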