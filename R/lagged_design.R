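#' Build the lagged regression design for one response genus
#'
#' The response vector holds the processed series of `response` at times
#' L+1 .. T'; the predictor matrix has one column per (genus, lag) pair,
#' ordered by taxon order then ascending lag, so that row r, column (g, k)
#' holds genus g at time r + L - k. With n taxa this gives n x L columns
#' (460 for a 23-genus site at L = 20, 1040 for 52 genera).
#'
#' @param series a `processed_series` from [preprocess()].
#' @param response genus name of the modelled (endogenous) series.
#' @param L maximum lag in days.
#' @return an object of class `lagged_design`: list with `response`, `y`,
#'   `X`, and `labels` (data.frame of `taxon`, `lag` per column).
#' @export
build_lagged_design <- function(series, response, L) {
  v <- series$values
  Tp <- ncol(v)
  n <- nrow(v)
  L <- as.integer(L)
  if (L >= Tp) stop("L (", L, ") must be smaller than series length (", Tp, ")")
  ri <- match(response, series$taxa)
  if (is.na(ri)) stop("unknown response taxon: ", response)
  nr <- Tp - L
  y <- v[ri, (L + 1):Tp]
  X <- matrix(0, nr, n * L)
  labels <- data.frame(taxon = rep(series$taxa, each = L),
                       lag = rep(seq_len(L), n),
                       stringsAsFactors = FALSE)
  for (g in seq_len(n)) for (k in seq_len(L))
    X[, (g - 1L) * L + k] <- v[g, (L + 1 - k):(Tp - k)]
  colnames(X) <- paste0(labels$taxon, ".L", labels$lag)
  structure(list(response = response, y = as.numeric(y), X = X,
                 labels = labels, L = L, taxa = series$taxa),
            class = "lagged_design")
}

#' Hypothesis counts and expected false positives
#'
#' Pairwise Granger testing examines every unordered taxon pair
#' (n(n-1)/2 hypotheses: 253 at n = 23, 1326 at n = 52), whereas the
#' conditional (multivariate) formulation fits one model per taxon
#' (n hypotheses). Expected false positives are `count * alpha` rounded to
#' the nearest integer.
#'
#' @param n_taxa number of genera (>= 2).
#' @param alpha per-test type-I error rate.
#' @param mode `"pairwise"` or `"conditional"`.
#' @return list with `hypotheses` and `expected_false_positives`.
#' @export
hypothesis_budget <- function(n_taxa, alpha = 0.05,
                              mode = c("pairwise", "conditional")) {
  mode <- match.arg(mode)
  stopifnot(n_taxa >= 2, alpha > 0, alpha < 1)
  count <- if (mode == "pairwise") n_taxa * (n_taxa - 1) / 2 else n_taxa
  list(hypotheses = as.integer(count),
       expected_false_positives = as.integer(floor(count * alpha + 0.5)))
}
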