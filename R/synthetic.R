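#' Specification of a synthetic microbial community
#'
#' Parameters of the ground-truth generator: a latent log-scale VAR with
#' strong negative lag-1 self-regulation on every taxon plus a sparse set
#' of signed interspecific lagged interactions, observed through
#' compositional closure, multinomial sequencing at fixed depth, and a
#' detection floor that records rare observations as zeros. Defaults:
#' 10 taxa over 350 days, 12 interspecific edges with magnitudes 0.2-0.6,
#' self-coefficients -0.4, depth 1e5 and no detection floor (100%
#' prevalence).
#'
#' @param n_taxa number of genera.
#' @param T number of observed days.
#' @param L_true maximum true interaction lag.
#' @param self_coefficient lag-1 self-effect (negative).
#' @param n_inter_edges number of interspecific edges.
#' @param inter_magnitude length-2 range of |coefficient| for
#'   interspecific edges.
#' @param positive_fraction probability an interspecific edge is positive.
#' @param innovation_sd standard deviation of the latent Gaussian
#'   innovations.
#' @param sequencing_depth reads drawn per day.
#' @param detection_floor relative abundance below which a count is
#'   recorded as zero.
#' @param seed integer seed.
#' @return an object of class `community_spec`.
#' @export
community_spec <- function(n_taxa = 10L, T = 350L, L_true = 20L,
                           self_coefficient = -0.4, n_inter_edges = 12L,
                           inter_magnitude = c(0.2, 0.6),
                           positive_fraction = 0.6, innovation_sd = 0.1,
                           sequencing_depth = 1e5, detection_floor = 0,
                           seed = 1L) {
  stopifnot(n_taxa >= 1, T >= 2, L_true >= 1, self_coefficient < 0,
            n_inter_edges <= n_taxa * (n_taxa - 1) * L_true,
            positive_fraction >= 0, positive_fraction <= 1,
            innovation_sd > 0, sequencing_depth > 0, detection_floor >= 0)
  structure(list(n_taxa = as.integer(n_taxa), T = as.integer(T),
                 L_true = as.integer(L_true),
                 self_coefficient = self_coefficient,
                 n_inter_edges = as.integer(n_inter_edges),
                 inter_magnitude = inter_magnitude,
                 positive_fraction = positive_fraction,
                 innovation_sd = innovation_sd,
                 sequencing_depth = sequencing_depth,
                 detection_floor = detection_floor,
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' Spectral radius of the VAR companion matrix
#'
#' Stacks the lag coefficient matrices into the nL x nL companion form and
#' returns the largest eigenvalue modulus; a radius below 1 certifies the
#' latent process is stationary.
#'
#' @param B n x n x L coefficient array (`B[effect, cause, lag]`).
#' @return non-negative scalar.
#' @export
stability_check <- function(B) {
  n <- dim(B)[1]
  L <- dim(B)[3]
  C <- matrix(0, n * L, n * L)
  for (k in seq_len(L)) C[1:n, (k - 1) * n + 1:n] <- B[, , k]
  if (L > 1)
    C[(n + 1):(n * L), 1:(n * (L - 1))] <- diag(n * (L - 1))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Simulate a synthetic community with known causal structure
#'
#' Draws a random sparse edge set per the spec (interspecific lags uniform
#' on 1..L_true, magnitudes uniform in range, signs Bernoulli), verifies
#' stationarity via [stability_check()] — rescaling interspecific
#' magnitudes by `0.95 / radius` when the radius reaches 1 — then
#' simulates the latent log-abundance VAR with Gaussian innovations after
#' a 200-step burn-in. Taxa receive fixed log-spaced baseline abundances
#' spanning one decade; latent states are exponentiated, closed to
#' relative abundances, sampled as multinomial counts at the sequencing
#' depth, and counts whose relative abundance falls below the detection
#' floor are zeroed.
#'
#' @param spec a [community_spec()].
#' @return list with `table` (a [genus_table()] of counts) and `truth`
#'   (list with `edges` data.frame incl. self-edges, the latent matrix
#'   `latent`, and the realized coefficient array `B`).
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  n <- spec$n_taxa
  L <- spec$L_true
  taxa <- sprintf("g%02d", seq_len(n))
  B <- array(0, dim = c(n, n, L))
  for (i in seq_len(n)) B[i, i, 1] <- spec$self_coefficient
  # sample distinct ordered interspecific pairs, then a lag for each
  pairs <- expand.grid(cause = seq_len(n), effect = seq_len(n))
  pairs <- pairs[pairs$cause != pairs$effect, , drop = FALSE]
  pick <- pairs[sample.int(nrow(pairs), spec$n_inter_edges), , drop = FALSE]
  pick$lag <- sample.int(L, spec$n_inter_edges, replace = TRUE)
  mag <- runif(spec$n_inter_edges, spec$inter_magnitude[1],
               spec$inter_magnitude[2])
  sgn <- ifelse(runif(spec$n_inter_edges) < spec$positive_fraction, 1, -1)
  pick$coefficient <- mag * sgn
  for (r in seq_len(nrow(pick)))
    B[pick$effect[r], pick$cause[r], pick$lag[r]] <- pick$coefficient[r]
  rad <- stability_check(B)
  rescaled <- FALSE
  for (tries in 1:5) {
    if (rad < 1) break
    scale <- 0.95 / rad
    for (r in seq_len(nrow(pick))) {
      pick$coefficient[r] <- pick$coefficient[r] * scale
      B[pick$effect[r], pick$cause[r], pick$lag[r]] <- pick$coefficient[r]
    }
    rad <- stability_check(B)
    rescaled <- TRUE
  }
  if (rad >= 1)
    stop("could not stabilize the community spec (spectral radius ",
         round(rad, 3), ")")
  if (rescaled)
    warning("interspecific magnitudes rescaled for stationarity ",
            "(spectral radius now ", round(rad, 3), ")")
  # baseline mean log-abundances: one decade, evenly log-spaced
  mu <- log(10^seq(0, 1, length.out = n))
  burn <- 200L
  Ttot <- spec$T + burn
  z <- matrix(0, n, Ttot)
  z[, 1:L] <- mu + rnorm(n * L, sd = spec$innovation_sd)
  for (t in (L + 1):Ttot) {
    zt <- mu
    for (k in seq_len(L)) zt <- zt + B[, , k] %*% (z[, t - k] - mu)
    z[, t] <- zt + rnorm(n, sd = spec$innovation_sd)
  }
  z <- z[, (burn + 1):Ttot, drop = FALSE]
  rel <- apply(exp(z), 2, function(col) col / sum(col))
  counts <- apply(rel, 2, function(p) rmultinom(1, spec$sequencing_depth, p))
  if (spec$detection_floor > 0) {
    obs_rel <- sweep(counts, 2, pmax(colSums(counts), 1), "/")
    counts[obs_rel < spec$detection_floor] <- 0
  }
  truth_edges <- rbind(
    data.frame(cause = taxa, effect = taxa, lag = 1L,
               coefficient = spec$self_coefficient,
               stringsAsFactors = FALSE),
    data.frame(cause = taxa[pick$cause], effect = taxa[pick$effect],
               lag = pick$lag, coefficient = pick$coefficient,
               stringsAsFactors = FALSE))
  truth_edges$sign <- ifelse(truth_edges$coefficient > 0, 1L, -1L)
  truth_edges$intraspecific <- truth_edges$cause == truth_edges$effect
  list(table = genus_table(counts, taxa = taxa, days = seq_len(spec$T),
                           site = "synthetic"),
       truth = list(edges = truth_edges, latent = z, B = B,
                    spectral_radius = rad, taxa = taxa))
}

#' Score recovery of ground-truth edges
#'
#' `exact_lag` matches an estimated edge to a true edge on identical
#' (cause, effect, lag); `lag_window` allows |lag difference| <= 1 on the
#' same ordered pair. Recall is the fraction of true edges matched;
#' precision the fraction of estimated edges matching some true edge
#' (`NA` for an empty estimate); sign accuracy is computed over matched
#' true edges against the largest-|coefficient| matching estimate.
#'
#' @param truth ground-truth list (or its `edges` data.frame).
#' @param edges estimated edge data.frame.
#' @param match `"exact_lag"` or `"lag_window"`.
#' @return list `precision`, `recall`, `sign_accuracy`, `n_true`,
#'   `n_estimated`, `n_matched`.
#' @export
score_recovery <- function(truth, edges, match = c("exact_lag",
                                                   "lag_window")) {
  match <- match.arg(match)
  te <- if (is.data.frame(truth)) truth else truth$edges
  hit <- function(c1, e1, l1, c2, e2, l2)
    c1 == c2 & e1 == e2 &
      (if (match == "exact_lag") l1 == l2 else abs(l1 - l2) <= 1)
  n_true <- nrow(te)
  n_est <- nrow(edges)
  matched <- 0L
  sign_ok <- 0L
  for (i in seq_len(n_true)) {
    m <- which(hit(te$cause[i], te$effect[i], te$lag[i],
                   edges$cause, edges$effect, edges$lag))
    if (length(m)) {
      matched <- matched + 1L
      best <- m[which.max(abs(edges$coefficient[m]))]
      if (sign(edges$coefficient[best]) == sign(te$coefficient[i]))
        sign_ok <- sign_ok + 1L
    }
  }
  est_hit <- vapply(seq_len(n_est), function(j)
    any(hit(edges$cause[j], edges$effect[j], edges$lag[j],
            te$cause, te$effect, te$lag)), logical(1))
  list(precision = if (n_est > 0) mean(est_hit) else NA_real_,
       recall = if (n_true > 0) matched / n_true else NA_real_,
       sign_accuracy = if (matched > 0) sign_ok / matched else NA_real_,
       n_true = n_true, n_estimated = n_est, n_matched = matched)
}
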