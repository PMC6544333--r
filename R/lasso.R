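#' Smallest penalty with an all-zero lasso solution
#'
#' `lambda_max = max_j |<x_j, y - mean(y)>| / N`; at or above this penalty
#' the lasso with unpenalized intercept shrinks every coefficient to zero.
#'
#' @param design a [build_lagged_design()] result (or any list with `X`, `y`).
#' @return non-negative scalar.
#' @export
lambda_max <- function(design) {
  y <- design$y
  max(abs(crossprod(design$X, y - mean(y)))) / length(y)
}

# decreasing log-spaced penalty grid from lmax down to lmax/ratio
lambda_grid <- function(lmax, size, ratio) {
  if (size == 1L) return(lmax)
  if (lmax <= 0) lmax <- .Machine$double.eps
  exp(seq(log(lmax), log(lmax / ratio), length.out = size))
}

#' Fit the lasso at one penalty
#'
#' Minimizes `(1/(2N)) sum(residual^2) + penalty * sum(|coefficient|)` by
#' cyclic coordinate descent with an unpenalized intercept; convergence
#' when the largest absolute coefficient change in a sweep is below `tol`.
#' The objective is evaluated after every full sweep and verified to be
#' non-increasing.
#'
#' @param design a [build_lagged_design()] result.
#' @param penalty non-negative penalty (lambda).
#' @param beta_init optional warm-start coefficient vector.
#' @param tol convergence tolerance on coefficient changes.
#' @param maxit maximum number of sweeps.
#' @return list with `coefficients` (named by design column), `intercept`,
#'   `n_sweeps`, `converged`, and the per-sweep `objective` trace.
#' @export
lasso_fit <- function(design, penalty, beta_init = NULL, tol = 1e-7,
                      maxit = 10000L) {
  stopifnot(penalty >= 0)
  if (!all(is.finite(design$X)) || !all(is.finite(design$y)))
    stop("design contains non-finite entries")
  if (is.null(beta_init)) beta_init <- numeric(ncol(design$X))
  fit <- cpp_lasso(design$X, design$y, penalty, beta_init, tol,
                   as.integer(maxit), TRUE)
  obj <- fit$objective
  if (length(obj) > 1 && any(diff(obj) > 1e-8 * (1 + abs(obj[-length(obj)]))))
    stop("coordinate descent objective increased; numerical failure")
  names(fit$beta) <- colnames(design$X)
  list(coefficients = fit$beta, intercept = fit$intercept,
       n_sweeps = fit$n_sweeps, converged = fit$converged, objective = obj)
}

#' Rolling-origin cross-validated penalty selection
#'
#' Splits the processed series into thirds at `T1 = floor(T'/3)` and
#' `T2 = floor(2T'/3)`. For every penalty on a log-spaced grid (anchored at
#' the full design's [lambda_max()]), the model is refit on observations
#' `1..t` for each t from T1 to T2-1 and scored on the one-step forecast of
#' observation t+1; the penalty minimizing this mean squared forecast error
#' is selected (smallest penalty among minimizers on ties). The selected
#' penalty is then validated analogously over the final third without
#' reselecting.
#'
#' @param series a `processed_series`.
#' @param response genus name.
#' @param config a [run_config()].
#' @param warm warm-start rolling refits from the previous window (results
#'   are equivalent with or without warm starting up to the refit
#'   tolerance; the flag only affects speed).
#' @param cv_tol,cv_maxit convergence tolerance and sweep cap of each
#'   rolling refit. Refits are screened to a KKT working set and capped:
#'   forecast-error ranking is insensitive to solving every interim model
#'   to the final-fit tolerance, and the selected penalty's final model is
#'   always refit at the full [lasso_fit()] contract.
#' @return an object of class `penalty_path`: list with `grid`, `msfe`,
#'   `selected`, `validation_msfe`, and the `design` dimensions used.
#' @export
rolling_cv_select <- function(series, response, config = run_config(),
                              warm = TRUE, cv_tol = 1e-5, cv_maxit = 10L) {
  L <- config$lags
  Tp <- ncol(series$values)
  if (Tp < 3 * (L + 2))
    stop("series too short for rolling cross-validation: need T' >= ",
         3 * (L + 2), ", have ", Tp)
  d <- build_lagged_design(series, response, L)
  grid <- lambda_grid(lambda_max(d), config$lambda_grid_size,
                      config$lambda_ratio)
  T1 <- floor(Tp / 3)
  T2 <- floor(2 * Tp / 3)
  # observation t corresponds to design row t - L (1-based); forecasting
  # observation t+1 means predicting row (t - L) + 1, i.e. 0-based row m
  # after fitting on the first m rows
  cv <- cpp_rolling_msfe(d$X, d$y, grid, T1 - L, T2 - 1L - L, cv_tol,
                         as.integer(cv_maxit), warm)
  msfe <- cv$msfe
  sel_idx <- max(which(msfe == min(msfe)))  # grid decreasing: last = smallest
  val <- cpp_rolling_msfe(d$X, d$y, grid[sel_idx], T2 - L, Tp - 1L - L,
                          cv_tol, as.integer(cv_maxit), warm)
  selected <- grid[sel_idx]
  structure(list(grid = grid, msfe = msfe, selected = selected,
                 validation_msfe = val$msfe[1], response = response,
                 n_obs = Tp, n_cols = ncol(d$X)),
            class = "penalty_path")
}

#' Fit the full conditional Granger model for every response genus
#'
#' Runs [rolling_cv_select()] per genus, then refits on the complete series
#' at each genus's selected penalty, assembling the n x n x L coefficient
#' tensor `B[effect, cause, lag]` on the standardized-differenced scale.
#' A zero entry means the coefficient was not retained by the lasso.
#'
#' @param series a `processed_series`.
#' @param config a [run_config()].
#' @return an object of class `coef_tensor`: list with `taxa`, `B` (3-d
#'   array), `penalties`, `intercepts`, `validation_msfe` per response.
#' @export
fit_all_responses <- function(series, config = run_config()) {
  taxa <- series$taxa
  n <- length(taxa)
  L <- config$lags
  B <- array(0, dim = c(n, n, L),
             dimnames = list(effect = taxa, cause = taxa, lag = NULL))
  penalties <- intercepts <- vmsfe <- setNames(numeric(n), taxa)
  for (e in seq_len(n)) {
    pp <- rolling_cv_select(series, taxa[e], config)
    d <- build_lagged_design(series, taxa[e], L)
    fit <- lasso_fit(d, pp$selected)
    for (g in seq_len(n))
      B[e, g, ] <- fit$coefficients[(g - 1L) * L + seq_len(L)]
    penalties[e] <- pp$selected
    intercepts[e] <- fit$intercept
    vmsfe[e] <- pp$validation_msfe
  }
  structure(list(taxa = taxa, B = B, penalties = penalties,
                 intercepts = intercepts, validation_msfe = vmsfe,
                 site = series$site),
            class = "coef_tensor")
}

#' @export
print.coef_tensor <- function(x, ...) {
  nz <- sum(x$B != 0)
  cat("coef_tensor: site '", x$site, "', ", length(x$taxa), " taxa x ",
      dim(x$B)[3], " lags; ", nz, " retained coefficients (",
      round(100 * nz / length(x$B), 1), "% of tensor)\n", sep = "")
  invisible(x)
}
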