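#' Pipeline run configuration
#'
#' Collects every tunable constant of the analysis in one validated object.
#' Defaults are the study conditions: 20 daily lags, genera retained when
#' detected on at least 90% of days, absences imputed uniformly between
#' 1e-5 and 1e-3 of the taxon's mean abundance, strong coefficients cut at
#' the top 5 percentile per sign, short interactions at lags 1-5 days and
#' long at 15-20 days, alpha 0.05 for the Pearson tests, and a 50-point
#' log-spaced penalty grid spanning four decades below lambda_max.
#'
#' @param lags maximum lag L in days.
#' @param prevalence_threshold minimum fraction of days with nonzero
#'   abundance for a genus to be retained, in (0, 1].
#' @param impute_lo,impute_hi bounds of the uniform imputation draw, as
#'   fractions of the taxon's mean; 0 < lo < hi < 1.
#' @param strong_percentile percentile (in percent) defining strong
#'   coefficients within each sign.
#' @param short_range,long_range inclusive lag windows (length-2 integer
#'   vectors), disjoint sub-intervals of `[1, lags]`.
#' @param alpha significance level for correlation tests.
#' @param lambda_grid_size number of penalty-grid points.
#' @param lambda_ratio ratio lambda_max / lambda_min of the grid.
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it so stages are independently reproducible.
#' @return an object of class `run_config` (a validated list).
#' @export
run_config <- function(lags = 20L, prevalence_threshold = 0.90,
                       impute_lo = 1e-5, impute_hi = 1e-3,
                       strong_percentile = 5, short_range = c(1L, 5L),
                       long_range = c(15L, 20L), alpha = 0.05,
                       lambda_grid_size = 50L, lambda_ratio = 1e4,
                       seed = 1L) {
  cfg <- structure(
    list(lags = as.integer(lags),
         prevalence_threshold = prevalence_threshold,
         impute_lo = impute_lo, impute_hi = impute_hi,
         strong_percentile = strong_percentile,
         short_range = as.integer(short_range),
         long_range = as.integer(long_range),
         alpha = alpha,
         lambda_grid_size = as.integer(lambda_grid_size),
         lambda_ratio = lambda_ratio,
         seed = as.integer(seed)),
    class = "run_config")
  validate_run_config(cfg)
}

#' @rdname run_config
#' @param cfg object to validate.
#' @export
validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  with(cfg, {
    if (!(prevalence_threshold > 0 && prevalence_threshold <= 1))
      stop("prevalence_threshold must be in (0, 1]")
    if (!(impute_lo > 0 && impute_lo < impute_hi && impute_hi < 1))
      stop("need 0 < impute_lo < impute_hi < 1")
    if (lags < 1L) stop("lags must be >= 1")
    for (r in list(short_range, long_range))
      if (length(r) != 2L || r[1] > r[2] || r[1] < 1L || r[2] > lags)
        stop("timescale windows must be sub-intervals of [1, lags]")
    if (short_range[2] >= long_range[1] && long_range[2] >= short_range[1])
      stop("short_range and long_range must be disjoint")
    if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
    if (lambda_grid_size < 1L) stop("lambda_grid_size must be >= 1")
    if (lambda_ratio <= 1) stop("lambda_ratio must exceed 1")
  })
  cfg
}

# deterministic per-stage seeds derived from the master seed; offsets keep
# results < 2^31 and distinct across stages
derive_seed <- function(cfg, stage) {
  offs <- c(impute = 101L, reshuffle = 211L, simulate = 307L)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage)
  (cfg$seed %% 2000000000L) + offs[[stage]]
}
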