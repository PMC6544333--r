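#' Keep genera detected in at least a given fraction of days
#'
#' @param table a [genus_table()].
#' @param threshold minimum fraction of days with nonzero abundance,
#'   in (0, 1]; the boundary is inclusive (a genus present on exactly
#'   `threshold` of days is kept).
#' @return a [genus_table()] with the retained taxa, input order preserved.
#' @export
filter_prevalent <- function(table, threshold = 0.90) {
  validate_genus_table(table)
  stopifnot(threshold > 0, threshold <= 1)
  prev <- rowMeans(table$values > 0)
  keep <- prev >= threshold
  if (!any(keep))
    stop("no taxon reaches prevalence ", threshold,
         "; lower the threshold or check the input table")
  genus_table(table$values[keep, , drop = FALSE],
              taxa = table$taxa[keep], days = table$days, site = table$site)
}

#' Replace undetected abundances by small random values
#'
#' Zeros are assumed to be detection failures, not true absences, so each
#' zero is replaced by an independent draw uniform on
#' `[lo * m, hi * m]` where `m` is that taxon's mean abundance over the raw
#' series. Nonzero entries are untouched.
#'
#' @param table a [genus_table()].
#' @param lo,hi bounds as fractions of the taxon mean, 0 < lo < hi.
#' @param seed integer seed making the draws reproducible.
#' @return an imputed [genus_table()].
#' @export
impute_absences <- function(table, lo = 1e-5, hi = 1e-3, seed = 1L) {
  validate_genus_table(table)
  stopifnot(lo > 0, lo < hi)
  v <- table$values
  means <- rowMeans(v)
  if (any(means <= 0))
    stop("all-zero series (mean undefined) for taxon '",
         table$taxa[which(means <= 0)[1]], "'")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  for (i in seq_len(nrow(v))) {
    z <- which(v[i, ] == 0)
    if (length(z))
      v[i, z] <- runif(length(z), lo * means[i], hi * means[i])
  }
  genus_table(v, taxa = table$taxa, days = table$days, site = table$site)
}

#' Convert abundances to per-day proportions (compositional closure)
#'
#' @param table a [genus_table()].
#' @return a [genus_table()] whose columns each sum to 1.
#' @export
to_relative <- function(table) {
  validate_genus_table(table)
  s <- colSums(table$values)
  if (any(s <= 0))
    stop("zero total abundance on day ", table$days[which(s <= 0)[1]])
  genus_table(sweep(table$values, 2, s, "/"),
              taxa = table$taxa, days = table$days, site = table$site)
}

#' Standardize each genus by its own mean and standard deviation
#'
#' Uses the sample (n-1) standard deviation. Abundances spanning orders of
#' magnitude are brought to a common scale so model coefficients read as
#' standard-deviation changes.
#'
#' @param table a [genus_table()].
#' @return a standardized table (class `genus_table` with possibly
#'   negative entries, stored as a plain list of the same shape).
#' @export
standardize <- function(table) {
  v <- table$values
  mu <- rowMeans(v)
  sdv <- apply(v, 1, sd)
  if (any(sdv == 0))
    stop("constant series for taxon '", table$taxa[which(sdv == 0)[1]],
         "'; standardization undefined")
  out <- (v - mu) / sdv
  structure(list(site = table$site, taxa = table$taxa, days = table$days,
                 values = out), class = "genus_table")
}

#' First-difference each genus series
#'
#' Removes stochastic and deterministic trends; output column t is input
#' column t+1 minus input column t.
#'
#' @param table a `genus_table`-shaped object (standardized values allowed).
#' @return same shape with one fewer column; day index d labels the
#'   transition d -> d+1.
#' @export
first_difference <- function(table) {
  v <- table$values
  if (ncol(v) < 2) stop("need at least 2 days to difference")
  out <- v[, -1, drop = FALSE] - v[, -ncol(v), drop = FALSE]
  structure(list(site = table$site, taxa = table$taxa,
                 days = table$days[-length(table$days)], values = out),
            class = "genus_table")
}

#' Full preprocessing chain for one body site
#'
#' Applies, in order: prevalence filtering, absence imputation, closure to
#' relative abundances, per-genus standardization, first differencing.
#' The imputation seed is derived from the master seed in `config`.
#'
#' @param table raw [genus_table()] of counts or abundances.
#' @param config a [run_config()].
#' @return an object of class `processed_series`: list with `site`, `taxa`,
#'   `values` (taxa x (T-1) matrix of standardized differenced relative
#'   abundances), `imputation_seed` and `provenance` (ordered step names).
#' @export
preprocess <- function(table, config = run_config()) {
  validate_run_config(config)
  iseed <- derive_seed(config, "impute")
  steps <- c("filter_prevalent", "impute_absences", "to_relative",
             "standardize", "first_difference")
  x <- filter_prevalent(table, config$prevalence_threshold)
  x <- impute_absences(x, config$impute_lo, config$impute_hi, seed = iseed)
  x <- to_relative(x)
  x <- standardize(x)
  x <- first_difference(x)
  structure(list(site = table$site, taxa = x$taxa, values = x$values,
                 imputation_seed = iseed, provenance = steps),
            class = "processed_series")
}

#' @export
print.processed_series <- function(x, ...) {
  cat("processed_series: site '", x$site, "', ", length(x$taxa),
      " taxa x ", ncol(x$values), " transitions\n", sep = "")
  cat("steps:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Serialize a processed series (matrix TSV + provenance sidecar)
#'
#' @param series a `processed_series`.
#' @param path matrix destination; the provenance sidecar is written next
#'   to it as `<path>.provenance.txt`.
#' @return `path`, invisibly.
#' @export
write_processed_series <- function(series, path) {
  df <- data.frame(taxon = series$taxa, series$values, check.names = FALSE)
  colnames(df) <- c("taxon", seq_len(ncol(series$values)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(paste0("site\t", series$site),
               paste0("imputation_seed\t", series$imputation_seed),
               paste0("step\t", series$provenance)),
             paste0(path, ".provenance.txt"))
  invisible(path)
}
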