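# programmatic fixtures shared across test files

make_counts_table <- function(n = 5, T = 40, seed = 1, site = "site",
                              zero_frac = 0) {
  set.seed(seed)
  m <- matrix(rpois(n * T, 50) + 1, n, T)
  if (zero_frac > 0)
    m[sample(length(m), round(zero_frac * length(m)))] <- 0
  genus_table(m, taxa = sprintf("g%02d", seq_len(n)), days = seq_len(T),
              site = site)
}

make_processed <- function(n = 3, T = 100, seed = 1, site = "syn") {
  set.seed(seed)
  structure(list(site = site, taxa = sprintf("g%02d", seq_len(n)),
                 values = matrix(rnorm(n * T), n, T),
                 imputation_seed = seed, provenance = "synthetic"),
            class = "processed_series")
}

make_edges <- function(cause, effect, lag, coefficient, strong = FALSE) {
  data.frame(cause = cause, effect = effect, lag = as.integer(lag),
             coefficient = coefficient,
             sign = ifelse(coefficient > 0, 1L, -1L),
             intraspecific = cause == effect,
             strong = rep(strong, length.out = length(cause)),
             stringsAsFactors = FALSE)
}

# processed series whose last taxon is a known lagged function of three
# predictor (taxon, lag) pairs plus Gaussian noise
make_known_predictor_series <- function(Tprime = 350, seed = 1, b = 0.5,
                                        noise_sd = 0.2) {
  set.seed(seed)
  n <- 5
  v <- matrix(rnorm(n * Tprime), n, Tprime)
  truth <- data.frame(taxon = c("g01", "g02", "g03"),
                      lag = c(2L, 7L, 15L),
                      coefficient = c(b, -b, b))
  for (t in 16:Tprime)
    v[n, t] <- truth$coefficient[1] * v[1, t - 2] +
      truth$coefficient[2] * v[2, t - 7] +
      truth$coefficient[3] * v[3, t - 15] + rnorm(1, sd = noise_sd)
  list(series = structure(
         list(site = "known", taxa = sprintf("g%02d", seq_len(n)),
              values = v, imputation_seed = seed, provenance = "synthetic"),
         class = "processed_series"),
       truth = truth, response = sprintf("g%02d", n))
}

# exact lasso by enumeration of sign patterns (closed-form stationarity
# solve per pattern); independent of the coordinate-descent path
lasso_brute <- function(X, y, lambda) {
  n <- nrow(X); p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  best <- NULL; bestobj <- Inf
  for (code in 0:(3^p - 1)) {
    s <- integer(p); c0 <- code
    for (j in seq_len(p)) { s[j] <- c0 %% 3 - 1; c0 <- c0 %/% 3 }
    S <- which(s != 0)
    b <- numeric(p)
    if (length(S)) {
      XS <- Xc[, S, drop = FALSE]
      bS <- tryCatch(
        solve(crossprod(XS), crossprod(XS, yc) - n * lambda * s[S]),
        error = function(e) NULL)
      if (is.null(bS) || any(sign(bS) != s[S])) next
      b[S] <- bS
    }
    obj <- sum((yc - Xc %*% b)^2) / (2 * n) + lambda * sum(abs(b))
    if (obj < bestobj) { bestobj <- obj; best <- b }
  }
  list(beta = best, objective = bestobj)
}
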