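make_tensor <- function(B, taxa) {
  structure(list(taxa = taxa, B = B,
                 penalties = setNames(numeric(length(taxa)), taxa),
                 intercepts = setNames(numeric(length(taxa)), taxa),
                 site = "t"), class = "coef_tensor")
}

test_that("edges materialize exactly the nonzero tensor entries", {
  taxa <- c("a", "b", "c")
  B <- array(0, c(3, 3, 4))
  expect_equal(nrow(extract_edges(make_tensor(B, taxa))), 0)
  B[2, 1, 2] <- 0.6
  e <- extract_edges(make_tensor(B, taxa))
  expect_equal(nrow(e), 1)
  expect_equal(e$cause, "a")
  expect_equal(e$effect, "b")
  expect_equal(e$lag, 2L)
  expect_equal(e$coefficient, 0.6)
  expect_false(e$intraspecific)

  set.seed(1)
  B2 <- array(0, c(3, 3, 4))
  B2[sample(length(B2), 15)] <- rnorm(15)
  e2 <- extract_edges(make_tensor(B2, taxa))
  expect_equal(nrow(e2), sum(B2 != 0))
  # counting oracle: every edge maps back to its tensor entry
  for (i in seq_len(nrow(e2)))
    expect_equal(B2[match(e2$effect[i], taxa), match(e2$cause[i], taxa),
                    e2$lag[i]], e2$coefficient[i])
})

test_that("strong cuts use interpolated percentiles per sign", {
  e <- make_edges(rep("a", 20), rep("b", 20), 1:20, as.numeric(1:20))
  ms <- mark_strong(e, 5)
  expect_equal(ms$thresholds$positive_cut, 19.05)
  expect_identical(which(ms$edges$strong), 20L)

  single <- make_edges("a", "b", 1, -0.3)
  expect_true(mark_strong(single, 5)$edges$strong)

  sym <- make_edges(rep("a", 40), rep("b", 40), rep(1:20, 2),
                    c(1:20, -(1:20)))
  mm <- mark_strong(sym, 5)
  expect_equal(sum(mm$edges$strong & mm$edges$coefficient > 0), 1)
  expect_equal(sum(mm$edges$strong & mm$edges$coefficient < 0), 1)
  expect_equal(mm$edges$coefficient[mm$edges$strong], c(20, -20))

  onlypos <- make_edges(c("a", "a"), c("b", "b"), 1:2, c(0.1, 0.4))
  expect_true(is.na(mark_strong(onlypos, 5)$thresholds$negative_cut))
})

test_that("strong count per sign stays within quantile granularity of 5%", {
  set.seed(2)
  for (E in c(40, 100, 400)) {
    e <- make_edges(rep("a", E), rep("b", E), sample(20, E, TRUE),
                    abs(rnorm(E)))
    k <- sum(mark_strong(e, 5)$edges$strong)
    expect_true(abs(k - ceiling(0.05 * E)) <= 1,
                label = paste("E =", E, "flagged", k))
  }
})

test_that("timescale calls follow the window and conflict rules", {
  one <- make_edges("a", "b", 3, 0.5)
  cl <- classify_timescales(one, c(1, 5), c(15, 20))
  expect_equal(cl$short_sign, "positive")
  expect_equal(cl$long_sign, "none")

  confl <- make_edges(c("a", "a"), c("b", "b"), c(2, 4), c(0.5, -0.5))
  expect_equal(classify_timescales(confl, c(1, 5), c(15, 20))$short_sign,
               "conflicting")

  mid <- make_edges("a", "b", 10, 0.5)
  clm <- classify_timescales(mid, c(1, 5), c(15, 20))
  expect_equal(clm$short_sign, "none")
  expect_equal(clm$long_sign, "none")

  # invariant to edge ordering
  set.seed(3)
  e <- make_edges(sample(letters[1:4], 30, TRUE),
                  sample(letters[1:4], 30, TRUE),
                  sample(20, 30, TRUE), rnorm(30))
  a <- classify_timescales(e, c(1, 5), c(15, 20))
  b <- classify_timescales(e[sample(nrow(e)), ], c(1, 5), c(15, 20))
  expect_equal(a, b)
})

test_that("pair extremes match a brute-force scan", {
  e <- make_edges(rep("a", 3), rep("b", 3), 1:3, c(0.2, 0.5, -0.1))
  px <- pair_extremes(e)
  expect_equal(px$max_positive, 0.5)
  expect_equal(px$min_negative, -0.1)
  pos <- make_edges(c("a", "a"), c("b", "b"), 1:2, c(0.2, 0.3))
  expect_true(is.na(pair_extremes(pos)$min_negative))

  set.seed(4)
  r <- make_edges(sample(letters[1:3], 40, TRUE),
                  sample(letters[1:3], 40, TRUE),
                  sample(20, 40, TRUE), rnorm(40))
  px2 <- pair_extremes(r)
  for (i in seq_len(nrow(px2))) {
    co <- r$coefficient[r$cause == px2$cause[i] & r$effect == px2$effect[i]]
    expect_equal(px2$max_positive[i],
                 if (any(co > 0)) max(co[co > 0]) else NA_real_)
    expect_equal(px2$min_negative[i],
                 if (any(co < 0)) min(co[co < 0]) else NA_real_)
  }
})

test_that("coefficient count summaries tally distinct lags per pair", {
  e <- make_edges(c("a", "a", "a", "b"), c("b", "b", "a", "b"),
                  c(1, 7, 1, 2), c(0.1, 0.2, -0.4, -0.2))
  s <- coefficient_count_summary(e, "all")
  ab <- s$pair_counts[s$pair_counts$cause == "a" &
                        s$pair_counts$effect == "b", ]
  expect_equal(ab$n_coefficients, 2L)
  expect_equal(s$frac_effects_with_interspecific_predictor, 0.5)

  set.seed(5)
  r <- make_edges(sample(letters[1:4], 50, TRUE),
                  sample(letters[1:4], 50, TRUE),
                  sample(20, 50, TRUE), rnorm(50))
  r <- r[!duplicated(r[c("cause", "effect", "lag")]), ]
  s2 <- coefficient_count_summary(r, "all")
  expect_equal(sum(s2$pair_counts$n_coefficients), nrow(r))
  for (i in sample(nrow(s2$pair_counts), 5))
    expect_equal(s2$pair_counts$n_coefficients[i],
                 sum(r$cause == s2$pair_counts$cause[i] &
                       r$effect == s2$pair_counts$effect[i]))
})

test_that("lag-sign spectra conserve edge counts", {
  intra <- make_edges("a", "a", 1, -0.5, strong = TRUE)
  sp <- lag_sign_spectrum(intra, L = 20)
  row <- sp$spectrum[sp$spectrum$lag == 1 &
                       sp$spectrum$class == "intraspecific", ]
  expect_equal(row$negative, 1L)
  expect_equal(sum(sp$spectrum$positive) + sum(sp$spectrum$negative), 1)

  set.seed(6)
  r <- make_edges(sample(letters[1:4], 60, TRUE),
                  sample(letters[1:4], 60, TRUE),
                  sample(20, 60, TRUE), rnorm(60), strong = TRUE)
  spr <- lag_sign_spectrum(r, L = 20)
  expect_equal(sum(spr$spectrum$positive) + sum(spr$spectrum$negative),
               nrow(r))
  expect_equal(sum(spr$totals$positive) + sum(spr$totals$negative), nrow(r))
})

test_that("genus summaries count causes, effects and mean lags", {
  e <- make_edges(c("a", "a", "b"), c("b", "c", "b"), c(4, 16, 1),
                  c(0.5, 0.2, -0.3), strong = TRUE)
  g <- genus_summary(e, "strong")
  a <- g[g$genus == "a", ]
  expect_equal(a$cause_positive, 2L)
  expect_equal(a$mean_lag_interspecific, 10)
  b <- g[g$genus == "b", ]
  expect_equal(b$mean_lag_intraspecific, 1)
  expect_equal(b$effect_positive, 1L)
  expect_equal(b$cause_negative, 0L)
})
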