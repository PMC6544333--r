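test_that("shared-taxa set algebra matches brute force", {
  same <- shared_taxa(list(a = c("x", "y"), b = c("x", "y")))
  expect_equal(same$pairwise$jaccard, 1)
  disj <- shared_taxa(list(a = c("x", "y"), b = c("u", "v")))
  expect_equal(disj$pairwise$n_shared, 0)

  set.seed(1)
  pool <- sprintf("g%02d", 1:30)
  sites <- lapply(1:4, function(i) sample(pool, sample(10:20, 1)))
  names(sites) <- paste0("s", 1:4)
  sh <- shared_taxa(sites)
  for (k in seq_len(nrow(sh$pairwise))) {
    a <- sites[[sh$pairwise$site_a[k]]]
    b <- sites[[sh$pairwise$site_b[k]]]
    expect_equal(sh$pairwise$n_shared[k], length(intersect(a, b)))
    expect_equal(sh$pairwise$n_union[k], length(union(a, b)))
  }
  expect_equal(sum(sh$venn), length(unique(unlist(sites))))
  expect_equal(sh$n_core, length(Reduce(intersect, sites)))
  expect_error(shared_taxa(list(a = "x")), "at least 2")
})

test_that("quantitative and qualitative conservation follow their definitions", {
  taxa <- c("Micrococcus", "Veillonella", "Other")
  both <- make_edges("Micrococcus", "Veillonella", 20, 0.5, strong = TRUE)
  repq <- conserved_edges(both, both, taxa, taxa, "quantitative", "strong")
  expect_equal(nrow(repq$conserved), 1)
  repl <- conserved_edges(both, both, taxa, taxa, "qualitative", "strong",
                          short_range = c(1, 5), long_range = c(15, 20))
  expect_equal(nrow(repl$conserved), 1)
  expect_equal(repl$conserved$window, "long")

  # same pair and window, different lag: qualitative only
  a <- make_edges("Micrococcus", "Veillonella", 2, 0.5, strong = TRUE)
  b <- make_edges("Micrococcus", "Veillonella", 4, 0.5, strong = TRUE)
  expect_equal(nrow(conserved_edges(a, b, taxa, taxa, "quantitative",
                                    "strong")$conserved), 0)
  expect_equal(nrow(conserved_edges(a, b, taxa, taxa, "qualitative",
                                    "strong")$conserved), 1)

  # comparison restricted to shared taxa
  only_a <- make_edges("Private", "Veillonella", 2, 0.5, strong = TRUE)
  rep2 <- conserved_edges(rbind(a, only_a), rbind(b, only_a),
                          c(taxa, "Private"), taxa, "quantitative", "strong")
  expect_false("Private" %in% rep2$conserved$cause)
})

test_that("conservation fractions use the union denominator and are symmetric", {
  taxa <- letters[1:4]
  ea <- make_edges(c("a", "b"), c("b", "c"), c(2, 3), c(0.5, -0.5),
                   strong = TRUE)
  eb <- make_edges(c("a", "d"), c("b", "a"), c(2, 4), c(0.4, 0.2),
                   strong = TRUE)
  rep_ab <- conserved_edges(ea, eb, taxa, taxa, "quantitative", "strong")
  rep_ba <- conserved_edges(eb, ea, taxa, taxa, "quantitative", "strong")
  # union has 3 interspecific keys, 1 conserved
  expect_equal(unname(rep_ab$fractions["interspecific"]), 1 / 3)
  expect_equal(rep_ab$fractions, rep_ba$fractions)

  ident <- conserved_edges(ea, ea, taxa, taxa, "quantitative", "strong")
  expect_equal(unname(ident$fractions["interspecific"]), 1)
  disj <- conserved_edges(ea, make_edges("c", "d", 9, 1, strong = TRUE),
                          taxa, taxa, "quantitative", "strong")
  expect_equal(unname(disj$fractions["interspecific"]), 0)
  expect_true(is.na(disj$fractions["intraspecific"]))  # empty union

  half <- conserved_edges(
    make_edges(c("a", "b"), c("b", "c"), c(2, 2), c(1, 1), strong = TRUE),
    make_edges(c("a", "c"), c("b", "d"), c(2, 2), c(1, 1), strong = TRUE),
    taxa, taxa, "quantitative", "strong")
  expect_equal(unname(half$fractions["interspecific"]), 1 / 3)
})

test_that("quantitative conservation implies qualitative when lags fall in a window", {
  set.seed(2)
  taxa <- letters[1:5]
  for (i in 1:5) {
    ea <- make_edges(sample(taxa, 12, TRUE), sample(taxa, 12, TRUE),
                     sample(c(1:5, 15:20), 12, TRUE), rnorm(12),
                     strong = TRUE)
    eb <- rbind(ea[sample(nrow(ea), 6), ],
                make_edges(sample(taxa, 6, TRUE), sample(taxa, 6, TRUE),
                           sample(c(1:5, 15:20), 6, TRUE), rnorm(6),
                           strong = TRUE))
    q <- conserved_edges(ea, eb, taxa, taxa, "quantitative", "strong")
    ql <- conserved_edges(ea, eb, taxa, taxa, "qualitative", "strong")
    qual_keys <- paste(ql$conserved$cause, ql$conserved$effect,
                       ql$conserved$sign)
    for (k in seq_len(nrow(q$conserved))) {
      row <- q$conserved[k, ]
      win_sign <- paste(row$cause, row$effect,
                        ifelse(row$sign > 0, "positive", "negative"))
      # skip pairs whose window call is conflicting in either site
      ca <- classify_timescales(ea[ea$cause == row$cause &
                                     ea$effect == row$effect, ])
      cb <- classify_timescales(eb[eb$cause == row$cause &
                                     eb$effect == row$effect, ])
      w <- if (row$lag <= 5) "short_sign" else "long_sign"
      if (ca[[w]] != "conflicting" && cb[[w]] != "conflicting")
        expect_true(win_sign %in% qual_keys)
    }
  }
})
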