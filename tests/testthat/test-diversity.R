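test_that("analytic rarefaction matches hand-enumerated toy values", {
  inc <- toy_incidence()
  expect_equal(inc$Ti, c(f1 = 1, f2 = 2, f3 = 4, f4 = 2, f5 = 1))
  expect_equal(analytic_rarefaction(inc, 1), 2.5)          # mean per-isolate richness
  expect_equal(analytic_rarefaction(inc, 2), 5 - 8 / 6)    # all 6 two-isolate subsets
  expect_equal(analytic_rarefaction(inc, 3), 4.5)
  expect_equal(analytic_rarefaction(inc, 4), inc$S_obs)    # t = T sees everything
  expect_error(analytic_rarefaction(inc, 5), class = "chemcov_bad-argument")
})

test_that("analytic rarefaction equals the exhaustive subset average", {
  set.seed(101)
  for (rep in 1:20) {
    T <- sample(3:8, 1)
    inc <- random_incidence(S = sample(5:25, 1), T = T)
    for (t in seq_len(T))
      expect_equal(analytic_rarefaction(inc, t), exhaustive_rarefaction(inc, t),
                   tolerance = 1e-12)
  }
})

test_that("analytic rarefaction agrees with vegan's exact method", {
  skip_if_not_installed("vegan")
  set.seed(7)
  inc <- random_incidence(S = 60, T = 15)
  sac <- vegan::specaccum(t(inc$incidence), method = "exact")
  expect_equal(analytic_rarefaction(inc, seq_len(inc$T)),
               as.numeric(sac$richness), tolerance = 1e-10)
})

test_that("interpolated curves are nondecreasing and concave", {
  set.seed(33)
  for (rep in 1:10) {
    inc <- random_incidence(S = 40, T = 12)
    curve <- analytic_rarefaction(inc, 1:12)
    expect_true(all(diff(curve) >= -1e-12))
    expect_true(all(diff(diff(curve)) <= 1e-12))
  }
})

test_that("Chao2 unseen richness follows both estimator branches", {
  expect_equal(chao2_unseen(0, 5, 10), 0)                    # no uniques
  expect_equal(chao2_unseen(4, 2, 10), 0.9 * 16 / 4)         # classic branch: 3.6
  expect_equal(chao2_unseen(3, 0, 5), 0.8 * 3 * 2 / 2)       # bias-corrected: 2.4
  expect_error(chao2_unseen(1, 1, 1), class = "chemcov_bad-argument")
})

test_that("extrapolation starts at S_obs and approaches the Chao2 asymptote", {
  inc <- toy_incidence()                      # Q1=2, Q2=2 => Q0 = 0.75
  expect_equal(extrapolate_richness(inc, 0), 5)
  expect_equal(extrapolate_richness(inc, 1), 5.3)   # 5 + 0.75 * (2 / 5)
  q0 <- chao2_unseen(inc$Q1, inc$Q2, inc$T)
  expect_equal(extrapolate_richness(inc, 1e6), inc$S_obs + q0, tolerance = 1e-9)
  # no uniques: nothing unseen, flat extrapolation
  flat <- incidence_matrix(matrix(1, 3, 4))
  expect_equal(extrapolate_richness(flat, c(0, 10, 1000)), rep(3, 3))
})

test_that("accumulation_curve stitches interpolation and extrapolation", {
  inc <- toy_incidence()
  ac <- accumulation_curve(inc, endpoint = 10)
  expect_equal(nrow(ac), 10)
  expect_equal(ac$method, rep(c("interpolated", "extrapolated"), c(4, 6)))
  expect_equal(ac$expected_richness[4], inc$S_obs)
  expect_true(all(ac$expected_richness[5:10] >= inc$S_obs))
  expect_true(all(diff(ac$expected_richness) >= -1e-12))
})

test_that("coverage solver returns smallest counts and is monotone", {
  inc <- toy_incidence()
  ct <- coverage_targets(inc, c(0.5, 0.75, 0.9))
  expect_equal(ct$n_isolates, c(1L, 3L, 3L))   # E[S(t)] = 2.5, 3.667, 4.5
  expect_equal(coverage_targets(inc, 1)$n_isolates, inc$T)  # singletons force t = T
  set.seed(5)
  for (rep in 1:10) {
    inc <- random_incidence(S = 50, T = 10)
    n <- coverage_targets(inc, sort(runif(5, 0.1, 1)))$n_isolates
    expect_true(all(diff(n) >= 0))
  }
})

test_that("end slope equals Q1 / T and vanishes without uniques", {
  inc <- toy_incidence()
  expect_equal(end_slope(inc), 0.5)
  expect_equal(end_slope(inc), inc$Q1 / inc$T)
  set.seed(9)
  for (rep in 1:10) {
    inc <- random_incidence(S = 30, T = 9)
    expect_equal(end_slope(inc), inc$Q1 / inc$T, tolerance = 1e-10)
  }
  no_uniq <- incidence_matrix(rbind(c(1, 1, 0), c(0, 1, 1), c(1, 1, 1)))
  expect_equal(end_slope(no_uniq), 0)
})

test_that("collector curve reproduces fixed orders and converges in mean", {
  inc <- toy_incidence()
  cc <- collector_curve(inc, order = c("iso4", "iso3", "iso2", "iso1"))
  expect_equal(cc$expected_richness, c(3, 3, 4, 5))   # hand-traced cumulative counts
  expect_equal(cc$expected_richness[inc$T], inc$S_obs)
  # mean over permutations approaches the exact expectation
  cm <- collector_curve(inc, n_perm = 4000, seed = 1)
  expect_equal(cm$expected_richness[2], 5 - 8 / 6, tolerance = 0.02)
  expect_error(collector_curve(inc, order = c(1, 1, 2, 3)),
               class = "chemcov_bad-argument")
})

test_that("alpha richness counts features per isolate", {
  inc <- toy_incidence()
  expect_equal(unname(alpha_richness(inc)), c(3, 2, 2, 3))
})

test_that("richness comparison reproduces a hand-computed ANOVA table", {
  r <- c(1, 2, 3, 11, 12, 13)
  g <- rep(c("a", "b"), each = 3)
  out <- compare_richness(r, g)
  expect_equal(out$anova_F, 150)         # MSB = 150, MSW = 1
  expect_equal(out$df, c(1, 4))
  expect_lt(out$anova_p, 0.001)
  # identical groups: F = 0, p = 1
  same <- compare_richness(c(1, 2, 3, 1, 2, 3), g)
  expect_equal(same$anova_F, 0, tolerance = 1e-12)
  expect_equal(same$anova_p, 1)
  # degenerate: no within-group variance anywhere
  expect_error(compare_richness(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               class = "chemcov_degenerate-anova")
})

test_that("Tukey HSD p-values match TukeyHSD and q uses Kramer SEs", {
  set.seed(2)
  r <- c(rnorm(5, 10), rnorm(8, 12), rnorm(4, 15))
  g <- rep(c("a", "b", "c"), c(5, 8, 4))
  out <- compare_richness(r, g)
  ref <- TukeyHSD(aov(r ~ factor(g)))$`factor(g)`
  expect_equal(out$tukey$p_adj, unname(ref[, "p adj"]))
  # q statistic referred to the studentized range reproduces the p-value
  p_from_q <- ptukey(out$tukey$q, nmeans = 3, df = length(r) - 3, lower.tail = FALSE)
  expect_equal(p_from_q, out$tukey$p_adj, tolerance = 1e-8)
})

test_that("balanced subsampling draws n per large group, keeps small ones", {
  set.seed(4)
  m <- matrix(rbinom(30 * 20, 1, 0.5), 30, 20)
  groups <- rep(c("big", "mid", "small"), c(10, 6, 4))
  inc <- incidence_matrix(m, groups = groups)
  expect_warning(sub <- balanced_subsample(inc, 6, seed = 1), "kept whole")
  expect_equal(as.integer(table(sub$groups)[c("big", "mid", "small")]),
               c(6L, 6L, 4L))
  # same seed, same draw
  sub2 <- suppressWarnings(balanced_subsample(inc, 6, seed = 1))
  expect_identical(colnames(sub$incidence), colnames(sub2$incidence))
  # n = group size is the identity on that group
  all6 <- suppressWarnings(balanced_subsample(inc, 10, seed = 2))
  expect_true(all(colnames(inc$incidence)[groups == "big"] %in%
                  colnames(all6$incidence)))
})
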