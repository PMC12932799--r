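test_that("frequency counts are exact sufficient statistics", {
  fc <- frequency_counts(c(a = 1, b = 1, c = 2))
  expect_equal(fc$S_obs, 3)
  expect_equal(fc$n, 4)
  expect_equal(f_k(fc, 1), 2L)
  expect_equal(f_k(fc, 2), 1L)
  expect_equal(f_k(fc, 99), 0L)

  # label invariance
  shuffled <- frequency_counts(c(c = 2, a = 1, b = 1))
  expect_equal(shuffled, fc)

  # invariants on random vectors: sum f_k = S_obs, sum k f_k = n
  set.seed(11)
  for (i in 1:20) {
    counts <- sample.int(12, sample.int(60, 1), replace = TRUE)
    fc <- frequency_counts(counts)
    expect_equal(sum(fc$f), fc$S_obs)
    expect_equal(sum(seq_along(fc$f) * fc$f), sum(counts))
  }

  degenerate <- frequency_counts(integer(0))
  expect_equal(degenerate$S_obs, 0)
  expect_equal(degenerate$n, 0)
  expect_error(frequency_counts(c(a = 0)), "positive")
})

test_that("chao1 follows both branches of the stated formula", {
  # no singletons: the correction vanishes
  expect_equal(chao1(counts_from_f(c(0, 3, 1))), 4)
  # S_obs = 10, f1 = 4, f2 = 2 -> 10 + 16/4 = 14
  expect_equal(chao1(c(counts_from_f(c(4, 2)), rep(5, 4))), 14)
  # bias-corrected branch: S_obs = 5, f1 = 3, f2 = 0 -> 5 + 3*2/2 = 8
  expect_equal(chao1(c(1, 1, 1, 3, 4)), 8)
})

test_that("ichao1 adds the stated f3/f4 correction", {
  # f3 = 0 reduces to chao1
  fc <- frequency_counts(counts_from_f(c(4, 2)))
  expect_equal(ichao1(fc), chao1(fc))
  # S_obs = 10, f1 = 4, f2 = 2, f3 = 2, f4 = 1 -> 14 + (2/4)*2 = 15
  expect_equal(ichao1(counts_from_f(c(4, 2, 2, 1, 1))), 15)
})

test_that("S_obs <= chao1 <= ichao1 on random frequency counts", {
  set.seed(21)
  for (i in 1:500) {
    counts <- sample.int(8, sample.int(40, 1), replace = TRUE)
    fc <- frequency_counts(counts)
    expect_gte(chao1(fc), fc$S_obs)
    expect_gte(ichao1(fc), chao1(fc))
  }
})

test_that("rarefaction interpolates and extrapolates correctly", {
  # two singletons, m = 1: 2 * (1 - C(1,1)/C(2,1)) = 1
  expect_equal(rarefaction_extrapolation(c(1, 1), 1), 1)

  set.seed(31)
  counts <- sample.int(10, 25, replace = TRUE)
  fc <- frequency_counts(counts)
  expect_equal(rarefaction_extrapolation(fc, 0), 0)
  expect_equal(rarefaction_extrapolation(fc, 1), 1)
  expect_equal(rarefaction_extrapolation(fc, fc$n), fc$S_obs)
  # the extrapolation limit is the Chao1 asymptote
  expect_equal(rarefaction_extrapolation(fc, fc$n + 1e7), chao1(fc),
               tolerance = 1e-9)

  # nondecreasing and concave on the interpolation range
  curve <- rarefaction_extrapolation(fc, 0:fc$n)
  expect_true(all(diff(curve) >= -1e-12))
  expect_true(all(diff(diff(curve)) <= 1e-12))

  # flat beyond n when there are no singletons
  nos <- frequency_counts(c(2, 2, 3))
  expect_equal(rarefaction_extrapolation(nos, 50), nos$S_obs)
})

test_that("analytic rarefaction matches Monte-Carlo subsampling", {
  set.seed(41)
  counts <- sample.int(15, 30, replace = TRUE)
  n <- sum(counts)
  m <- floor(n / 3)
  mc <- mc_rarefaction(counts, m, reps = 2e4)
  expect_lt(abs(rarefaction_extrapolation(counts, m) - mc$mean),
            3 * mc$mcse)
})

test_that("the log-transformed chao1 interval brackets the estimate", {
  # no singletons: T = 0 and the interval degenerates
  expect_equal(unname(chao1_log_ci(c(2, 2, 3))), c(3, 3))

  set.seed(51)
  for (i in 1:50) {
    counts <- sample.int(6, sample.int(80, 2)[2], replace = TRUE)
    fc <- frequency_counts(counts)
    ci <- chao1_log_ci(fc)
    expect_gte(ci[["lcl"]], fc$S_obs)
    expect_lte(ci[["lcl"]], chao1(fc))
    expect_gte(ci[["ucl"]], chao1(fc))
  }
})

test_that("bootstrap intervals are seeded, ordered, and B-stable", {
  set.seed(61)
  av <- abundance_vector(
    setNames(sample.int(10, 60, replace = TRUE), paste0("sp", 1:60)),
    "AA")
  ci1 <- bootstrap_ci(av, "ichao1", B = 100, seed = 9)
  ci2 <- bootstrap_ci(av, "ichao1", B = 100, seed = 9)
  expect_identical(ci1, ci2)
  expect_lte(ci1$lcl, ci1$point)
  expect_lte(ci1$point, ci1$ucl)

  big <- bootstrap_ci(av, "ichao1", B = 2000, seed = 10)
  small <- bootstrap_ci(av, "ichao1", B = 200, seed = 10)
  expect_lt(abs(big$se - small$se) / big$se, 0.25)

  # f1 = 0: full estimated coverage, so no undetected species are added
  # and resampling happens over the empirical distribution only
  flat <- abundance_vector(c(a = 2, b = 2, c = 3), "AA")
  ci <- bootstrap_ci(flat, "chao1", B = 100, seed = 1)
  expect_equal(ci$point, 3)
  expect_equal(ci$lcl, 3) # truncated at S_obs

  expect_error(bootstrap_ci(av, "chao1", B = 1), "at least 2")
})

test_that("estimate_richness keeps S_obs <= lcl <= point <= ucl", {
  set.seed(71)
  av <- abundance_vector(
    setNames(sample.int(6, 40, replace = TRUE), paste0("sp", 1:40)),
    "AA")
  for (spec in list(list(m = "ichao1", ci = "bootstrap"),
                    list(m = "inext", ci = "bootstrap"),
                    list(m = "inext", ci = "log"))) {
    est <- estimate_richness(av, spec$m, ci = spec$ci, B = 100, seed = 3)
    expect_gte(est$lcl, est$S_obs)
    expect_lte(est$lcl, est$point)
    expect_lte(est$point, est$ucl)
  }
  expect_error(estimate_richness(av, "ichao1", ci = "log"), "inext")
})

test_that("estimates approach truth as sampling saturates a community", {
  com <- generate_community(80, seed = 9)
  p <- com$species$p
  set.seed(10)
  prev_S <- 0
  for (n in c(200, 2000, 20000)) {
    counts <- tabulate(sample.int(80, n, replace = TRUE, prob = p))
    fc <- frequency_counts(counts[counts > 0])
    expect_gte(fc$S_obs, prev_S)
    expect_gte(chao1(fc), fc$S_obs)
    prev_S <- fc$S_obs
  }
  # at near-saturation the observed richness approaches the truth and
  # the estimator stays between it and a modest overshoot
  expect_gte(fc$S_obs, 70)
  expect_lte(fc$S_obs, 80)
  expect_lte(chao1(fc), 92)
})
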