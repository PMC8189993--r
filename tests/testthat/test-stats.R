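test_that("Welch from summaries equals Welch from raw data", {
  set.seed(41)
  for (i in 1:5) {
    x <- rnorm(8 + i, 10, 2)
    y <- rnorm(12, 11, 3)
    w <- welch_from_summary(mean(x), sd(x), length(x),
                            mean(y), sd(y), length(y))
    oracle <- t.test(x, y)
    expect_equal(w$t, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(oracle$parameter), tolerance = 1e-10)
    expect_equal(w$p, oracle$p.value, tolerance = 1e-10)
  }
  ident <- welch_from_summary(5, 1, 10, 5, 1, 10)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  sw <- welch_from_summary(11, 3, 12, 10, 2, 9)
  rev <- welch_from_summary(10, 2, 9, 11, 3, 12)
  expect_equal(sw$p, rev$p)
  expect_equal(sw$t, -rev$t)
  expect_error(welch_from_summary(1, 0, 5, 1, 0, 5), "not both zero")
  expect_error(welch_from_summary(1, 1, 1, 2, 1, 5), "n >= 2")
})

test_that("published Welch p-values are reproduced from the packaged table", {
  r1 <- species_tab[species_tab$species_code == "R1", ]
  r2 <- species_tab[species_tab$species_code == "R2", ]
  w <- welch_from_summary(r1$IL_mean, r1$IL_sd, 20, r2$IL_mean, r2$IL_sd, 20)
  expect_equal(signif(w$p, 2), 0.045)
  pest <- toupper(meta_tab$species_code[meta_tab$pest])
  is_pest <- toupper(species_tab$species_code) %in% pest
  v1 <- species_tab$VR_mean[is_pest]
  v2 <- species_tab$VR_mean[!is_pest]
  w2 <- welch_from_summary(mean(v1), sd(v1), length(v1),
                           mean(v2), sd(v2), length(v2))
  expect_equal(signif(w2$p, 2), 0.10)   # printed 0.1024
  expect_lt(abs(w2$p - 0.1024), 0.005)
})

test_that("Watson U2 randomization matches exhaustive permutation on tiny n", {
  a <- c(10, 40, 95, 170)
  b <- c(200, 250, 300, 355)
  obs <- watson_two_sample(a, b, mode = "randomization", B = 1999, seed = 2)
  # oracle: all C(8,4) = 70 label splits
  x <- c(a, b) * pi / 180
  u2_of <- function(i) chelamorph:::.watson_u2(x[i], x[-i])
  splits <- combn(8, 4)
  u2_all <- apply(splits, 2, u2_of)
  u2_obs <- u2_of(1:4)
  p_exact <- mean(u2_all >= u2_obs - 1e-12)
  expect_lt(abs(obs$p_randomization - p_exact), 0.05)
})

test_that("circular two-sample tests behave at the extremes", {
  a <- c(5, 15, 25, 35, 45, 55, 65, 75, 85, 95)
  same <- watson_two_sample(a, a, mode = "randomization", B = 499, seed = 3)
  expect_gt(same$p_randomization, 0.5)
  mww_same <- mardia_watson_wheeler(a, a, mode = "both", B = 499, seed = 3)
  expect_gt(mww_same$p_randomization, 0.5)
  expect_gt(mww_same$p_asymptotic, 0.5)
  # two tight clusters 180 degrees apart are decisively heterogeneous
  set.seed(4)
  ca <- (rnorm(10, 0, 5)) %% 360
  cb <- (rnorm(10, 180, 5)) %% 360
  w <- watson_two_sample(ca, cb, mode = "randomization", B = 999, seed = 4)
  expect_lte(w$p_randomization, 0.01)
  mw <- mardia_watson_wheeler(ca, cb, mode = "asymptotic")
  expect_lt(mw$p_asymptotic, 0.01)
  # symmetry in the sample order
  w_ab <- watson_two_sample(ca, cb, mode = "asymptotic")
  w_ba <- watson_two_sample(cb, ca, mode = "asymptotic")
  expect_equal(w_ab$statistic, w_ba$statistic, tolerance = 1e-12)
  expect_error(watson_two_sample(1:3, 1:10), "at least 4")
})

test_that("MWW asymptotic and randomization p agree for moderate samples", {
  set.seed(5)
  for (i in 1:3) {
    a <- (rnorm(25, 40, 30)) %% 360
    b <- (rnorm(25, 90, 30)) %% 360
    m <- mardia_watson_wheeler(a, b, mode = "both", B = 999, seed = i)
    expect_lt(abs(m$p_asymptotic - m$p_randomization), 0.05)
  }
})

test_that("size-ratio metrics follow their closed-form extremes", {
  g <- size_ratio_null_test(c(100, 130, 169), iterations = 50, seed = 1)
  expect_equal(unname(g$observed["variance_ratio"]), 0, tolerance = 1e-12)
  tied <- size_ratio_null_test(c(100, 100, 120), iterations = 50, seed = 1)
  expect_equal(unname(tied$observed["minimum_ratio"]), 1)
  expect_equal(unname(tied$observed["minimum_difference"]), 0)
  # adjacent ratios of the grassland-biome idiosomal indices
  s <- sort(c(211.78, 287.59, 304.24))
  expect_equal(round(s[2] / s[1], 4), 1.3580)
  expect_equal(round(s[3] / s[2], 4), 1.0579)
  expect_error(size_ratio_null_test(c(1, 2)), "at least 3")
  expect_error(size_ratio_null_test(c(-1, 2, 3)), "positive")
})

test_that("ratio metrics are scale invariant, difference metrics scale", {
  set.seed(6)
  s <- sort(runif(6, 100, 300))
  a <- chelamorph:::.size_metrics(s)
  b <- chelamorph:::.size_metrics(s * 2.5)
  expect_equal(b["variance_ratio"], a["variance_ratio"], tolerance = 1e-10)
  expect_equal(b["minimum_ratio"], a["minimum_ratio"], tolerance = 1e-10)
  expect_equal(unname(b["minimum_difference"]),
               unname(a["minimum_difference"]) * 2.5, tolerance = 1e-10)
  expect_equal(unname(b["variance_difference"]),
               unname(a["variance_difference"]) * 2.5^2, tolerance = 1e-10)
})

test_that("null-model p-values are calibrated under their own null", {
  set.seed(7)
  ps <- replicate(250, {
    sizes <- c(100, 300, runif(4, 100, 300))
    size_ratio_null_test(sizes, iterations = 199,
                         seed = sample.int(1e6, 1))$p[["variance_ratio"]]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(ps) - 0.5), 0.06)
})
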