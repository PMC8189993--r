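test_that("the divergence transform reproduces hand-computed values", {
  # identical distributions evaluated at the shared mean give exactly zero
  expect_equal(lbf(5, 5, 2, 5, 2), 0)
  # published-parameter worked examples (AC204 idiosomal index)
  expect_equal(lbf(185.87, 185.87, 10.93, 216.42, 2.995),
               log(10.93 / 2.995) - 30.55^2 / (2 * 2.995^2))
  expect_equal(round(lbf(185.87, 185.87, 10.93, 216.42, 2.995), 2), -50.73)
  expect_equal(round(lbf(216.42, 185.87, 10.93, 216.42, 2.995), 2), 5.20)
  expect_error(lbf(1, 1, 0, 1, 1, label = "IL"), "IL")
})

test_that("divergence matrix has the contracted shape and reference rows", {
  co <- simulate_cohort(mini_ref, n_per_species = 20, seed = 2)
  typ <- build_typical_reference(co)
  all_ind <- rbind(co[names(typ$individuals)], typ$individuals)
  dm <- build_divergence_matrix(all_ind, summarize_cohort(all_ind),
                                indicators = TRUE)
  n_sp <- length(unique(all_ind$species_code))
  expect_equal(dim(dm$lbf), c(nrow(all_ind), 6L))
  expect_equal(ncol(dm$standardised), 6L + n_sp)
  # typical rows average ~0 in every divergence column (3 SE tolerance)
  typ_rows <- dm$lbf[all_ind$species_code == "Typical", ]
  for (k in 1:6) {
    se <- sd(typ_rows[, k]) / sqrt(nrow(typ_rows))
    expect_lt(abs(mean(typ_rows[, k])), 3 * se + 1e-12)
  }
  # a species far from the reference has strongly negative divergences
  kl_rows <- dm$lbf[all_ind$species_code == "KL", ]
  expect_lt(mean(kl_rows[, "lbf_IL"]), 0)
})

test_that("full-cohort fit has the contracted dimensions and eigenstructure", {
  fit <- run_pipeline(seed = 3)$ordination
  n_cols <- 6 + 48
  expect_s3_class(fit, "chelal_ordination")
  expect_equal(length(fit$eigenvalues), n_cols)
  expect_equal(sum(fit$eigenvalues), n_cols, tolerance = 1e-8)
  expect_true(all(fit$eigenvalues > -1e-8))
  expect_equal(nrow(fit$scores), 48 * 20)
  # orientation: component-1 measure loadings share one sign, chelal and
  # cheliceral loadings exceed the body-size loading, CHI among the largest
  l1 <- fit$loadings[1:6, 1]
  expect_true(all(l1 > 0))
  expect_true(all(l1[c("lbf_L1U", "lbf_L2M", "lbf_CHI", "lbf_CLI",
                       "lbf_F2AV")] > l1["lbf_IL"]))
  expect_gte(rank(l1)[["lbf_CHI"]], 5)
  expect_lte(fit$loadings["lbf_IL", 2], 0)
})

test_that("row permutation leaves eigenvalues fixed and scores permuted", {
  co <- simulate_cohort(mini_ref, n_per_species = 8, seed = 6)
  typ <- build_typical_reference(co)
  all_ind <- rbind(co[names(typ$individuals)], typ$individuals)
  fit1 <- chelal_ordination(all_ind)
  perm <- sample(nrow(all_ind))
  fit2 <- chelal_ordination(all_ind[perm, ])
  expect_equal(fit2$eigenvalues, fit1$eigenvalues, tolerance = 1e-8)
  expect_equal(fit2$scores[, 1:2], fit1$scores[perm, 1:2], tolerance = 1e-6)
})

test_that("polar conversion follows the compass convention", {
  fake <- structure(list(scores = rbind(c(0, 1), c(1, 0), c(0, -2),
                                        c(-3, 0)),
                         species = c("N", "E", "S", "W")),
                    class = "chelal_ordination")
  ps <- polar_summary(fake)
  expect_equal(ps$angle_deg[match(c("N", "E", "S", "W"), ps$species_code)],
               c(0, 90, 180, 270))
  expect_equal(ps$distance[match(c("N", "E", "S", "W"), ps$species_code)],
               c(1, 1, 2, 3))
  # zero distance flags an undefined angle
  fake0 <- structure(list(scores = rbind(c(0, 0)), species = "O"),
                     class = "chelal_ordination")
  expect_true(is.na(polar_summary(fake0)$angle_deg))
  expect_error(polar_summary(fake, species_code = "missing"), "unknown")
})

test_that("the typical pseudo-species anchors the origin", {
  pp <- run_pipeline(seed = 4)
  ps <- pp$polar
  d_typ <- ps$distance[ps$species_code == "Typical"]
  expect_lt(d_typ, 0.1 * median(ps$distance[ps$species_code != "Typical"]))
})

test_that("group contrasts behave at the degenerate and published extremes", {
  pp <- run_pipeline(seed = 5)
  omn <- meta_tab$species_code[meta_tab$published_group == "omnivore"]
  fra <- meta_tab$species_code[meta_tab$published_group == "fragmentary"]
  gc <- group_contrast(pp$ordination, omn, fra, B = 199, seed = 5)
  expect_lt(gc$mww$p_randomization, 0.01)
  expect_lt(gc$watson$p_asymptotic, 0.01)
  expect_gt(gc$distance$p, 0)
  expect_error(group_contrast(pp$ordination, "KL", fra), "at least 2")
  expect_error(group_contrast(pp$ordination, omn, omn), "disjoint")
})

test_that("new individuals of a known species score beside their cohort", {
  pp <- run_pipeline(seed = 7)
  fit <- pp$ordination
  newd <- pp$cohort[pp$cohort$species_code == "KL", ][1:5, ]
  sc <- predict(fit, newd)
  in_fit <- fit$scores[fit$species == "KL", 1:2]
  expect_equal(dim(sc), c(5L, ncol(fit$scores)))
  expect_lt(sqrt(sum((colMeans(sc[, 1:2]) - colMeans(in_fit))^2)),
            2 * sd(in_fit[, 1]) + 2 * sd(in_fit[, 2]) + 1)
  expect_error(predict(fit, transform(newd, species_code = "nope")),
               "no summary")
})
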