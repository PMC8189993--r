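test_that("the eight-descriptor coder reproduces every transcribed label", {
  cls <- classify_species(ref_tab)
  m <- merge(cls, meta_tab, by = "species_code")
  expect_equal(nrow(m), 48L)
  slots <- rbind(c("size", "t6_size"), c("reach", "t6_reach"),
                 c("rel_reach", "t6_rel_reach"),
                 c("hardness", "t6_hardness"), c("grip", "t6_grip"),
                 c("food_size", "t6_food_size"), c("grab", "t6_grab"),
                 c("stuffing", "t6_stuffing"))
  for (i in seq_len(nrow(slots))) {
    expect_identical(m[[slots[i, 1]]], m[[slots[i, 2]]],
                     label = paste("descriptor", slots[i, 1]))
  }
})

test_that("published worked examples of the trophic coder hold", {
  ca4 <- trophic_code(ref_tab[ref_tab$species_code == "Ca4", ], typical_row)
  expect_equal(unname(ca4$labels),
               c("Small", "Short distance", "Close to", "Soft",
                 "Feeble effort", "Small food", "Major grab",
                 "Well stuffed"))
  kl <- trophic_code(ref_tab[ref_tab$species_code == "KL", ], typical_row)
  expect_equal(unname(kl$labels[c("size", "reach", "hardness", "grip")]),
               c("Large", "Long Range", "Hard", "Powerful grip"))
  # the typical row against itself ties everywhere, hence all -1
  ty <- trophic_code(typical_row, typical_row)
  expect_true(all(ty$signs == -1L))
})

test_that("four-box models place published examples and respect ties", {
  kl <- ref_tab[ref_tab$species_code == "KL", ]
  fb <- four_box(kl, typical_row, c("IL", "CLI"))
  expect_equal(fb$quadrant, "high-high")
  expect_match(fb$semantics, "crevice feeding/excavating")
  d5 <- ref_tab[ref_tab$species_code == "D5", ]
  expect_equal(four_box(d5, typical_row, c("L2M", "F2AV"))$quadrant,
               "low-low")
  at_cut <- typical_row
  expect_equal(four_box(at_cut, typical_row, c("L2M", "F2AV"))$quadrant,
               "low-low")
  expect_error(four_box(kl, typical_row, c("IL", "L1U")), "unknown")
})

test_that("rule-derived functional groups reproduce the published partition", {
  cls <- classify_species(ref_tab)
  cls <- cls[cls$species_code != "Typical", ]
  tab <- table(cls$group)
  expect_equal(as.integer(tab[c("omnivore_type1", "fragmentary_type2",
                                "small_omnivore", "specialist")]),
               c(10L, 20L, 5L, 12L))
  m <- merge(cls, meta_tab, by = "species_code")
  expect_identical(m$group, m$fig23_group)
  # published example species
  expect_equal(cls$group[toupper(cls$species_code) == "A10B"],
               "omnivore_type1")
  expect_equal(cls$group[cls$species_code == "G3"], "small_omnivore")
  expect_equal(cls$group[cls$species_code == "D4"], "specialist")
  expect_equal(cls$specialist_label[cls$species_code == "D4"],
               "wide-mouthed durophage")
  # surface/interstitial from the size descriptor alone gives the 20/27 split
  expect_identical(m$habit, m$published_habit)
})

test_that("verbal summaries carry the published tokens", {
  cls <- classify_species(ref_tab)
  m <- merge(cls[cls$species_code != "Typical", ],
             meta_tab, by = "species_code")
  expect_identical(m$class_token, m$t7_class)
  expect_identical(m$habit, m$t7_habit)
  expect_identical(m$foraging, m$t7_foraging)
  a15 <- m[m$species_code == "A15", ]
  expect_match(a15$summary_text, "Macro-saprophages", fixed = TRUE)
  expect_match(a15$summary_text, "Wide-mouthed burrower", fixed = TRUE)
  th3 <- m[m$species_code == "TH3", ]
  expect_match(th3$summary_text, "Micro-saprophages", fixed = TRUE)
  ty <- cls[cls$species_code == "Typical", ]
  expect_match(ty$summary_text, "Fragmentary feeders", fixed = TRUE)
})

test_that("cross-suborder banding follows the published thresholds", {
  d5 <- cross_suborder_band(0.715, 43.11)
  expect_equal(d5$speed_band, "primary-decomposer-like")
  ca4 <- cross_suborder_band(0.355, 32.51)
  expect_equal(ca4$toughness, 0.355 * 32.51^2, tolerance = 1e-10)
  expect_lt(ca4$toughness, 1039)
  expect_equal(ca4$toughness_band, "fragmentary/hypocarnivore band")
  expect_false(ca4$pest_range)
  # exact boundary values band low (global tie rule)
  expect_equal(cross_suborder_band(1039, 1)$toughness_band,
               "fragmentary/hypocarnivore band")
  expect_equal(cross_suborder_band(0.5, 1)$speed_band,
               "crushing fungal/fragmentary")
  expect_error(cross_suborder_band(-1, 10), "positive")
})

test_that("coding is invariant to representation-preserving table changes", {
  shuffled <- ref_tab[sample(nrow(ref_tab)), ]
  a <- classify_species(ref_tab)
  b <- classify_species(shuffled)
  b <- b[match(a$species_code, b$species_code), ]
  rownames(b) <- NULL
  expect_equal(a, b)
})
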