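#' Score a field sample on the published two-component nomogram
#'
#' Each individual's six measures are divergence-transformed with the
#' sample's own mean and SD as the species parameters against the packaged
#' typical reference constants, then combined with the fixed published
#' weights:
#' \deqn{Score1 = (0.525\,lbf_{IL} + 0.889\,lbf_{L1U} + 0.927\,lbf_{L2M} +
#'   0.954\,lbf_{CHI} + 0.906\,lbf_{CLI} + 0.925\,lbf_{F2AV})/\sqrt{5.48}}
#' \deqn{Score2 = (-0.796\,lbf_{IL} + 0.333\,lbf_{L1U} + 0.010\,lbf_{L2M} +
#'   0.104\,lbf_{CHI} - 0.200\,lbf_{CLI} + 0.216\,lbf_{F2AV})/\sqrt{1.81}}
#' The weights and the eigenvalue normalisers 5.48 / 1.81 are constants of
#' the original fit (see [chelal_constants()]) and are never re-derived from
#' data.  A sample statistically identical to the typical reference maps to
#' (0, 0).  Both the per-individual points and their sample mean are
#' returned; samples of fewer than 10 individuals get a warning (the sample
#' SD entering the divergence is then poorly estimated), and a single
#' specimen is an error -- use [nearest_species()] instead.
#'
#' @param sample Per-individual data frame with columns `IL`, `L1U`, `L2M`,
#'   `CHI`, `CLI` and optionally `F2AV` (computed from the primaries when
#'   absent).
#' @return List with `individuals` (per-individual Score1/Score2 and lbf
#'   contributions), `mean` (the sample-mean point), and the sample summary
#'   used.
#' @export
nomogram_scores <- function(sample) {
  if (nrow(sample) < 2) {
    stop("nomogram scoring needs n >= 2 (sample SDs); ",
         "use nearest_species() for a single specimen")
  }
  if (nrow(sample) < 10) {
    warning("small sample (n < 10): the sample SD entering the divergence ",
            "is poorly estimated")
  }
  if (!"F2AV" %in% names(sample)) {
    sample$F2AV <- chelal_forces(sample)$F2AV
  }
  meas <- .const$measures
  mu <- vapply(meas, function(m) mean(sample[[m]]), numeric(1))
  sg <- vapply(meas, function(m) stats::sd(sample[[m]]), numeric(1))
  if (any(sg <= 0)) {
    stop("zero sample SD for: ", paste(meas[sg <= 0], collapse = ", "))
  }
  L <- vapply(meas, function(m) {
    lbf(sample[[m]], mu[[m]], sg[[m]],
        .const$typical_mean[[m]], .const$typical_sd[[m]], label = m)
  }, numeric(nrow(sample)))
  L <- matrix(L, nrow = nrow(sample),
              dimnames = list(NULL, paste0("lbf_", meas)))
  s1 <- drop(L %*% .const$score1_weights) / sqrt(.const$score_normalisers[1])
  s2 <- drop(L %*% .const$score2_weights) / sqrt(.const$score_normalisers[2])
  list(individuals = data.frame(Score1 = s1, Score2 = s2, L),
       mean = c(Score1 = mean(s1), Score2 = mean(s2)),
       sample_mean = mu, sample_sd = sg)
}

#' Nearest reference species by raw Euclidean distance
#'
#' The published single-specimen matching rule: the distance from a
#' specimen's six measures to each reference species' printed means,
#' \deqn{d_j = \sqrt{\sum_{k=1}^{6} (x_k - \mu_{j,k})^2},}
#' mixing um and um^2 scales exactly as printed (so the crunch force
#' dominates by construction; a standardised variant, clearly non-canonical,
#' divides each coordinate by the reference column SD of species means
#' first).  `F2AV` is computed from the primaries when not supplied.
#'
#' @param x Named vector or one-row data frame with `IL`, `L1U`, `L2M`,
#'   `CHI`, `CLI` and optionally `F2AV`.
#' @param reference Reference summary table; the "Typical" row is excluded
#'   from matching.
#' @param standardised Use the non-canonical standardised variant?
#' @return Data frame ranked by distance: `species_code`, `distance`.
#' @export
nearest_species <- function(x, reference = load_reference_summaries(),
                            standardised = FALSE) {
  x <- as.list(x)
  if (is.null(x$F2AV)) {
    x$F2AV <- chelal_forces(as.data.frame(x[c("IL", "L1U", "L2M",
                                              "CHI", "CLI")]))$F2AV
  }
  meas <- .const$measures
  sp <- reference[reference$species_code != "Typical", ]
  M <- as.matrix(sp[paste0(meas, "_mean")])
  v <- unlist(x[meas])
  if (standardised) {
    s <- apply(M, 2, stats::sd)
    D <- sqrt(colSums((t(M) / s - v / s)^2))
  } else {
    D <- sqrt(colSums((t(M) - v)^2))
  }
  out <- data.frame(species_code = sp$species_code, distance = unname(D))
  out[order(out$distance), , drop = FALSE]
}

#' Sign-code lookup match of a specimen
#'
#' The high-throughput screening rule: each available measure is scored +1 if
#' above the typical reference mean, else -1 (ties down), and the resulting
#' code string is matched against the reference species' codes (themselves
#' derived from the reference means by the same rule).  An exact unique match
#' wins; otherwise the match distance is the count of mismatching available
#' slots (a Manhattan-style distance), and all co-minimal species are
#' reported as ties.  Missing measures are simply dropped from the
#' comparison, so the procedure tolerates partial data.
#'
#' @param x Named vector/list of any subset of `IL`, `L1U`, `L2M`, `CHI`,
#'   `CLI`, `F2AV`.
#' @param reference Reference summary table.
#' @return List with `code` (the specimen's +-1 code over available slots),
#'   `matches` (data frame of all species with mismatch counts, ranked) and
#'   `best` (codes of the co-minimal species).
#' @export
sign_code_lookup <- function(x, reference = load_reference_summaries()) {
  x <- as.list(x)
  meas <- intersect(.const$measures, names(x)[!vapply(x, is.null, logical(1))])
  meas <- meas[vapply(x[meas], function(v) is.finite(v), logical(1))]
  if (!length(meas)) stop("at least one measure must be present")
  code <- vapply(meas, function(m) {
    if (x[[m]] > .const$typical_mean[[m]]) 1L else -1L
  }, integer(1))
  sp <- reference[reference$species_code != "Typical", ]
  ref_codes <- vapply(meas, function(m) {
    ifelse(sp[[paste0(m, "_mean")]] > .const$typical_mean[[m]], 1L, -1L)
  }, integer(nrow(sp)))
  ref_codes <- matrix(ref_codes, nrow = nrow(sp),
                      dimnames = list(sp$species_code, meas))
  mism <- rowSums(ref_codes != matrix(code, nrow(sp), length(meas),
                                      byrow = TRUE))
  matches <- data.frame(species_code = sp$species_code,
                        mismatches = unname(mism))
  matches <- matches[order(matches$mismatches, matches$species_code), ]
  rownames(matches) <- NULL
  list(code = code, matches = matches,
       best = matches$species_code[matches$mismatches == min(mism)])
}

#' Full field-prediction workflow for a sample of unknown mites
#'
#' Implements the published five-step field procedure: summarise the sample,
#' divergence-transform it, place it on the nomogram (per individual and as
#' a sample mean), find the nearest reference species (Euclidean on the
#' sample-mean specimen, plus the sign-code lookup), and attach the matched
#' species' functional-group classification and verbal narrative.  A
#' single-specimen sample skips the nomogram and reports the Euclidean
#' route, saying so.
#'
#' @param sample Per-individual data frame (`IL`, `L1U`, `L2M`, `CHI`,
#'   `CLI`; `F2AV` computed when absent).
#' @param reference Reference summary table.
#' @param top How many Euclidean matches to report.
#' @return A list report: `n`, `method`, `nomogram` (or NULL), `euclidean`
#'   (top matches), `sign_code`, `classification` of the best match, and
#'   `notes`.
#' @export
field_predict <- function(sample, reference = load_reference_summaries(),
                          top = 3) {
  if (!"F2AV" %in% names(sample)) {
    sample$F2AV <- chelal_forces(sample)$F2AV
  }
  meas <- .const$measures
  mu <- vapply(meas, function(m) mean(sample[[m]]), numeric(1))
  n <- nrow(sample)
  notes <- character(0)
  nom <- NULL
  if (n >= 2) {
    nom <- suppressWarnings(nomogram_scores(sample))
    if (n < 10) notes <- c(notes, "small sample: nomogram SDs poorly estimated")
    method <- "nomogram + euclidean"
  } else {
    notes <- c(notes,
               "single specimen: nomogram skipped, d_j nearest-species route used")
    method <- "euclidean (single specimen)"
  }
  eu <- nearest_species(mu, reference)
  sc <- sign_code_lookup(as.list(mu), reference)
  best <- eu$species_code[1]
  bs <- reference[reference$species_code == best, ]
  code <- trophic_code(bs, reference[reference$species_code == "Typical", ])
  grp <- functional_group(code)
  list(n = n, method = method, nomogram = nom,
       euclidean = utils::head(eu, top), sign_code = sc,
       best_match = best,
       classification = list(group = grp, narrative = verbal_summary(code, grp)),
       notes = notes)
}

#' Run the full synthetic pipeline end to end
#'
#' Convenience driver wiring the stages together under one seed: simulate a
#' cohort from the packaged reference, build the typical set, fit the
#' ordination, classify every species, and summarise the polar positions.
#'
#' @param seed Integer seed.
#' @param n_per_species Individuals per species.
#' @param indicators Include species indicators in the ordination.
#' @return List with `cohort`, `typical`, `ordination`, `classification`,
#'   `polar` and the `config` used.
#' @export
run_pipeline <- function(seed = 1, n_per_species = 20, indicators = TRUE) {
  ref <- load_reference_summaries()
  cohort <- simulate_cohort(ref, n_per_species = n_per_species, seed = seed)
  typ <- build_typical_reference(cohort)
  all_ind <- rbind(cohort[names(typ$individuals)], typ$individuals)
  ord <- chelal_ordination(all_ind, indicators = indicators)
  list(cohort = cohort, typical = typ, ordination = ord,
       classification = classify_species(ref),
       polar = polar_summary(ord),
       config = list(seed = seed, n_per_species = n_per_species,
                     indicators = indicators))
}
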