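#' Simulate per-species cohorts of individual mites
#'
#' Draws `n_per_species` individuals for every species row of a summary table
#' (excluding any "Typical" row), each primary measure independently Normal at
#' the species' stored mean and SD by default; an optional 5x5 cross-measure
#' correlation matrix (order IL, L1U, L2M, CHI, CLI) induces within-species
#' covariance via its Cholesky factor.  Draws violating positivity or the
#' pennate-space condition `CLI > 1.1 * L2M` are rejected and redrawn
#' (truncation by redraw preserves approximate Normality near the
#' boundaries); more than 100 consecutive rejections for one individual is an
#' error naming the species.  Each individual's crunch force `F2AV` is then
#' computed from its own five primaries via [chelal_forces()], so the
#' generator and the force model stay consistent.
#'
#' A single global seed drives everything; each species gets a
#' deterministically derived substream so adding or removing a species leaves
#' the other cohorts untouched.
#'
#' @param summaries Reference summary table ([load_reference_summaries()]).
#' @param n_per_species Individuals per species (>= 2); the reference study
#'   used 20 adult females.
#' @param seed Integer seed.
#' @param correlation Optional 5x5 correlation matrix over the primary
#'   measures; identity (independence) by default.
#' @return A data frame of individuals: `species_code`, `individual_id`, the
#'   five primaries, and the derived mechanics columns.  Attributes `seed`,
#'   `n_per_species` record the provenance.
#' @export
simulate_cohort <- function(summaries, n_per_species = 20, seed = 1,
                            correlation = NULL) {
  if (n_per_species < 2) stop("n_per_species must be >= 2")
  prim <- c("IL", "L1U", "L2M", "CHI", "CLI")
  if (is.null(correlation)) correlation <- diag(5)
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation), tolerance = 1e-8)) ||
      any(abs(diag(correlation) - 1) > 1e-8)) {
    stop("correlation must be symmetric with unit diagonal")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation matrix is not positive semi-definite")
  L <- chol(correlation + diag(5) * max(0, -min(ev) + 1e-12))

  sp <- summaries[summaries$species_code != "Typical", ]
  out <- vector("list", nrow(sp))
  for (j in seq_len(nrow(sp))) {
    mu <- c(sp$IL_mean[j], sp$L1U_mean[j], sp$L2M_mean[j],
            sp$CHI_mean[j], sp$CLI_mean[j])
    sg <- c(sp$IL_sd[j], sp$L1U_sd[j], sp$L2M_sd[j],
            sp$CHI_sd[j], sp$CLI_sd[j])
    set.seed(((seed %% 1000003L) * 1009L + j) %% .Machine$integer.max)
    x <- matrix(NA_real_, n_per_species, 5)
    for (i in seq_len(n_per_species)) {
      ok <- FALSE
      for (tries in seq_len(100L)) {
        z <- drop(crossprod(L, stats::rnorm(5)))
        cand <- mu + sg * z
        if (all(cand > 0) && cand[5] > 1.1 * cand[3]) { ok <- TRUE; break }
      }
      if (!ok) {
        stop("could not draw a valid individual for species ",
             sp$species_code[j], " after 100 attempts")
      }
      x[i, ] <- cand
    }
    df <- data.frame(species_code = sp$species_code[j],
                     individual_id = seq_len(n_per_species))
    df[prim] <- x
    out[[j]] <- df
  }
  cohort <- do.call(rbind, out)
  cohort <- cbind(cohort, chelal_forces(cohort))
  rownames(cohort) <- NULL
  attr(cohort, "seed") <- seed
  attr(cohort, "n_per_species") <- n_per_species
  cohort
}

#' Construct the synthetic typical reference set from a cohort
#'
#' The i-th typical individual's primary measure k is the mean over all
#' species of the i-th individual's measure k, so the typical set is a
#' compact central 'anchor' whose spread is the between-draw variance of a
#' 47-species average.  Its crunch force is computed from its own averaged
#' primaries (matching the published typical constants, which sit below the
#' column mean of the species crunch-force summaries because of the
#' per-species averaging gap).
#'
#' @param cohort Result of [simulate_cohort()]; every species must have the
#'   same number of individuals.
#' @return A list with `individuals` (the typical records, species_code
#'   "Typical") and `summary` (a one-row summary table in the reference
#'   dialect, SDs with divisor n - 1).
#' @export
build_typical_reference <- function(cohort) {
  prim <- c("IL", "L1U", "L2M", "CHI", "CLI")
  ns <- table(cohort$species_code)
  if (length(unique(as.integer(ns))) != 1L) {
    stop("all species must have equal numbers of individuals")
  }
  n <- as.integer(ns[1])
  typ <- data.frame(species_code = "Typical", individual_id = seq_len(n))
  for (m in prim) {
    typ[[m]] <- as.numeric(
      tapply(cohort[[m]], cohort$individual_id, mean)[as.character(seq_len(n))])
  }
  typ <- cbind(typ, chelal_forces(typ))
  rownames(typ) <- NULL
  s <- data.frame(species_code = "Typical", binomial = "Typical reference mite",
                  n = n)
  for (m in c("IL", "CLI", "L2M", "VR", "F2AV", "CHI", "L1U")) {
    s[[paste0(m, "_mean")]] <- mean(typ[[m]])
    s[[paste0(m, "_sd")]] <- stats::sd(typ[[m]])
  }
  list(individuals = typ, summary = s)
}

#' Summarise a cohort to per-species means and SDs
#'
#' @param cohort A per-individual table with `species_code` and the measure
#'   columns (as produced by [simulate_cohort()]).
#' @return A summary table in the reference dialect (mean and n - 1 sample SD
#'   for IL, CLI, L2M, VR, F2AV, CHI, L1U).
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0L) stop("cohort is empty")
  codes <- unique(cohort$species_code)
  meas <- c("IL", "CLI", "L2M", "VR", "F2AV", "CHI", "L1U")
  out <- lapply(codes, function(cc) {
    g <- cohort[cohort$species_code == cc, ]
    s <- data.frame(species_code = cc, binomial = cc, n = nrow(g))
    for (m in meas) {
      s[[paste0(m, "_mean")]] <- mean(g[[m]])
      s[[paste0(m, "_sd")]] <- stats::sd(g[[m]])
    }
    s
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
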