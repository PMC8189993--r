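#' Chelal lever-mechanics force estimates
#'
#' Static rigid-lever model of the astigmatid cheliceral chela.  For each
#' individual record the adductive-tendon force is estimated twice, under a
#' pennate muscle topology filling the shaft behind the moveable digit,
#' \deqn{F1P = (CHI/2)\,(CLI - 1.1\,L2M),}
#' and under a radial (circular cross-section) topology,
#' \deqn{F1C = \pi (CHI/2)^2.}
#' Both are rectified into crunch forces at the digit tips by the chelal
#' velocity ratio \eqn{VR = L1U/L2M} (the mechanical advantage of a
#' frictionless lever), and the consensus crunch force is their mean,
#' \eqn{F2AV = (F2P + F2C)/2}.  The 1.1 condyle inflation factor and the
#' half-shaft muscle fraction are exposed as arguments but default to the
#' reference values.  `toughness` is \eqn{VR \times CHI^2}, the cross-study
#' food-toughness surrogate used on the comparative oribatid axes (note it
#' squares the full shaft height, unlike `F1C`).
#'
#' Units: inputs in micrometres; all forces are force surrogates in um^2.
#'
#' @param rec Data frame with columns `IL`, `L1U`, `L2M`, `CHI`, `CLI`
#'   (micrometres), one row per individual.  Extra columns are ignored.
#' @param inflation Condyle inflation factor applied to `L2M` in the pennate
#'   estimate.
#' @param shaft_fraction Fraction of `CHI` available to the adductor muscle.
#' @return A data frame with columns `VR`, `F1P`, `F1C`, `F2P`, `F2C`,
#'   `F2AV`, `toughness`, one row per input row.
#' @examples
#' typ <- data.frame(IL = 216.42, L1U = 12.66, L2M = 26.45,
#'                   CHI = 51.59, CLI = 98.17)
#' chelal_forces(typ)  # F2AV approx 926.7 um^2
#' @export
chelal_forces <- function(rec, inflation = 1.1, shaft_fraction = 0.5) {
  need <- c("IL", "L1U", "L2M", "CHI", "CLI")
  missing_cols <- setdiff(need, names(rec))
  if (length(missing_cols)) {
    stop("measurement record lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  m <- rec[need]
  bad <- which(apply(m, 1, function(r) any(!is.finite(r) | r <= 0)))
  if (length(bad)) {
    stop("non-positive measurement in row(s) ", paste(bad, collapse = ", "))
  }
  pen <- rec$CLI - inflation * rec$L2M
  if (any(pen <= 0)) {
    stop("pennate muscle space non-positive (CLI <= ", inflation,
         " * L2M) in row(s) ", paste(which(pen <= 0), collapse = ", "))
  }
  h <- shaft_fraction * rec$CHI
  VR <- rec$L1U / rec$L2M
  F1P <- h * pen
  F1C <- pi * h^2
  F2P <- F1P * VR
  F2C <- F1C * VR
  data.frame(VR = VR, F1P = F1P, F1C = F1C, F2P = F2P, F2C = F2C,
             F2AV = (F2P + F2C) / 2, toughness = VR * rec$CHI^2)
}

#' Dimensionless design ratios of an individual record
#'
#' Relative sizing is done by simple arithmetic division at the level of each
#' individual specimen: reach over size (`CLI/IL`), gape over size
#' (`L2M/IL`), gape over reach (`L2M/CLI`, the oral-stuffing axis), cheliceral
#' aspect ratio (`CHI/CLI`), relative crunch force (`F2AV/IL`), the classic
#' fixed-digit over moveable-digit ratio fd/md (`CLI/L2M`) and the relative
#' input lever (`L1U/CHI`).  All are invariant to a common rescaling of the
#' linear measures except `rel_crunch`, which carries units of um (force
#' surrogate over length) and scales linearly.
#'
#' @param rec As for [chelal_forces()].
#' @param forces Optional result of [chelal_forces()] on `rec`; computed if
#'   missing.
#' @inheritParams chelal_forces
#' @return Data frame of the seven ratios, one row per input row.
#' @export
derived_ratios <- function(rec, forces = NULL, inflation = 1.1,
                           shaft_fraction = 0.5) {
  if (is.null(forces)) {
    forces <- chelal_forces(rec, inflation = inflation,
                            shaft_fraction = shaft_fraction)
  }
  data.frame(
    reach_over_size = rec$CLI / rec$IL,
    gape_over_size = rec$L2M / rec$IL,
    gape_over_reach = rec$L2M / rec$CLI,
    aspect = rec$CHI / rec$CLI,
    rel_crunch = forces$F2AV / rec$IL,
    fd_over_md = rec$CLI / rec$L2M,
    rel_lever = rec$L1U / rec$CHI
  )
}

#' Append derived mechanics to a per-individual measurement table
#'
#' Batch convenience: reads a table of individuals (columns `species_code`,
#' `individual_id`, `IL`, `L1U`, `L2M`, `CHI`, `CLI`) and appends the force
#' estimates and the seven design ratios.
#'
#' @param rec Per-individual measurement data frame.
#' @inheritParams chelal_forces
#' @return The input with the [chelal_forces()] and [derived_ratios()]
#'   columns appended.
#' @export
augment_mechanics <- function(rec, inflation = 1.1, shaft_fraction = 0.5) {
  f <- chelal_forces(rec, inflation = inflation, shaft_fraction = shaft_fraction)
  cbind(rec, f, derived_ratios(rec, f))
}
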