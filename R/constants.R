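#' Fixed constants of the reference analysis
#'
#' All numeric constants of the published reference fit live here as versioned
#' data rather than as literals scattered through code: the condyle inflation
#' factor of the pennate force model, the typical reference mite's means and
#' SDs, the two-component nomogram weights and their eigenvalue normalisers,
#' and the cross-suborder banding thresholds.  The nomogram weights are
#' constants of the original fit; re-running [chelal_ordination()] on new data
#' produces a new, clearly distinct model and never alters them.
#'
#' @return A named list with elements:
#'   \describe{
#'     \item{condyle_inflation}{1.1, the condyle-position inflation of the
#'       moveable digit inside the cheliceral base.}
#'     \item{shaft_fraction}{0.5, fraction of cheliceral height available to
#'       the adductor in both force estimates.}
#'     \item{typical_mean, typical_sd}{named vectors over the six analysis
#'       measures (IL, L1U, L2M, CHI, CLI, F2AV) for the typical reference
#'       mite, in um (F2AV in um^2).}
#'     \item{score1_weights, score2_weights}{nomogram loading vectors.}
#'     \item{score_normalisers}{the eigenvalue normalisers 5.48 and 1.81.}
#'     \item{toughness_bands, speed_bands, pest_toughness}{cross-suborder
#'       banding thresholds on VR*CHI^2 and on VR.}
#'   }
#' @export
chelal_constants <- function() {
  measures <- c("IL", "L1U", "L2M", "CHI", "CLI", "F2AV")
  list(
    measures = measures,
    condyle_inflation = 1.1,
    shaft_fraction = 0.5,
    typical_mean = c(IL = 216.42, L1U = 12.66, L2M = 26.45,
                     CHI = 51.59, CLI = 98.17, F2AV = 926.53),
    typical_sd = c(IL = 2.995, L1U = 0.238, L2M = 0.239,
                   CHI = 0.621, CLI = 0.689, F2AV = 33.228),
    typical_vr = 0.478,
    score1_weights = c(IL = 0.525, L1U = 0.889, L2M = 0.927,
                       CHI = 0.954, CLI = 0.906, F2AV = 0.925),
    score2_weights = c(IL = -0.796, L1U = 0.333, L2M = 0.010,
                       CHI = 0.104, CLI = -0.200, F2AV = 0.216),
    score_normalisers = c(5.48, 1.81),
    toughness_bands = c(1039.0, 2642.7, 3807.0),
    speed_bands = c(0.276, 0.5, 0.65),
    pest_toughness = 1100.6
  )
}

# Internal shorthand used throughout; evaluated once at load.
.const <- chelal_constants()
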