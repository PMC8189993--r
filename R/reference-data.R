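#' Load the packaged per-species measurement summaries
#'
#' The reference table holds, for each of 47 free-living astigmatid species
#' plus the synthetic "Typical" pseudo-species, the mean and sample SD (n = 20
#' adult females per species) of the idiosomal index `IL`, cheliceral length
#' (reach) `CLI`, moveable-digit length (gape) `L2M`, chelal velocity ratio
#' `VR`, consensus crunch force `F2AV`, cheliceral height `CHI` and chelal
#' input moment arm `L1U`.  Lengths are in micrometres, `F2AV` in um^2, `VR`
#' dimensionless.  Values are stored exactly as published (2 dp); species
#' `F2AV` summaries are per-individual averages and are deliberately not
#' re-derived from the primary-measure means (the per-individual averaging
#' gap makes recomputed values differ by up to ~2%).
#'
#' @param path Optional path to a user CSV in the same dialect (comma
#'   separated, `.` decimal point, header row, same columns).  Defaults to the
#'   packaged table.
#' @return A data frame with one row per species and columns `species_code`,
#'   `binomial`, `n`, and `<measure>_mean` / `<measure>_sd` for the seven
#'   summarised measures.
#' @seealso [validate_reference()], [load_species_metadata()]
#' @export
load_reference_summaries <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_summaries.csv",
                        package = "chelamorph", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("reference summary file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("reference summary file is empty: ", path)

  need <- c("species_code", "n",
            paste0(rep(c("IL", "CLI", "L2M", "VR", "F2AV", "CHI", "L1U"), each = 2),
                   c("_mean", "_sd")))
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop("missing column(s) in reference summaries: ",
         paste(missing_cols, collapse = ", "))
  }
  num <- setdiff(need, "species_code")
  for (cl in num) {
    if (!is.numeric(d[[cl]])) {
      stop("non-numeric value in column '", cl, "' (row ",
           which(!grepl("^\\s*-?[0-9.]+\\s*$", as.character(d[[cl]])))[1], ")")
    }
  }
  dup <- d$species_code[duplicated(d$species_code)]
  if (length(dup)) stop("duplicate species_code: ", paste(dup, collapse = ", "))
  bad <- which(apply(d[num], 1, function(r) any(r <= 0)) | d$n < 2)
  if (length(bad)) {
    stop("non-positive summary or n < 2 in row(s): ",
         paste(d$species_code[bad], collapse = ", "))
  }
  d
}

#' Load the packaged species metadata
#'
#' Taxonomy (superfamily / family / subfamily), the pest flag, the published
#' omnivore/fragmentary and surface/interstitial assignments, the published
#' functional-group label, and the transcribed verbal trophic coding (eight
#' descriptor labels per species) plus the habit / foraging / morsel-class
#' tokens of the standardised verbal summaries.  The published binary
#' omnivore/fragmentary split over the 17 specialists is not rule-derivable
#' and is carried as data for statistics reproduction, never recomputed.
#'
#' @param path Optional path to a user CSV; defaults to the packaged table.
#' @return A data frame keyed by `species_code`.
#' @export
load_species_metadata <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "species_metadata.csv",
                        package = "chelamorph", mustWork = TRUE)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("species metadata file is empty: ", path)
  d$pest <- as.logical(d$pest)
  d
}

#' Load the packaged comparative oribatid/mesostigmatid records
#'
#' Cross-suborder cheliceral records (leverage or velocity ratio, squared
#' cheliceral height `PHI_squared`, their product as a crunch-force surrogate,
#' gape and reach, plus the source study's trophic designation) used for
#' banding astigmatids against oribatid feeding types.  Records are carried
#' verbatim from their sources; rows originating from the radio-isotope study
#' include some whose product column is not leverage x PHI^2 and no
#' reconciliation is attempted.
#'
#' @param path Optional path to a user CSV; defaults to the packaged table.
#' @return A data frame of comparative records.
#' @export
load_comparative_records <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "comparative_oribatids.csv",
                        package = "chelamorph", mustWork = TRUE)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("comparative record file is empty: ", path)
  num <- c("leverage", "PHI_squared", "product", "gape", "reach")
  missing_cols <- setdiff(c("taxon", num, "designation", "source"), names(d))
  if (length(missing_cols)) {
    stop("missing column(s) in comparative records: ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(apply(d[num], 1, function(r) any(!is.finite(r) | r <= 0)))
  if (length(bad)) {
    stop("malformed comparative record row(s): ",
         paste(d$taxon[bad], collapse = ", "))
  }
  d
}

#' Consistency report for a reference summary table
#'
#' The typical pseudo-species is constructed by averaging individuals across
#' the 47 species, so its mean for each directly measured quantity must equal
#' the corresponding column mean of the species rows.  This is checked within
#' an absolute tolerance that absorbs the 2-dp rounding of the stored values.
#' The crunch force is the exception: the typical individuals' `F2AV` is
#' computed from their averaged primary measures, so it is validated by
#' recomputing the crunch force from the primary-measure column means rather
#' than by column-averaging the species `F2AV` summaries (which sit ~6%
#' higher because of the per-species averaging gap).
#'
#' @param summaries A table from [load_reference_summaries()].
#' @param tol Absolute tolerance for the directly averaged measures.
#' @param tol_f2av Absolute tolerance (um^2) for the recomputed crunch force.
#' @return A data frame with one row per measure: the typical value, the
#'   reconstructed value, their absolute difference and a `pass` flag.
#' @export
validate_reference <- function(summaries, tol = 0.02, tol_f2av = 1.0) {
  sp <- summaries[summaries$species_code != "Typical", ]
  ty <- summaries[summaries$species_code == "Typical", ]
  if (nrow(ty) != 1L) stop("summary table must contain exactly one 'Typical' row")

  direct <- c("IL", "CLI", "L2M", "VR", "CHI", "L1U")
  rows <- lapply(direct, function(m) {
    cm <- mean(sp[[paste0(m, "_mean")]])
    tv <- ty[[paste0(m, "_mean")]]
    data.frame(measure = m, typical = tv, reconstructed = cm,
               abs_diff = abs(cm - tv), tolerance = tol,
               pass = abs(cm - tv) <= tol)
  })
  # F2AV: recompute from the primary-measure column means
  f <- chelal_forces(data.frame(
    species_code = "column-means", individual_id = 1L,
    IL = mean(sp$IL_mean), L1U = mean(sp$L1U_mean), L2M = mean(sp$L2M_mean),
    CHI = mean(sp$CHI_mean), CLI = mean(sp$CLI_mean)))
  tv <- ty$F2AV_mean
  rows <- c(rows, list(data.frame(
    measure = "F2AV", typical = tv, reconstructed = f$F2AV,
    abs_diff = abs(f$F2AV - tv), tolerance = tol_f2av,
    pass = abs(f$F2AV - tv) <= tol_f2av)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
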