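#' Encode the eight signed trophic descriptors of a species
#'
#' Each species' summary is scored above (+1) or at-or-below (-1) the typical
#' reference mite on eight trophic axes: size (`IL`), reach (`CLI`), relative
#' reach (`CLI/IL`), food hardness (`F2AV`), grip power (`F2AV/IL`), food
#' size (`L2M`), grab (`L2M/IL`) and oral stuffing (`L2M/CLI`).  Cuts for the
#' plain measures are the typical means; cuts for the ratios are the ratios
#' of the typical means, compared against each species' ratio of means.  Ties
#' code -1 (the typical row itself carries the all-lower labels).  Each sign
#' maps bijectively to the published verbal label (Large/Small, Long
#' Range/Short distance, Well away/Close to, Hard/Soft, Powerful grip/Feeble
#' effort, Big food/Small food, Major grab/Little chunks, Well stuffed/Tiny
#' mouthfulls).
#'
#' @param summary One summary row (the `<measure>_mean` columns are used).
#' @param typical The typical reference row (defaults to the packaged
#'   constants).
#' @return A list with `signs` (named +-1 vector) and `labels` (named
#'   character vector), class `trophic_code`.
#' @export
trophic_code <- function(summary, typical = NULL) {
  tm <- if (is.null(typical)) .const$typical_mean else
    c(IL = typical$IL_mean, L1U = typical$L1U_mean, L2M = typical$L2M_mean,
      CHI = typical$CHI_mean, CLI = typical$CLI_mean, F2AV = typical$F2AV_mean)
  v <- c(IL = summary$IL_mean, CLI = summary$CLI_mean,
         L2M = summary$L2M_mean, F2AV = summary$F2AV_mean)
  x <- c(size = v[["IL"]],
         reach = v[["CLI"]],
         rel_reach = v[["CLI"]] / v[["IL"]],
         hardness = v[["F2AV"]],
         grip = v[["F2AV"]] / v[["IL"]],
         food_size = v[["L2M"]],
         grab = v[["L2M"]] / v[["IL"]],
         stuffing = v[["L2M"]] / v[["CLI"]])
  cut <- c(size = tm[["IL"]],
           reach = tm[["CLI"]],
           rel_reach = tm[["CLI"]] / tm[["IL"]],
           hardness = tm[["F2AV"]],
           grip = tm[["F2AV"]] / tm[["IL"]],
           food_size = tm[["L2M"]],
           grab = tm[["L2M"]] / tm[["IL"]],
           stuffing = tm[["L2M"]] / tm[["CLI"]])
  signs <- ifelse(x > cut, 1L, -1L)
  hi <- c(size = "Large", reach = "Long Range", rel_reach = "Well away",
          hardness = "Hard", grip = "Powerful grip", food_size = "Big food",
          grab = "Major grab", stuffing = "Well stuffed")
  lo <- c(size = "Small", reach = "Short distance", rel_reach = "Close to",
          hardness = "Soft", grip = "Feeble effort", food_size = "Small food",
          grab = "Little chunks", stuffing = "Tiny mouthfulls")
  labels <- ifelse(signs > 0, hi, lo)
  names(labels) <- names(signs) <- names(x)
  structure(list(signs = signs, labels = labels), class = "trophic_code")
}

#' @export
print.trophic_code <- function(x, ...) {
  cat(paste(sprintf("%s=%s", names(x$labels), x$labels), collapse = ", "),
      "\n")
  invisible(x)
}

# valid four-box pairings, as (x axis, y axis)
.four_box_models <- list(
  c("IL", "CLI"), c("L2M", "F2AV"), c("L2M", "CLI"),
  c("L2M", "IL"), c("F2AV", "CLI"), c("IL", "F2AV"))

#' Four-box heuristic model of a species
#'
#' Cross-classifies a species as high/low on two measures against the typical
#' cuts, for one of the six published measure pairings: (IL, CLI) food
#' access, (L2M, F2AV) morsel handling, and the four supplementary pairings
#' (L2M, CLI), (L2M, IL), (F2AV, CLI), (IL, F2AV).  Values exactly at a cut
#' classify low.
#'
#' @param summary,typical As for [trophic_code()].
#' @param model Character vector of the two measures, e.g. `c("L2M",
#'   "F2AV")`.
#' @return A list: the two measures, their high/low flags, the quadrant
#'   (`"low-low"` etc.) and the quadrant's biological reading.
#' @export
four_box <- function(summary, typical = NULL, model = c("IL", "CLI")) {
  ok <- any(vapply(.four_box_models, function(p) all(p == model), logical(1)))
  if (!ok) {
    stop("unknown four-box pairing: ", paste(model, collapse = ","))
  }
  tm <- if (is.null(typical)) .const$typical_mean else
    c(IL = typical$IL_mean, L2M = typical$L2M_mean,
      CLI = typical$CLI_mean, F2AV = typical$F2AV_mean)
  hi <- vapply(model, function(m) summary[[paste0(m, "_mean")]] > tm[[m]],
               logical(1))
  quadrant <- paste(ifelse(hi, "high", "low"), collapse = "-")
  semantics <- switch(paste(model, collapse = ","),
    "IL,CLI" = c("low-low" = "interstitial browsing/gleaning",
                 "high-low" = "surface browsing/gleaning",
                 "low-high" = "interstitial crevice feeding/excavating",
                 "high-high" = "surface-living, potential crevice feeding/excavating")[[quadrant]],
    "L2M,F2AV" = c("low-low" = "fragmentary feeder (small soft morsels)",
                   "high-low" = "macrosaprophage (large but soft morsels)",
                   "low-high" = "microsaprophage (small but hard morsels)",
                   "high-high" = "pan-saprophage (large and hard morsels)")[[quadrant]],
    paste(model[1], ifelse(hi[1], "high", "low"), "/",
          model[2], ifelse(hi[2], "high", "low")))
  list(model = model, high = hi, quadrant = quadrant, semantics = semantics)
}

#' Assign a species to its functional group
#'
#' The morsel class follows the (food size, hardness) signs of the trophic
#' code: both high is a pan-saprophage, big-but-soft a macro-saprophage,
#' small-but-hard a micro-saprophage, both low a fragmentary feeder.  The
#' functional group then follows the published partition rule: large
#' pan-saprophages are Type 1 omnivores; small fragmentary feeders are Type 2
#' fragmentary feeders; small long-reach pan-saprophages are small omnivores;
#' every other combination is a specialist, sub-labelled from its remaining
#' descriptors.  Habit is surface for large species, interstitial for small.
#'
#' @param code A [trophic_code()].
#' @return List with `group`, `morsel_class`, `habit`, `specialist_label`
#'   (NA unless a specialist).
#' @export
functional_group <- function(code) {
  s <- code$signs
  morsel <- if (s[["food_size"]] > 0 && s[["hardness"]] > 0) "pan_saprophage"
  else if (s[["food_size"]] > 0) "macro_saprophage"
  else if (s[["hardness"]] > 0) "micro_saprophage"
  else "fragmentary_feeder"
  large <- s[["size"]] > 0
  long <- s[["reach"]] > 0
  group <- if (large && morsel == "pan_saprophage") "omnivore_type1"
  else if (!large && morsel == "fragmentary_feeder") "fragmentary_type2"
  else if (!large && long && morsel == "pan_saprophage") "small_omnivore"
  else "specialist"
  label <- NA_character_
  if (group == "specialist") {
    label <- switch(morsel,
      pan_saprophage = "wide-mouthed durophage",           # small, short, pan
      macro_saprophage = if (large) "soft-food chunk feeder"
                         else "wide-mouthed burrower",
      micro_saprophage = "hard small-morsel picker",
      fragmentary_feeder = "surface fragmentary variant")  # large, fragmentary
  }
  list(group = group, morsel_class = morsel,
       habit = if (large) "surface" else "interstitial",
       specialist_label = label)
}

#' Standardised verbal summary of a species' trophic design
#'
#' Assembles the published template: a habit sentence (surface-living vs
#' interstitial / potential cavity-living), a foraging clause keyed on reach
#' (crevice feeding/excavating specialist vs substratum browsing/gleaning
#' generalist; "potential" for surface species, "possible" for interstitial
#' ones), the morsel clause with its parenthetical class token
#' (Pan-/Macro-/Micro-saprophages or Fragmentary feeders), and the feeding
#' epithets keyed on habit x class.
#'
#' @param code A [trophic_code()].
#' @param group Optional [functional_group()] result; computed if missing.
#' @return A list with the assembled `text` and its `tokens` (habit,
#'   foraging, class_token, epithets).
#' @export
verbal_summary <- function(code, group = NULL) {
  if (is.null(group)) group <- functional_group(code)
  surface <- group$habit == "surface"
  long <- code$signs[["reach"]] > 0
  habit <- if (surface) "Surface-living"
           else "Interstitial. Potential cavity-living"
  foraging <- if (long) {
    paste0(if (surface) "potential" else "possible",
           " crevice feeding/excavating specialist")
  } else "substratum browsing/gleaning generalist"
  cls <- c(pan_saprophage = "Pan-saprophages",
           macro_saprophage = "Macro-saprophages",
           micro_saprophage = "Micro-saprophages",
           fragmentary_feeder = "Fragmentary feeders")[[group$morsel_class]]
  morsel <- switch(group$morsel_class,
    pan_saprophage = paste0("Potential specialist for large (and small), ",
                            "hard (and soft) food morsels (", cls, ")"),
    macro_saprophage = paste0("Potential specialist for large but must be ",
                              "soft food morsels (", cls, ")"),
    micro_saprophage = paste0("Only small morsels but potential specialist ",
                              "for hard (and soft) food (", cls, ")"),
    fragmentary_feeder = paste0("Only small and soft food morsels (", cls,
                                ")"))
  epithets <- switch(group$morsel_class,
    pan_saprophage = if (surface)
      "Chunk or Demolition feeder, Nutcracker or Cruncher"
      else "Burrowing Cruncher",
    macro_saprophage = if (surface)
      "Chunk or Demolition feeder, Squasher, Soft slicer or 'Plankton' feeder"
      else "Wide-mouthed burrower, Squasher, Soft slicer or 'Plankton' feeder",
    micro_saprophage = "Picker or 'Plankton' feeder, Nutcracker or Cruncher",
    fragmentary_feeder = if (surface)
      "Picker, Squasher, Soft slicer or 'Plankton' feeder"
      else paste0("Burrowing picker, Selective burrower, Squasher, ",
                  "Soft slicer or 'Plankton' feeder"))
  list(text = paste0(habit, ", ", foraging, ". ", morsel, ". ", epithets),
       tokens = list(habit = if (surface) "surface" else "interstitial",
                     foraging = if (long) "specialist" else "generalist",
                     class_token = cls, epithets = epithets))
}

#' Classify every species row of a summary table
#'
#' Batch driver over [trophic_code()], [functional_group()] and
#' [verbal_summary()].
#'
#' @param summaries Reference-style summary table (a "Typical" row, if
#'   present, supplies the cuts and is itself coded too).
#' @param typical Optional explicit typical row.
#' @return Data frame with the eight descriptor labels, the group, morsel
#'   class, habit, specialist label and summary text per species.
#' @export
classify_species <- function(summaries, typical = NULL) {
  if (is.null(typical)) {
    ty <- summaries[summaries$species_code == "Typical", ]
    if (nrow(ty) == 1L) typical <- ty
  }
  rows <- lapply(seq_len(nrow(summaries)), function(i) {
    s <- summaries[i, ]
    code <- trophic_code(s, typical)
    grp <- functional_group(code)
    vs <- verbal_summary(code, grp)
    data.frame(species_code = s$species_code,
               t(code$labels),
               group = grp$group, morsel_class = grp$morsel_class,
               habit = grp$habit, specialist_label = grp$specialist_label,
               class_token = vs$tokens$class_token,
               foraging = vs$tokens$foraging,
               summary_text = vs$text,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-suborder trophic banding of a chelal design
#'
#' Places a design on the comparative oribatid/mesostigmatid axes using the
#' food-toughness surrogate `toughness = VR * CHI^2` and the chelal closing
#' speed surrogate `VR`.  Toughness bands at 1039.0, 2642.7 and 3807.0 um^2
#' separate fragmentary/hypocarnivore-like, microphytophage-like,
#' macrophytophage-like and panphytophage/non-specialised-like designs; speed
#' bands at VR = 0.276, 0.5 and 0.65 separate cutting-carnivore-like,
#' crushing fungal/fragmentary, secondary-decomposer-like and
#' primary-decomposer-like designs.  Values exactly on a boundary band low
#' (the global tie rule).  Designs with toughness at or above 1100.6 um^2
#' fall in the range of the recognised agricultural pest species.
#'
#' @param VR Velocity ratio (or leverage), positive.
#' @param CHI Cheliceral height in micrometres, positive.
#' @return Data frame with `toughness`, `toughness_band`, `speed_band`,
#'   `pest_range` and a combined `label`.
#' @export
cross_suborder_band <- function(VR, CHI) {
  if (any(VR <= 0) || any(CHI <= 0)) stop("VR and CHI must be positive")
  tough <- VR * CHI^2
  tb <- .const$toughness_bands
  sb <- .const$speed_bands
  t_lab <- c("fragmentary/hypocarnivore band", "microphytophage-like band",
             "macrophytophage-like band", "panphytophage-like band")
  s_lab <- c("cutting-carnivore-like", "crushing fungal/fragmentary",
             "secondary-decomposer-like", "primary-decomposer-like")
  ti <- findInterval(tough, tb, left.open = TRUE) + 1L
  si <- findInterval(VR, sb, left.open = TRUE) + 1L
  data.frame(VR = VR, CHI = CHI, toughness = tough,
             toughness_band = t_lab[ti], speed_band = s_lab[si],
             pest_range = tough >= .const$pest_toughness,
             label = paste0(s_lab[si], "; ", t_lab[ti]))
}
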