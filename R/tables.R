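## Published summary tables of the two-mountain (Mt. Kinabalu /
## Mt. Tambuyukon) small-mammal survey, shipped as constructors so the
## reported trap-success and camera-rate figures can be recomputed through
## the package without the capture-level deposit.

#' Published capture and trapping-effort totals per trapping location
#'
#' Captures (`n`) and trap nights for each trapping location on
#' Mt. Kinabalu and Mt. Tambuyukon, both including and excluding
#' arboreal/pitfall trapping. Recaptured animals are not counted.
#'
#' @return data.frame with columns `mountain`, `elevation` (nominal, m),
#'   `n_incl`, `nights_incl` (all trap classes), `n_excl`, `nights_excl`
#'   (ground traps only).
#' @seealso [studySurveyFromTables()], [trapSuccess()]
#' @export
studyEffortTable <- function() {
  data.frame(
    mountain = rep(c("Kinabalu", "Tambuyukon"), each = 6),
    elevation = c(500, 900, 1500, 2200, 2700, 3200,
                  500, 900, 1300, 1600, 2000, 2400),
    n_incl = c(33, 20, 36, 35, 60, 29,
               78, 24, 53, 22, 55, 67),
    nights_incl = c(300, 360, 360, 434, 390, 200,
                    1713, 992, 712, 1036, 1036, 698),
    n_excl = c(30, 20, 36, 34, 60, 29,
               75, 24, 52, 22, 55, 67),
    nights_excl = c(285, 360, 360, 427, 390, 200,
                    1588, 956, 702, 1025, 988, 698),
    stringsAsFactors = FALSE)
}

#' Published camera-trap series counts on Mt. Tambuyukon
#'
#' Independent visit series per species for the trail cameras with a known
#' number of camera nights (camera 3's night total was not reported and is
#' omitted). The camera-2 denominator is ambiguous in the published summary;
#' its recomputed rates should not be treated as ground truth.
#'
#' @return data.frame with `camera_id`, `elevation`, `common_name`,
#'   `species`, `n_series`, `camera_nights`.
#' @seealso [cameraRelativeAbundance()]
#' @export
studyCameraTable <- function() {
  data.frame(
    camera_id = c(1, 1, 1, 1, 1, 2, 2, 4, 4),
    elevation = c(500, 500, 500, 500, 500, 900, 900, 1300, 1300),
    common_name = c("Pig-tailed Macaque", "Common Porcupine", "Mouse Deer",
                    "Muntjac", "Sambar Deer", "Malay Civet",
                    "Banded Linsang", "Malay Civet", "Masked Palm Civet"),
    species = c("Macaca nemestrina", "Hystrix brachyura", "Tragulus sp.",
                "Muntiacus sp.", "Rusa unicolor", "Viverra tangalunga",
                "Prionodon linsang", "Viverra tangalunga", "Paguma larvata"),
    n_series = c(1, 2, 2, 1, 1, 2, 1, 1, 1),
    camera_nights = c(42, 42, 42, 42, 42, 42, 42, 29, 29),
    stringsAsFactors = FALSE)
}

#' Reconstruct a SurveyDataset from the published effort totals
#'
#' Expands the per-location capture/effort totals of [studyEffortTable()]
#' into a minimal [SurveyDataset-class]: `n_excl` ground records plus
#' `n_incl - n_excl` non-ground records per location (labelled arboreal —
#' the published totals only distinguish ground from arboreal+pitfall), with
#' matching ground and non-ground trap-night rows. Species identities are
#' not part of the published totals, so all records carry a placeholder
#' label; the object supports effort accounting ([trapSuccess()],
#' [filterRecords()]) but not diversity analyses.
#'
#' @return a [SurveyDataset-class].
#' @examples
#' ds <- studySurveyFromTables()
#' trapSuccess(filterRecords(ds), groupBy = "mountain")
#' @export
studySurveyFromTables <- function() {
  tab <- studyEffortTable()
  rec_list <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    n_nonground <- r$n_incl - r$n_excl
    data.frame(
      species = "unidentified sp.",
      mountain = r$mountain,
      location = as.character(r$elevation),
      elevation = r$elevation,
      trap_class = rep(c("ground", "arboreal"), c(r$n_excl, n_nonground)),
      recapture = FALSE,
      stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rec_list)
  eff <- rbind(
    data.frame(mountain = tab$mountain, location = as.character(tab$elevation),
               trap_class = "ground", trap_nights = tab$nights_excl),
    data.frame(mountain = tab$mountain, location = as.character(tab$elevation),
               trap_class = "arboreal",
               trap_nights = tab$nights_incl - tab$nights_excl))
  eff <- eff[eff$trap_nights > 0 | eff$trap_class == "ground", , drop = FALSE]
  suppressWarnings(
    surveyDataset(rec, eff,
                  meta = data.frame(species = "unidentified sp.",
                                    endemic = "unknown",
                                    notes = "published totals only"),
                  provenance = "reconstructed from published effort totals"))
}
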