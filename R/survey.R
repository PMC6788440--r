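## Reading, validating, filtering and aggregating trap-survey data.

## round-half-up, the rounding used in the printed tables (base round() is
## round-half-even)
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Construct a SurveyDataset from data frames
#'
#' Assembles and validates a [SurveyDataset-class]. Species appearing in
#' `records` but absent from `meta` are added with endemic status
#' `"unknown"`, with a warning. `capture_day` and `record_id` are filled
#' when missing.
#'
#' @param records data.frame with columns `species`, `mountain`, `location`,
#'   `elevation`, `trap_class`; optional `record_id`, `recapture`,
#'   `capture_day`.
#' @param efforts data.frame with `mountain`, `location`, `trap_class`,
#'   `trap_nights`; may be empty.
#' @param meta data.frame with `species`, `endemic`; may be empty.
#' @param provenance character, initial provenance entries.
#' @return a validated [SurveyDataset-class].
#' @export
surveyDataset <- function(records, efforts = NULL, meta = NULL,
                          provenance = "constructed from data frames") {
  records <- as.data.frame(records)
  need <- c("species", "mountain", "location", "elevation", "trap_class")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(records$record_id))
    records$record_id <- sprintf("r%05d", seq_len(nrow(records)))
  if (is.null(records$recapture)) records$recapture <- FALSE
  if (is.null(records$capture_day)) records$capture_day <- NA_integer_
  records$species <- as.character(records$species)
  records$mountain <- as.character(records$mountain)
  records$location <- as.character(records$location)
  records$trap_class <- as.character(records$trap_class)
  records$recapture <- as.logical(records$recapture)
  records$capture_day <- as.integer(records$capture_day)
  if (any(!is.finite(records$elevation)) || any(records$elevation <= 0))
    stop("records: elevation must be finite and > 0", call. = FALSE)

  if (is.null(efforts))
    efforts <- data.frame(mountain = character(), location = character(),
                          trap_class = character(), trap_nights = integer())
  efforts <- as.data.frame(efforts)
  if (nrow(efforts) && any(efforts$trap_nights < 0))
    stop("efforts: trap_nights must be >= 0", call. = FALSE)

  if (is.null(meta))
    meta <- data.frame(species = character(), endemic = character(),
                       notes = character())
  meta <- as.data.frame(meta)
  if (is.null(meta$notes)) meta$notes <- rep("", nrow(meta))
  unknown <- setdiff(unique(records$species), meta$species)
  if (length(unknown)) {
    warning("species without metadata set to endemic = 'unknown': ",
            paste(unknown, collapse = ", "), call. = FALSE)
    meta <- rbind(meta,
                  data.frame(species = unknown, endemic = "unknown",
                             notes = "auto-added"))
  }
  new("SurveyDataset", records = records, efforts = efforts, meta = meta,
      provenance = provenance)
}

#' Read a trap survey from delimited text files
#'
#' Loads capture records, trap-night totals and species metadata from
#' CSV/TSV files into a validated [SurveyDataset-class]. The records file
#' must carry columns `species`, `mountain`, `location`, `elevation`,
#' `trap_class` (`ground`/`arboreal`/`pitfall`); optional `record_id`,
#' `recapture` (logical), `capture_day` (integer). The efforts file carries
#' `mountain`, `location`, `trap_class`, `trap_nights`; the metadata file
#' `species`, `endemic` (`endemic`/`non_endemic`/`unknown`). Species present
#' in the records but missing from the metadata are added with status
#' `"unknown"` (with a warning).
#'
#' @param records path to the capture-record table.
#' @param efforts optional path to the trapping-effort table.
#' @param meta optional path to the species-metadata table.
#' @param sep field separator (`","` default; use `"\t"` for TSV).
#' @return a [SurveyDataset-class].
#' @examples
#' toy <- system.file("extdata", "toy_records.csv", package = "elevdiv")
#' eff <- system.file("extdata", "toy_efforts.csv", package = "elevdiv")
#' met <- system.file("extdata", "toy_species.csv", package = "elevdiv")
#' ds <- readSurvey(toy, eff, met)
#' ds
#' @export
readSurvey <- function(records, efforts = NULL, meta = NULL, sep = ",") {
  if (!file.exists(records))
    stop("records file not found: ", records, call. = FALSE)
  rec <- utils::read.table(records, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  eff <- NULL
  if (!is.null(efforts)) {
    if (!file.exists(efforts))
      stop("efforts file not found: ", efforts, call. = FALSE)
    eff <- utils::read.table(efforts, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  }
  met <- NULL
  if (!is.null(meta)) {
    if (!file.exists(meta))
      stop("meta file not found: ", meta, call. = FALSE)
    met <- utils::read.table(meta, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  }
  surveyDataset(rec, eff, met,
                provenance = paste0("read from ", basename(records)))
}

#' Write a SurveyDataset to delimited text files
#'
#' Emits the three tables (`records.csv`, `efforts.csv`, `species.csv`) in
#' the exact schema [readSurvey()] consumes.
#'
#' @param ds a [SurveyDataset-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
writeSurvey <- function(ds, dir) {
  stopifnot(is(ds, "SurveyDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("records.csv", "efforts.csv", "species.csv"))
  utils::write.csv(records(ds), paths[1], row.names = FALSE)
  utils::write.csv(efforts(ds), paths[2], row.names = FALSE)
  utils::write.csv(speciesMeta(ds), paths[3], row.names = FALSE)
  invisible(paths)
}

#' Filter capture records (and matching effort) by trap class and recapture
#'
#' Restricts a survey to the record subset used by the analyses: by default
#' arboreal and pitfall captures and recaptured animals are dropped, leaving
#' the ground-trap community of first captures. When a trap class is
#' excluded its effort rows are removed as well, so trap-success denominators
#' stay consistent. The filter is recorded in the provenance log; an empty
#' result is legal; applying the same filter twice is a no-op.
#'
#' @param x a [SurveyDataset-class].
#' @param includeArboreal keep captures in traps set above ~3 m? (default
#'   `FALSE`)
#' @param includePitfall keep pitfall-trap captures? (default `FALSE`)
#' @param includeRecaptures keep recaptured individuals? (default `FALSE`)
#' @param ... unused.
#' @return the filtered [SurveyDataset-class].
#' @export
setMethod("filterRecords", "SurveyDataset",
  function(x, includeArboreal = FALSE, includePitfall = FALSE,
           includeRecaptures = FALSE, ...) {
    rec <- x@records
    eff <- x@efforts
    drop_class <- c(if (!includeArboreal) "arboreal",
                    if (!includePitfall) "pitfall")
    if (length(drop_class)) {
      rec <- rec[!rec$trap_class %in% drop_class, , drop = FALSE]
      eff <- eff[!eff$trap_class %in% drop_class, , drop = FALSE]
    }
    if (!includeRecaptures)
      rec <- rec[!rec$recapture, , drop = FALSE]
    step <- sprintf(
      "filter: arboreal=%s, pitfall=%s, recaptures=%s -> %d records",
      includeArboreal, includePitfall, includeRecaptures, nrow(rec))
    new("SurveyDataset", records = rec, efforts = eff, meta = x@meta,
        provenance = c(x@provenance, step))
  })

## site table from records: one row per (mountain, location); nominal
## elevation = median capture elevation; deterministic ordering by mountain,
## then elevation ascending, then location label
.siteTable <- function(rec) {
  key <- paste(rec$mountain, rec$location, sep = " / ")
  sites <- unique(data.frame(site = key, mountain = rec$mountain,
                             location = rec$location,
                             stringsAsFactors = FALSE))
  sites$elevation <- vapply(sites$site, function(s)
    stats::median(rec$elevation[key == s]), numeric(1))
  ## use the numeric location label as the nominal elevation where it parses
  num <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", sites$location)))
  sites$elevation <- ifelse(is.finite(num) & num > 0, num, sites$elevation)
  ord <- order(sites$mountain, sites$elevation, sites$location)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Build the sites x species abundance matrix
#'
#' Cross-tabulates capture records into a [CommunityMatrix-class]:
#' `counts[i, j]` is the number of records of species `j` at site `i`
#' (site = mountain + trapping location). Sites are ordered by mountain,
#' then nominal elevation ascending, then label; species columns
#' lexicographically. Row sums equal per-site capture totals after
#' filtering, and no all-zero species column is retained.
#'
#' @param x a [SurveyDataset-class] with at least one record.
#' @param ... unused.
#' @return a [CommunityMatrix-class].
#' @export
setMethod("buildAbundanceMatrix", "SurveyDataset", function(x, ...) {
  rec <- x@records
  if (!nrow(rec))
    stop("cannot build an abundance matrix from an empty dataset",
         call. = FALSE)
  sites <- .siteTable(rec)
  key <- paste(rec$mountain, rec$location, sep = " / ")
  sp <- sort(unique(rec$species))
  cm <- matrix(0L, nrow(sites), length(sp),
               dimnames = list(sites$site, sp))
  tab <- table(factor(key, levels = sites$site),
               factor(rec$species, levels = sp))
  cm[] <- as.integer(tab)
  new("CommunityMatrix", counts = cm, siteData = sites)
})

#' Subset a CommunityMatrix to one mountain
#'
#' @param x a [CommunityMatrix-class].
#' @param mountain mountain label to keep.
#' @return a [CommunityMatrix-class] with that mountain's sites and any
#'   species recorded there.
#' @export
subsetMountain <- function(x, mountain) {
  stopifnot(is(x, "CommunityMatrix"))
  keep <- x@siteData$mountain == mountain
  if (!any(keep)) stop("no sites on mountain '", mountain, "'", call. = FALSE)
  cm <- x@counts[keep, , drop = FALSE]
  cm <- cm[, colSums(cm) > 0, drop = FALSE]
  sd <- x@siteData[keep, , drop = FALSE]
  rownames(sd) <- NULL
  new("CommunityMatrix", counts = cm, siteData = sd)
}

#' Trap success per trapping location or mountain
#'
#' Captures per 100 trap nights, the survey's relative-abundance proxy:
#' `percent = 100 * n_captures / trap_nights`, reported rounded half-up to
#' one decimal (`percent`) alongside the unrounded value (`percent_raw`).
#' Effort is summed over the trap classes still present in the dataset, so
#' filtering arboreal/pitfall traps upstream removes their trap nights from
#' the denominator.
#'
#' @param x a [SurveyDataset-class]; efforts must cover every group that has
#'   records.
#' @param groupBy `"location"` (mountain x trapping location, default) or
#'   `"mountain"`.
#' @param ... unused.
#' @return data.frame with `group`, `mountain`, `n_captures`, `trap_nights`,
#'   `percent`, `percent_raw`.
#' @examples
#' ds <- filterRecords(studySurveyFromTables())
#' trapSuccess(ds, groupBy = "mountain")
#' @export
setMethod("trapSuccess", "SurveyDataset",
  function(x, groupBy = c("location", "mountain"), ...) {
    groupBy <- match.arg(groupBy)
    rec <- x@records
    eff <- x@efforts
    gkey <- function(m, l) if (groupBy == "mountain") m
                           else paste(m, l, sep = " / ")
    rg <- gkey(rec$mountain, rec$location)
    eg <- gkey(eff$mountain, eff$location)
    groups <- sort(unique(c(rg, eg)))
    n_cap <- vapply(groups, function(g) sum(rg == g), integer(1))
    nights <- vapply(groups, function(g) sum(eff$trap_nights[eg == g]),
                     numeric(1))
    no_eff <- n_cap > 0 & nights == 0
    if (any(no_eff))
      stop("captures recorded with zero trap nights for group(s): ",
           paste(groups[no_eff], collapse = ", "), call. = FALSE)
    raw <- ifelse(nights > 0, 100 * n_cap / nights, NA_real_)
    mtn <- vapply(groups, function(g) {
      i <- match(g, rg)
      if (!is.na(i)) rec$mountain[i] else eff$mountain[match(g, eg)]
    }, character(1))
    out <- data.frame(group = groups, mountain = mtn,
                      n_captures = n_cap, trap_nights = nights,
                      percent = roundHalfUp(raw, 1), percent_raw = raw,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })

#' Species accumulation curve for one trapping location
#'
#' Cumulative species richness against cumulative trap nights over
#' successive trapping days, assuming all traps were set on day 1 (the
#' per-day effort is `nTraps`; when `nTraps` is `NULL` it is taken as the
#' location's total trap nights divided by the number of days). The curve is
#' non-decreasing in both coordinates and ends at the site's observed
#' richness; it is the saturation diagnostic used to judge survey
#' completeness.
#'
#' @param x a [SurveyDataset-class] whose records at `site` carry
#'   `capture_day`.
#' @param site site label, `"<mountain> / <location>"`.
#' @param nTraps traps operating per day at the site, or `NULL` to infer.
#' @param nDays number of trapping days, defaults to the latest capture day.
#' @param ... unused.
#' @return data.frame with `day`, `cum_trap_nights`, `cum_richness`.
#' @export
setMethod("accumulationCurve", "SurveyDataset",
  function(x, site, nTraps = NULL, nDays = NULL, ...) {
    rec <- x@records
    key <- paste(rec$mountain, rec$location, sep = " / ")
    rec <- rec[key == site, , drop = FALSE]
    if (nrow(rec) && any(is.na(rec$capture_day)))
      stop("accumulation curve needs capture_day on every record at ", site,
           call. = FALSE)
    if (is.null(nDays))
      nDays <- if (nrow(rec)) max(rec$capture_day) else 1L
    if (is.null(nTraps)) {
      eff <- x@efforts
      ekey <- paste(eff$mountain, eff$location, sep = " / ")
      tot <- sum(eff$trap_nights[ekey == site])
      if (tot <= 0)
        stop("cannot infer nTraps: no effort recorded for ", site,
             call. = FALSE)
      nTraps <- tot / nDays
    }
    days <- seq_len(nDays)
    rich <- vapply(days, function(d)
      length(unique(rec$species[rec$capture_day <= d])), integer(1))
    data.frame(day = days, cum_trap_nights = days * nTraps,
               cum_richness = rich)
  })

#' Camera-trap relative abundance per 100 camera nights
#'
#' `rate = 100 * n_series / camera_nights`, rounded half-up to two decimals
#' (`rate_raw` keeps the unrounded value). One row per camera x species;
#' `n_series` counts independent visit series.
#'
#' @param series data.frame with columns `camera_id`, `elevation`, `species`,
#'   `n_series` (>= 0) and `camera_nights` (> 0).
#' @return the input with `rate` and `rate_raw` columns appended.
#' @examples
#' cameraRelativeAbundance(studyCameraTable())
#' @export
cameraRelativeAbundance <- function(series) {
  need <- c("camera_id", "species", "n_series", "camera_nights")
  miss <- setdiff(need, names(series))
  if (length(miss))
    stop("camera series missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(series$camera_nights)) || any(series$camera_nights <= 0))
    stop("camera_nights must be > 0", call. = FALSE)
  if (any(series$n_series < 0))
    stop("n_series must be >= 0", call. = FALSE)
  raw <- 100 * series$n_series / series$camera_nights
  series$rate <- roundHalfUp(raw, 2)
  series$rate_raw <- raw
  series
}
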