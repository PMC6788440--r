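## Central S4 containers. Capture records, effort totals and species metadata
## travel together in a SurveyDataset; all diversity math runs off a
## CommunityMatrix (sites x species counts with a site table).

TRAP_CLASSES <- c("ground", "arboreal", "pitfall")
ENDEMIC_LEVELS <- c("endemic", "non_endemic", "unknown")

#' SurveyDataset: capture-level trap-survey data
#'
#' Holds one trap survey: one row per capture (`records`), per-location
#' trap-night totals by trap class (`efforts`), per-species metadata with the
#' Borneo-endemic flag (`meta`), and a free-text `provenance` log that grows
#' monotonically as filters are applied.
#'
#' Records carry `record_id`, `species`, `mountain`, `location`, `elevation`
#' (m above sea level, > 0), `trap_class` (`ground`/`arboreal`/`pitfall`),
#' logical `recapture`, and optional integer `capture_day` (>= 1; `NA` when
#' unknown). Efforts carry `mountain`, `location`, `trap_class`,
#' `trap_nights` (one trap operational for one night); the triple
#' (mountain, location, trap_class) is unique. Metadata carries `species`,
#' `endemic` (`endemic`/`non_endemic`/`unknown`) and `notes`.
#'
#' @slot records data.frame of captures.
#' @slot efforts data.frame of trap-night totals.
#' @slot meta data.frame of species metadata.
#' @slot provenance character vector, one entry per construction/filter step.
#'
#' @seealso [readSurvey()], [filterRecords()], [buildAbundanceMatrix()]
#' @export
setClass("SurveyDataset",
  representation(records = "data.frame", efforts = "data.frame",
                 meta = "data.frame", provenance = "character"))

.validSurveyDataset <- function(object) {
  msg <- character()
  rec <- object@records
  eff <- object@efforts
  met <- object@meta
  need_rec <- c("record_id", "species", "mountain", "location", "elevation",
                "trap_class", "recapture", "capture_day")
  miss <- setdiff(need_rec, names(rec))
  if (length(miss))
    msg <- c(msg, paste0("records missing column(s): ",
                         paste(miss, collapse = ", ")))
  need_eff <- c("mountain", "location", "trap_class", "trap_nights")
  miss <- setdiff(need_eff, names(eff))
  if (length(miss))
    msg <- c(msg, paste0("efforts missing column(s): ",
                         paste(miss, collapse = ", ")))
  need_met <- c("species", "endemic")
  miss <- setdiff(need_met, names(met))
  if (length(miss))
    msg <- c(msg, paste0("meta missing column(s): ",
                         paste(miss, collapse = ", ")))
  if (length(msg)) return(msg)

  if (nrow(rec)) {
    if (any(is.na(rec$species)) || any(!nzchar(rec$species)))
      msg <- c(msg, "records: species labels must be non-empty")
    if (any(!is.finite(rec$elevation)) || any(rec$elevation <= 0))
      msg <- c(msg, "records: elevation must be finite and > 0")
    if (any(!rec$trap_class %in% TRAP_CLASSES))
      msg <- c(msg, paste0("records: trap_class must be one of ",
                           paste(TRAP_CLASSES, collapse = "/")))
    if (any(!is.na(rec$capture_day) & rec$capture_day < 1))
      msg <- c(msg, "records: capture_day must be >= 1 when present")
    unmet <- setdiff(unique(rec$species), met$species)
    if (length(unmet))
      msg <- c(msg, paste0("records reference species without metadata: ",
                           paste(unmet, collapse = ", ")))
  }
  if (nrow(eff)) {
    if (any(!is.finite(eff$trap_nights)) || any(eff$trap_nights < 0))
      msg <- c(msg, "efforts: trap_nights must be >= 0")
    key <- paste(eff$mountain, eff$location, eff$trap_class, sep = "\r")
    if (anyDuplicated(key))
      msg <- c(msg, "efforts: (mountain, location, trap_class) must be unique")
  }
  if (nrow(met)) {
    if (any(!met$endemic %in% ENDEMIC_LEVELS))
      msg <- c(msg, paste0("meta: endemic must be one of ",
                           paste(ENDEMIC_LEVELS, collapse = "/")))
    if (anyDuplicated(met$species))
      msg <- c(msg, "meta: species must be unique")
  }
  if (length(msg)) msg else TRUE
}
setValidity("SurveyDataset", .validSurveyDataset)

#' CommunityMatrix: sites x species counts
#'
#' A sites-by-species abundance matrix with a site table. Rows (sites) are
#' ordered by mountain, then nominal elevation ascending, then label, so all
#' downstream outputs are deterministic. `incidence()` derives the logical
#' presence/absence matrix.
#'
#' @slot counts non-negative integer matrix, sites in rows, species in columns.
#' @slot siteData data.frame with columns `site`, `mountain`, `location`,
#'   `elevation` (nominal site elevation, m), aligned with `rownames(counts)`.
#'
#' @seealso [buildAbundanceMatrix()], [diversityProfile()],
#'   [multisitePartition()]
#' @export
setClass("CommunityMatrix",
  representation(counts = "matrix", siteData = "data.frame"))

.validCommunityMatrix <- function(object) {
  msg <- character()
  cm <- object@counts
  sd <- object@siteData
  if (!is.numeric(cm)) msg <- c(msg, "counts must be numeric")
  else {
    if (any(cm < 0) || any(cm != round(cm)))
      msg <- c(msg, "counts must be non-negative integers")
    if (ncol(cm) && any(colSums(cm) == 0))
      msg <- c(msg, "counts must have no all-zero species column")
  }
  if (!all(c("site", "mountain", "location", "elevation") %in% names(sd)))
    msg <- c(msg, "siteData needs columns site, mountain, location, elevation")
  else if (!identical(rownames(cm), as.character(sd$site)))
    msg <- c(msg, "rownames(counts) must equal siteData$site")
  if (length(msg)) msg else TRUE
}
setValidity("CommunityMatrix", .validCommunityMatrix)

#' ElevationDomain: a discretized elevational extent
#'
#' The elevational domain of one mountain, tiled into contiguous bands of
#' `bandWidth` metres: band k (1-based) covers
#' `[minElev + (k-1)w, minElev + kw)`, with the top band closed so the domain
#' maximum falls inside it. The default width, 50 m, is the discretization
#' used throughout the mid-domain-effect null model.
#'
#' @slot mountain character label.
#' @slot minElev,maxElev numeric, domain extremes (m), from the lowest and
#'   highest trap elevations.
#' @slot bandWidth numeric, band width in metres (> 0).
#' @slot nBands integer, number of bands tiling the domain.
#' @export
setClass("ElevationDomain",
  representation(mountain = "character", minElev = "numeric",
                 maxElev = "numeric", bandWidth = "numeric",
                 nBands = "integer"))

setValidity("ElevationDomain", function(object) {
  msg <- character()
  if (object@bandWidth <= 0) msg <- c(msg, "bandWidth must be > 0")
  if (object@maxElev < object@minElev)
    msg <- c(msg, "maxElev must be >= minElev")
  k <- max(1L, as.integer(ceiling((object@maxElev - object@minElev) /
                                    object@bandWidth)))
  if (object@nBands != k)
    msg <- c(msg, "nBands inconsistent with extent and bandWidth")
  if (length(msg)) msg else TRUE
})

#' SpeciesRangeSet: discretized elevational ranges
#'
#' Per-species contiguous band ranges on an [ElevationDomain-class]: ranges
#' run from the band holding the species' lowest capture to the band holding
#' its highest (interpolated as continuous occupancy in between).
#'
#' @slot domain the [ElevationDomain-class].
#' @slot ranges data.frame with `species`, `lowBand`, `highBand`, `size`
#'   (bands, `highBand - lowBand + 1`), `minElev`, `maxElev` (observed, m).
#' @export
setClass("SpeciesRangeSet",
  representation(domain = "ElevationDomain", ranges = "data.frame"))

setValidity("SpeciesRangeSet", function(object) {
  r <- object@ranges
  msg <- character()
  if (!all(c("species", "lowBand", "highBand", "size") %in% names(r)))
    return("ranges needs columns species, lowBand, highBand, size")
  if (nrow(r)) {
    if (any(r$lowBand < 1L) || any(r$highBand > object@domain@nBands))
      msg <- c(msg, "band indices must lie within the domain")
    if (any(r$lowBand > r$highBand))
      msg <- c(msg, "lowBand must be <= highBand")
    if (any(r$size != r$highBand - r$lowBand + 1L))
      msg <- c(msg, "size must equal highBand - lowBand + 1")
  }
  if (length(msg)) msg else TRUE
})

#' MDEEnvelope: null richness envelope under the mid-domain effect
#'
#' Per-band expected species richness under random placement of observed
#' range sizes within the domain: the mean and the 2.5% / 97.5% percentiles
#' over replicates, with the boundary rule, replicate count and seed that
#' produced them.
#'
#' @slot bands data.frame with `band`, `lo`, `hi` (m), `mean`, `q025`, `q975`.
#' @slot reps integer, number of randomizations.
#' @slot boundaries `"soft"` or `"hard"`.
#' @slot seed integer seed used.
#' @slot nSpecies integer, number of ranges shuffled.
#' @seealso [rangeShuffle()], [compareObserved()]
#' @export
setClass("MDEEnvelope",
  representation(bands = "data.frame", reps = "integer",
                 boundaries = "character", seed = "integer",
                 nSpecies = "integer"))

setValidity("MDEEnvelope", function(object) {
  b <- object@bands
  msg <- character()
  if (!all(c("band", "lo", "hi", "mean", "q025", "q975") %in% names(b)))
    return("bands needs columns band, lo, hi, mean, q025, q975")
  if (any(b$q025 > b$mean + 1e-9) || any(b$mean > b$q975 + 1e-9))
    msg <- c(msg, "per band, q025 <= mean <= q975 must hold")
  if (!object@boundaries %in% c("soft", "hard"))
    msg <- c(msg, "boundaries must be 'soft' or 'hard'")
  if (object@reps < 1L) msg <- c(msg, "reps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' BetaPartition: Sorensen dissimilarity split into turnover and nestedness
#'
#' The Sorensen-family dissimilarity of a set of sites, partitioned as
#' `sor = sim + sne`: `sim` is the turnover (species-replacement) component,
#' insensitive to richness differences, and `sne` the nestedness-resultant
#' component. `scope` records whether the values are pairwise (two sites) or
#' multiple-site.
#'
#' @slot sor,sim,sne numeric in \[0, 1\].
#' @slot scope `"pairwise"` or `"multisite"`.
#' @slot sites character, the site labels involved.
#' @seealso [multisitePartition()], [pairwisePartition()]
#' @export
setClass("BetaPartition",
  representation(sor = "numeric", sim = "numeric", sne = "numeric",
                 scope = "character", sites = "character"))

setValidity("BetaPartition", function(object) {
  msg <- character()
  if (!object@scope %in% c("pairwise", "multisite"))
    msg <- c(msg, "scope must be 'pairwise' or 'multisite'")
  if (is.finite(object@sor)) {
    if (object@sor < -1e-12 || object@sor > 1 + 1e-12)
      msg <- c(msg, "sor must lie in [0, 1]")
    if (abs(object@sor - (object@sim + object@sne)) > 1e-9)
      msg <- c(msg, "sor must equal sim + sne")
  }
  if (length(msg)) msg else TRUE
})

#' BootstrapEnvelope: percentile envelope for endemism proportions
#'
#' Per-site 2.5% / 97.5% percentile interval of the endemic proportion under
#' resampling (species lists or capture records, with replacement, original
#' size), plus the point estimate and bookkeeping. Sites with no classified
#' species are flagged and carry `NA` envelopes.
#'
#' @slot table data.frame with `site`, `estimate`, `q025`, `q975`,
#'   `n_classified`, `flagged`.
#' @slot reps integer replicate count.
#' @slot seed integer seed.
#' @slot unit `"species"` or `"captures"`.
#' @seealso [bootstrapEnvelope()]
#' @export
setClass("BootstrapEnvelope",
  representation(table = "data.frame", reps = "integer", seed = "integer",
                 unit = "character"))

setValidity("BootstrapEnvelope", function(object) {
  msg <- character()
  if (!object@unit %in% c("species", "captures"))
    msg <- c(msg, "unit must be 'species' or 'captures'")
  tb <- object@table
  ok <- is.finite(tb$q025) & is.finite(tb$q975)
  if (any(tb$q025[ok] > tb$q975[ok]))
    msg <- c(msg, "q025 must be <= q975")
  if (length(msg)) msg else TRUE
})

#' EndemicRemovalResult: permutation test for the contribution of endemics
#'
#' Observed multiple-site beta components after removing endemic species,
#' compared to a null of equal-size random species subsets drawn without
#' replacement from the mountain's classified species pool. One-tailed
#' empirical p-values with add-one correction; the tail follows the sign of
#' (observed - full-matrix component).
#'
#' @slot mountain character.
#' @slot observed named numeric (`sor`, `sim`, `sne`) on the non-endemic
#'   submatrix.
#' @slot full named numeric, components of the complete classified matrix.
#' @slot null reps x 3 matrix of null components (columns sor, sim, sne).
#' @slot p named numeric (`p_sor`, `p_sim`, `p_sne`), each in (0, 1\].
#' @slot tail named character, `"le"` (decrease) or `"ge"` (increase).
#' @slot reps,seed integers.
#' @slot subsetSize integer, number of non-endemic species (null subset size).
#' @seealso [endemicRemovalTest()]
#' @export
setClass("EndemicRemovalResult",
  representation(mountain = "character", observed = "numeric",
                 full = "numeric", null = "matrix", p = "numeric",
                 tail = "character", reps = "integer", seed = "integer",
                 subsetSize = "integer"))

setValidity("EndemicRemovalResult", function(object) {
  msg <- character()
  if (any(object@p <= 0) || any(object@p > 1))
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (nrow(object@null) != object@reps)
    msg <- c(msg, "null must have reps rows")
  if (length(msg)) msg else TRUE
})

#' SyntheticConfig: parameters of the synthetic trap-survey generator
#'
#' Ground-truth configuration for [simulateSurvey()]. Species receive
#' contiguous elevational ranges (midpoint drawn with an elevation-dependent
#' weight so that expected richness changes by `richnessSlope` species per
#' 1,000 m; size in 50 m bands from a truncated normal). A species' endemic
#' flag is Bernoulli with logit-linear probability in its range midpoint
#' (`endemismLogitSlope` per 1,000 m). Abundances combine geometric
#' species-dominance weights with log-normal site effects; captures arise by
#' per-trap-night Bernoulli detection of each available individual over
#' `nDays` days with `nTraps` traps per site.
#'
#' @slot mountainNames character, one label per mountain.
#' @slot elevRange numeric matrix, 2 rows (min, max) x mountains.
#' @slot nSites integer, trapping locations per mountain.
#' @slot nSpecies integer, species in the regional pool.
#' @slot richnessSlope numeric, expected change in true richness per 1,000 m
#'   (negative = decline with elevation).
#' @slot endemismLogitIntercept,endemismLogitSlope numeric, logit-scale
#'   intercept and per-1,000 m slope of P(endemic | midpoint).
#' @slot rangeMeanBands,rangeSdBands numeric, range-size distribution (bands).
#' @slot bandWidth numeric, metres per band.
#' @slot meanAbundance numeric, mean available individuals per species in
#'   range per site before dominance/site effects.
#' @slot dominanceRatio numeric in (0, 1\], geometric dominance decay.
#' @slot siteEffectSd numeric, sd of log-normal site effects.
#' @slot nTraps,nDays integers per site (trap nights = nTraps * nDays).
#' @slot detectionP numeric, per-trap-night detection probability of one
#'   available individual by one trap.
#' @slot seed integer.
#' @seealso [paperlikePreset()], [simulateSurvey()]
#' @export
setClass("SyntheticConfig",
  representation(mountainNames = "character", elevRange = "matrix",
                 nSites = "integer", nSpecies = "integer",
                 richnessSlope = "numeric",
                 endemismLogitIntercept = "numeric",
                 endemismLogitSlope = "numeric",
                 rangeMeanBands = "numeric", rangeSdBands = "numeric",
                 bandWidth = "numeric", meanAbundance = "numeric",
                 dominanceRatio = "numeric", siteEffectSd = "numeric",
                 nTraps = "integer", nDays = "integer",
                 detectionP = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (length(object@mountainNames) < 1L)
    msg <- c(msg, "need at least one mountain")
  if (ncol(object@elevRange) != length(object@mountainNames) ||
      nrow(object@elevRange) != 2L)
    msg <- c(msg, "elevRange must be a 2 x nMountains matrix (min, max)")
  else if (any(object@elevRange[1, ] >= object@elevRange[2, ]))
    msg <- c(msg, "elevRange min must be < max")
  if (object@nSites < 2L) msg <- c(msg, "nSites must be >= 2")
  if (object@nSpecies < 1L) msg <- c(msg, "nSpecies must be >= 1")
  if (object@bandWidth <= 0) msg <- c(msg, "bandWidth must be > 0")
  if (object@rangeMeanBands < 1) msg <- c(msg, "rangeMeanBands must be >= 1")
  if (object@detectionP < 0 || object@detectionP > 1)
    msg <- c(msg, "detectionP must lie in [0, 1]")
  if (object@dominanceRatio <= 0 || object@dominanceRatio > 1)
    msg <- c(msg, "dominanceRatio must lie in (0, 1]")
  if (object@nTraps < 1L || object@nDays < 1L)
    msg <- c(msg, "nTraps and nDays must be >= 1 (zero trap nights is infeasible)")
  if (object@meanAbundance <= 0) msg <- c(msg, "meanAbundance must be > 0")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "SurveyDataset", function(object) {
  cat("SurveyDataset:", nrow(object@records), "capture records,",
      nrow(object@efforts), "effort rows,",
      nrow(object@meta), "species\n")
  if (nrow(object@records)) {
    tab <- table(object@records$mountain)
    cat("  mountains:",
        paste(sprintf("%s (%d)", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
  }
  cat("  provenance:", length(object@provenance), "step(s)\n")
})

setMethod("show", "CommunityMatrix", function(object) {
  cat("CommunityMatrix:", nrow(object@counts), "sites x",
      ncol(object@counts), "species,",
      sum(object@counts), "individuals\n")
})

setMethod("show", "ElevationDomain", function(object) {
  cat(sprintf("ElevationDomain '%s': %g-%g m, %g m bands (n = %d)\n",
              object@mountain, object@minElev, object@maxElev,
              object@bandWidth, object@nBands))
})

setMethod("show", "SpeciesRangeSet", function(object) {
  cat("SpeciesRangeSet:", nrow(object@ranges), "species on ")
  show(object@domain)
})

setMethod("show", "MDEEnvelope", function(object) {
  cat(sprintf(
    "MDEEnvelope: %d bands, %d species, %d reps, %s boundaries (seed %d)\n",
    nrow(object@bands), object@nSpecies, object@reps, object@boundaries,
    object@seed))
})

setMethod("show", "BetaPartition", function(object) {
  cat(sprintf("BetaPartition (%s, %d sites): sor = %.4f = sim %.4f + sne %.4f\n",
              object@scope, length(object@sites), object@sor, object@sim,
              object@sne))
})

setMethod("show", "BootstrapEnvelope", function(object) {
  cat(sprintf("BootstrapEnvelope (%s unit): %d sites, %d reps (seed %d)\n",
              object@unit, nrow(object@table), object@reps, object@seed))
})

setMethod("show", "EndemicRemovalResult", function(object) {
  cat(sprintf("EndemicRemovalResult '%s': %d-species null subsets, %d reps\n",
              object@mountain, object@subsetSize, object@reps))
  cat(sprintf("  observed (endemics removed): sim = %.3f, sne = %.3f, sor = %.3f\n",
              object@observed["sim"], object@observed["sne"],
              object@observed["sor"]))
  cat(sprintf("  p_sim = %.4g (%s), p_sne = %.4g (%s)\n",
              object@p["p_sim"], object@tail["sim"],
              object@p["p_sne"], object@tail["sne"]))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d mountain(s) x %d sites, %d species, seed %d\n",
    length(object@mountainNames), object@nSites, object@nSpecies,
    object@seed))
})

## ---- accessors ----------------------------------------------------------

#' @rdname accessors
setMethod("records", "SurveyDataset", function(x) x@records)

#' @rdname accessors
setMethod("efforts", "SurveyDataset", function(x) x@efforts)

#' @rdname accessors
setMethod("speciesMeta", "SurveyDataset", function(x) x@meta)

#' @rdname accessors
setMethod("provenance", "SurveyDataset", function(x) x@provenance)

#' @rdname accessors
setMethod("counts", "CommunityMatrix", function(x, ...) x@counts)

#' @rdname accessors
setMethod("incidence", "CommunityMatrix",
          function(x, ...) x@counts > 0)

#' @rdname accessors
setMethod("siteData", "CommunityMatrix", function(x) x@siteData)
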