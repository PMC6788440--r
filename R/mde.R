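## Mid-domain-effect null model: discretize observed elevational ranges into
## bands, then shuffle range midpoints within the bounded domain and tally
## the richness expected from chance range overlap alone.

#' Construct an ElevationDomain
#'
#' @param mountain label.
#' @param minElev,maxElev domain extremes (m).
#' @param bandWidth band width in metres (default 50).
#' @return an [ElevationDomain-class].
#' @export
elevationDomain <- function(mountain, minElev, maxElev, bandWidth = 50) {
  if (bandWidth <= 0) stop("bandWidth must be > 0", call. = FALSE)
  n <- max(1L, as.integer(ceiling((maxElev - minElev) / bandWidth)))
  new("ElevationDomain", mountain = as.character(mountain),
      minElev = as.numeric(minElev), maxElev = as.numeric(maxElev),
      bandWidth = as.numeric(bandWidth), nBands = n)
}

#' Map elevations to band indices
#'
#' Band k covers `[minElev + (k-1)w, minElev + kw)`; the domain maximum
#' falls in the top band. Elevations outside the domain raise an error.
#'
#' @param domain an [ElevationDomain-class].
#' @param elevation numeric vector of elevations (m).
#' @return integer band indices (1-based).
#' @export
elevationToBand <- function(domain, elevation) {
  if (any(elevation < domain@minElev - 1e-9) ||
      any(elevation > domain@maxElev + 1e-9))
    stop("elevation outside the domain [", domain@minElev, ", ",
         domain@maxElev, "] m", call. = FALSE)
  b <- floor((elevation - domain@minElev) / domain@bandWidth) + 1L
  pmin(as.integer(b), domain@nBands)
}

#' Band boundaries of a domain
#'
#' @param domain an [ElevationDomain-class].
#' @return data.frame with `band`, `lo`, `hi` (m).
#' @export
bandBounds <- function(domain) {
  k <- seq_len(domain@nBands)
  data.frame(band = k,
             lo = domain@minElev + (k - 1L) * domain@bandWidth,
             hi = domain@minElev + k * domain@bandWidth)
}

#' Discretize observed species ranges into elevational bands
#'
#' For one mountain, builds the [ElevationDomain-class] spanning the lowest
#' to the highest trap elevation (tiled into `bandWidth`-m bands) and, for
#' every species recorded there, the contiguous band range from the band
#' holding its lowest capture to the band holding its highest — treating
#' the species as present at all elevations in between, the interpolation
#' justified by ranges being observed contiguously in this survey design.
#'
#' @param ds a [SurveyDataset-class].
#' @param mountain mountain to analyse (default: the only one present).
#' @param bandWidth band width in metres (default 50, the discretization
#'   used throughout).
#' @param domain optional [ElevationDomain-class] overriding the observed
#'   extent (e.g., the full trapped extent when records were filtered).
#' @return a [SpeciesRangeSet-class].
#' @export
discretizeRanges <- function(ds, mountain = NULL, bandWidth = 50,
                             domain = NULL) {
  stopifnot(is(ds, "SurveyDataset"))
  if (bandWidth <= 0) stop("bandWidth must be > 0", call. = FALSE)
  rec <- records(ds)
  if (is.null(mountain)) {
    mountain <- unique(rec$mountain)
    if (length(mountain) != 1L)
      stop("several mountains present; pass `mountain`", call. = FALSE)
  }
  rec <- rec[rec$mountain == mountain, , drop = FALSE]
  if (!nrow(rec)) stop("no records on mountain '", mountain, "'",
                       call. = FALSE)
  if (is.null(domain)) {
    ## trapped extent: capture elevations plus the nominal location
    ## elevations (so sites with few captures still map into the domain)
    nom <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", rec$location)))
    ext <- range(c(rec$elevation, nom[is.finite(nom) & nom > 0]))
    domain <- elevationDomain(mountain, ext[1], ext[2], bandWidth)
  }
  sp <- sort(unique(rec$species))
  lo <- vapply(sp, function(s) min(rec$elevation[rec$species == s]),
               numeric(1))
  hi <- vapply(sp, function(s) max(rec$elevation[rec$species == s]),
               numeric(1))
  lowBand <- elevationToBand(domain, lo)
  highBand <- elevationToBand(domain, hi)
  ranges <- data.frame(species = sp, lowBand = lowBand, highBand = highBand,
                       size = highBand - lowBand + 1L,
                       minElev = lo, maxElev = hi,
                       stringsAsFactors = FALSE, row.names = NULL)
  new("SpeciesRangeSet", domain = domain, ranges = ranges)
}

## one randomized placement of every range; returns per-band richness.
## sizes: integer vector; n: band count.
.placeRanges <- function(sizes, n, boundaries) {
  if (boundaries == "hard") {
    start <- vapply(sizes, function(s)
      sample.int(n - s + 1L, 1L), integer(1))
    lo <- start
    hi <- start + sizes - 1L
  } else {
    mid <- sample.int(n, length(sizes), replace = TRUE)
    odd <- sizes %% 2L == 1L
    half <- (sizes - 1L) %/% 2L          # floor((s-1)/2)
    up <- stats::runif(length(sizes)) < 0.5  # extra band uphill?
    lo <- ifelse(odd, mid - half, mid - half - ifelse(up, 0L, 1L))
    hi <- ifelse(odd, mid + half, mid + half + ifelse(up, 1L, 0L))
    lo <- pmax(lo, 1L)
    hi <- pmin(hi, n)
  }
  ## richness per band via a difference array
  d <- integer(n + 1L)
  for (k in seq_along(lo)) {
    d[lo[k]] <- d[lo[k]] + 1L
    d[hi[k] + 1L] <- d[hi[k] + 1L] - 1L
  }
  cumsum(d[seq_len(n)])
}

#' Shuffle species range midpoints within the domain
#'
#' The mid-domain-effect null: each replicate keeps every species' range
#' size (in bands) and assigns it a uniformly random position in the
#' domain, then tallies richness per band; the envelope holds the per-band
#' mean and the 2.5% / 97.5% percentiles (linear interpolation between
#' order statistics) over replicates.
#'
#' Boundary rules: with `"soft"` boundaries (the default used in the
#' analysis) the midpoint band is uniform over all bands and the range
#' extends half its size each way, truncated where it overshoots the domain
#' edge (for even sizes the odd band goes up- or downhill by a fair coin
#' per placement). With `"hard"` boundaries the whole range must fit: its
#' start band is uniform over the feasible positions, and a range wider
#' than the domain is an error.
#'
#' @param ranges a [SpeciesRangeSet-class].
#' @param reps randomizations (default 5000).
#' @param boundaries `"soft"` (default) or `"hard"`.
#' @param seed integer seed (mandatory, for reproducibility).
#' @return an [MDEEnvelope-class].
#' @examples
#' dom <- elevationDomain("toy", 0, 400, 50)
#' rs <- new("SpeciesRangeSet", domain = dom,
#'           ranges = data.frame(species = c("a", "b"),
#'                               lowBand = c(1L, 3L), highBand = c(4L, 8L),
#'                               size = c(4L, 6L)))
#' rangeShuffle(rs, reps = 100, seed = 1)
#' @export
rangeShuffle <- function(ranges, reps = 5000, boundaries = c("soft", "hard"),
                         seed) {
  stopifnot(is(ranges, "SpeciesRangeSet"))
  boundaries <- match.arg(boundaries)
  if (missing(seed) || !is.finite(seed))
    stop("a seed is required for the range shuffle", call. = FALSE)
  reps <- as.integer(reps)
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  sizes <- as.integer(ranges@ranges$size)
  if (!length(sizes)) stop("no species ranges to shuffle", call. = FALSE)
  n <- ranges@domain@nBands
  if (boundaries == "hard" && any(sizes > n))
    stop("a range exceeds the domain: infeasible under hard boundaries",
         call. = FALSE)
  set.seed(as.integer(seed))
  rich <- matrix(0L, reps, n)
  for (r in seq_len(reps))
    rich[r, ] <- .placeRanges(sizes, n, boundaries)
  q <- apply(rich, 2, stats::quantile, probs = c(0.025, 0.975), type = 7)
  bands <- bandBounds(ranges@domain)
  bands$mean <- colMeans(rich)
  bands$q025 <- q[1, ]
  bands$q975 <- q[2, ]
  new("MDEEnvelope", bands = bands, reps = reps, boundaries = boundaries,
      seed = as.integer(seed), nSpecies = length(sizes))
}

#' Compare observed site richness against the null envelope
#'
#' Maps each site's elevation to its domain band and classifies observed
#' richness against the envelope's 2.5% / 97.5% percentiles. The interval
#' is closed: an observation exactly on a percentile counts as `"within"`.
#'
#' @param observed data.frame with columns `site`, `elevation` (m) and
#'   `richness` (e.g., from [diversityProfile()]).
#' @param envelope an [MDEEnvelope-class].
#' @param domain the [ElevationDomain-class] the envelope was built on.
#' @return data.frame with `site`, `elevation`, `band`, `observed`,
#'   `mean`, `q025`, `q975`, `position` (`"below"`/`"within"`/`"above"`).
#' @export
compareObserved <- function(observed, envelope, domain) {
  stopifnot(is(envelope, "MDEEnvelope"), is(domain, "ElevationDomain"))
  need <- c("site", "elevation", "richness")
  miss <- setdiff(need, names(observed))
  if (length(miss))
    stop("observed missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  band <- elevationToBand(domain, observed$elevation)
  env <- envelope@bands[band, , drop = FALSE]
  pos <- ifelse(observed$richness < env$q025, "below",
                ifelse(observed$richness > env$q975, "above", "within"))
  data.frame(site = observed$site, elevation = observed$elevation,
             band = band, observed = observed$richness,
             mean = env$mean, q025 = env$q025, q975 = env$q975,
             position = pos, stringsAsFactors = FALSE, row.names = NULL)
}
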