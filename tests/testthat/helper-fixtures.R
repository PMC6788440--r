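## Shared fixtures, built in code.

toyPath <- function(f) system.file("extdata", f, package = "elevdiv")

readToySurvey <- function() {
  readSurvey(toyPath("toy_records.csv"), toyPath("toy_efforts.csv"),
             toyPath("toy_species.csv"))
}

## a CommunityMatrix straight from counts (one mountain unless given)
makeCM <- function(counts, elevation = seq_len(nrow(counts)) * 100,
                   mountain = "M") {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("s", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sp", seq_len(ncol(counts)))
  storage.mode(counts) <- "integer"
  mtn <- rep(mountain, length.out = nrow(counts))
  sdat <- data.frame(site = rownames(counts), mountain = mtn,
                     location = rownames(counts), elevation = elevation,
                     stringsAsFactors = FALSE)
  new("CommunityMatrix", counts = counts, siteData = sdat)
}

## random incidence matrix with no empty species column
randomIncidence <- function(nSites, nSpecies, p = 0.4) {
  m <- matrix(stats::runif(nSites * nSpecies) < p, nSites, nSpecies,
              dimnames = list(paste0("s", seq_len(nSites)),
                              paste0("sp", seq_len(nSpecies))))
  m[, colSums(m) > 0, drop = FALSE]
}

## exact per-band expected richness under the hard-boundary placement:
## start band uniform over the feasible positions
exactHardMean <- function(sizes, nBands) {
  sapply(seq_len(nBands), function(b) {
    sum(sapply(sizes, function(s) {
      starts <- seq_len(nBands - s + 1L)
      mean(b >= starts & b <= starts + s - 1L)
    }))
  })
}

## exact per-band expected richness under the soft-boundary placement:
## midpoint uniform over all bands, half-size extension, truncation,
## fair coin for the odd band of even sizes
exactSoftMean <- function(sizes, nBands) {
  sapply(seq_len(nBands), function(b) {
    sum(sapply(sizes, function(s) {
      half <- (s - 1L) %/% 2L
      cover <- sapply(seq_len(nBands), function(m) {
        if (s %% 2L == 1L) {
          (b >= max(1L, m - half)) && (b <= min(nBands, m + half))
        } else {
          up <- (b >= max(1L, m - half)) && (b <= min(nBands, m + half + 1L))
          dn <- (b >= max(1L, m - half - 1L)) && (b <= min(nBands, m + half))
          (up + dn) / 2
        }
      })
      mean(cover)
    }))
  })
}
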