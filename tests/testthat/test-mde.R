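mkRanges <- function(sizes, nBands, width = 50) {
  dom <- elevationDomain("t", 0, nBands * width, width)
  lo <- rep(1L, length(sizes))
  hi <- as.integer(sizes)
  new("SpeciesRangeSet", domain = dom,
      ranges = data.frame(species = paste0("sp", seq_along(sizes)),
                          lowBand = lo, highBand = hi,
                          size = as.integer(sizes)))
}

test_that("discretizeRanges spans min to max capture band on the trapped extent", {
  rec <- data.frame(
    species = c("wide", "wide", "point", "same", "same"),
    mountain = "K",
    location = c("800", "3400", "1000", "600", "600"),
    elevation = c(836, 3382, 1000, 610, 640),
    trap_class = "ground", recapture = FALSE)
  ds <- suppressWarnings(surveyDataset(rec))
  dom <- elevationDomain("K", 503, 3466, 50)
  rs <- discretizeRanges(ds, bandWidth = 50, domain = dom)
  r <- rs@ranges

  ## a species caught at 836 and 3,382 m occupies every band intersecting
  ## [836, 3382]
  wide <- r[r$species == "wide", ]
  expect_equal(wide$lowBand, floor((836 - 503) / 50) + 1)
  expect_equal(wide$highBand, floor((3382 - 503) / 50) + 1)
  bb <- bandBounds(dom)
  covered <- bb$band[bb$hi > 836 & bb$lo <= 3382]
  expect_equal(wide$lowBand:wide$highBand, covered)

  ## single capture and two captures in one band both give size 1
  expect_equal(r$size[r$species == "point"], 1)
  expect_equal(r$size[r$species == "same"], 1)

  ## a point species at 1,000 m on a 0-2,000 m domain sits in the 21st
  ## 50 m band (1-based)
  ds_pt <- suppressWarnings(surveyDataset(rec[rec$species == "point", ]))
  dom2 <- elevationDomain("K", 0, 2000, 50)
  rs2 <- discretizeRanges(ds_pt, bandWidth = 50, domain = dom2)
  expect_equal(rs2@ranges$lowBand, 21)
  expect_equal(rs2@ranges$size, 1)

  expect_error(discretizeRanges(ds, bandWidth = -5), "bandWidth")
  ## domain tiles the extent completely
  expect_equal(nrow(bb), dom@nBands)
  expect_true(bb$hi[nrow(bb)] >= dom@maxElev)
})

test_that("range shuffle preserves range sizes and honours boundary rules", {
  ## single species spanning the whole domain, hard boundaries: richness is
  ## exactly 1 everywhere
  rs <- mkRanges(8, 8)
  env <- rangeShuffle(rs, reps = 50, boundaries = "hard", seed = 1)
  expect_equal(env@bands$mean, rep(1, 8))
  expect_equal(env@bands$q025, rep(1, 8))
  expect_equal(env@bands$q975, rep(1, 8))

  ## n full-domain species: richness n everywhere
  rs5 <- mkRanges(rep(8, 5), 8)
  env5 <- rangeShuffle(rs5, reps = 50, boundaries = "hard", seed = 1)
  expect_equal(env5@bands$mean, rep(5, 8))

  ## range-size conservation under hard boundaries: summed mean richness
  ## equals summed range sizes exactly (every replicate conserves incidences)
  sizes <- c(2, 3, 5, 7)
  envc <- rangeShuffle(mkRanges(sizes, 8), reps = 400, boundaries = "hard",
                       seed = 3)
  expect_equal(sum(envc@bands$mean), sum(sizes))
  ## under soft boundaries truncation can only lose bands
  envs <- rangeShuffle(mkRanges(sizes, 8), reps = 400, boundaries = "soft",
                       seed = 3)
  expect_lte(sum(envs@bands$mean), sum(sizes))

  ## a range wider than its domain cannot even be constructed
  expect_error(mkRanges(9, 8), "within the domain")
  expect_error(rangeShuffle(rs, reps = 0, seed = 1), "reps")
  expect_error(rangeShuffle(rs, reps = 10), "seed")
})

test_that("Monte-Carlo band means converge to exact enumeration (<= 8 bands)", {
  cases <- list(list(sizes = c(3, 4, 8), n = 8),
                list(sizes = c(1, 2, 5, 6), n = 7),
                list(sizes = c(2, 2, 3), n = 5))
  for (cs in cases) {
    reps <- 8000
    for (rule in c("hard", "soft")) {
      env <- rangeShuffle(mkRanges(cs$sizes, cs$n), reps = reps,
                          boundaries = rule, seed = 17)
      exact <- if (rule == "hard") exactHardMean(cs$sizes, cs$n)
               else exactSoftMean(cs$sizes, cs$n)
      ## binomial standard error per band, summed over independent species
      se <- sapply(seq_len(cs$n), function(b) {
        pb <- sapply(cs$sizes, function(s) {
          e1 <- if (rule == "hard") exactHardMean(s, cs$n)[b]
                else exactSoftMean(s, cs$n)[b]
          e1
        })
        sqrt(sum(pb * (1 - pb)) / reps)
      })
      expect_true(all(abs(env@bands$mean - exact) <= 3 * se + 1e-9),
                  info = paste(rule, "boundaries"))
    }
  }
})

test_that("hard-boundary expected richness is symmetric about the domain centre", {
  for (s in c(1, 2, 3, 5)) {
    exact <- exactHardMean(s, 7)
    expect_equal(exact, rev(exact))
    env <- rangeShuffle(mkRanges(s, 7), reps = 6000, boundaries = "hard",
                        seed = 5)
    expect_equal(env@bands$mean, rev(env@bands$mean), tolerance = 0.05)
  }
})

test_that("the shuffle is deterministic under a fixed seed", {
  rs <- mkRanges(c(2, 4, 6), 10)
  e1 <- rangeShuffle(rs, reps = 300, seed = 11)
  e2 <- rangeShuffle(rs, reps = 300, seed = 11)
  expect_identical(e1@bands, e2@bands)
  e3 <- rangeShuffle(rs, reps = 300, seed = 12)
  expect_false(identical(e1@bands$mean, e3@bands$mean))
})

test_that("observed richness is classified against the closed envelope interval", {
  dom <- elevationDomain("t", 0, 300, 50)
  bands <- bandBounds(dom)
  bands$mean <- rep(8, 6); bands$q025 <- rep(5, 6); bands$q975 <- rep(11, 6)
  env <- new("MDEEnvelope", bands = bands, reps = 100L, boundaries = "soft",
             seed = 1L, nSpecies = 12L)
  obs <- data.frame(site = c("a", "b", "c", "d"),
                    elevation = c(25, 75, 125, 175),
                    richness = c(11, 19, 4, 7))
  cmp <- compareObserved(obs, env, dom)
  ## a value exactly on the 97.5% percentile is "within" (closed interval)
  expect_equal(cmp$position, c("within", "above", "below", "within"))
  expect_error(compareObserved(
    data.frame(site = "x", elevation = 999, richness = 1), env, dom),
    "outside the domain")
})
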