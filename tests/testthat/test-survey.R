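test_that("readSurvey round-trips the toy fixture and enforces the schema", {
  ds <- readToySurvey()
  expect_s4_class(ds, "SurveyDataset")
  expect_equal(nrow(records(ds)), 12)
  expect_equal(nrow(speciesMeta(ds)), 7)

  bad <- tempfile(fileext = ".csv")
  rec <- records(ds)
  utils::write.csv(rec[, setdiff(names(rec), "species")], bad,
                   row.names = FALSE)
  expect_error(readSurvey(bad), "species")

  rec2 <- rec
  rec2$elevation[3] <- -10
  utils::write.csv(rec2, bad, row.names = FALSE)
  expect_error(readSurvey(bad), "elevation")

  expect_error(readSurvey(tempfile()), "not found")
  ## unknown species get metadata with a warning
  expect_warning(surveyDataset(rec[, names(rec) != "record_id"]),
                 "unknown")
})

test_that("filterRecords drops trap classes and recaptures, with matching effort", {
  ds <- readToySurvey()
  f <- filterRecords(ds)
  rec <- records(f)
  expect_equal(nrow(rec), 9)   # 12 - arboreal - pitfall - recapture
  expect_true(all(rec$trap_class == "ground"))
  expect_false(any(rec$recapture))
  expect_equal(sum(efforts(f)$trap_nights), 900)  # arboreal+pitfall nights gone

  ## identity when everything is kept
  all_in <- filterRecords(ds, TRUE, TRUE, TRUE)
  expect_equal(records(all_in), records(ds))
  expect_equal(efforts(all_in), efforts(ds))

  ## idempotence
  f2 <- filterRecords(f)
  expect_equal(records(f2), records(f))
  expect_equal(efforts(f2), efforts(f))

  ## provenance grows monotonically
  expect_length(provenance(f2), length(provenance(ds)) + 2)
})

test_that("published effort totals filter from 213/2,044 to 209/2,022 nights", {
  ds <- studySurveyFromTables()
  kin <- function(d) {
    r <- records(d); e <- efforts(d)
    c(n = sum(r$mountain == "Kinabalu"),
      nights = sum(e$trap_nights[e$mountain == "Kinabalu"]))
  }
  expect_equal(kin(ds), c(n = 213, nights = 2044))
  expect_equal(kin(filterRecords(ds)), c(n = 209, nights = 2022))
})

test_that("buildAbundanceMatrix cross-tabulates deterministically and conserves counts", {
  ds <- filterRecords(readToySurvey())
  cm <- buildAbundanceMatrix(ds)
  expect_equal(counts(cm)["Toy / 500", "Maxomys whiteheadi"], 2)
  ## shared species appears once, in several sites
  expect_equal(sum(colnames(counts(cm)) == "Rattus baluensis"), 1)
  expect_equal(sum(counts(cm)[, "Rattus baluensis"] > 0), 2)
  ## ordering: mountain, then nominal elevation ascending
  expect_equal(siteData(cm)$site, c("Toy / 500", "Toy / 1500", "Toy / 2400"))
  ## count conservation
  expect_equal(sum(counts(cm)), nrow(records(ds)))
  expect_equal(unname(rowSums(counts(cm))),
               as.vector(table(factor(paste(records(ds)$mountain,
                                            records(ds)$location,
                                            sep = " / "),
                                      levels = siteData(cm)$site))))
  ## incidence derives from counts
  expect_identical(incidence(cm), counts(cm) > 0)
  expect_error(buildAbundanceMatrix(filterRecords(ds) |>
    (\(d) new("SurveyDataset", records = records(d)[0, ],
              efforts = efforts(d), meta = speciesMeta(d),
              provenance = "x"))()), "empty")
})

test_that("abundance-matrix row sums match the generator's capture bookkeeping", {
  sim <- simulateSurvey(syntheticConfig(nSpecies = 10L, richnessSlope = -2,
                                        seed = 33L))
  ds <- filterRecords(sim$dataset)
  cm <- buildAbundanceMatrix(ds)
  truth <- sim$truth$sites
  truth_key <- paste(truth$mountain, truth$location, sep = " / ")
  expect_equal(unname(rowSums(counts(cm))),
               truth$n_captures[match(siteData(cm)$site, truth_key)])
})

test_that("trapSuccess reports captures per 100 trap nights, internally consistent", {
  ds <- filterRecords(readToySurvey())
  ts <- trapSuccess(ds)
  expect_equal(ts$percent[ts$group == "Toy / 500"], 100 * 4 / 300,
               tolerance = 0.05)
  ## internal consistency: percent recomputes from its own row
  expect_equal(ts$percent,
               round(100 * ts$n_captures / ts$trap_nights + 1e-9, 1))
  ## zero captures with effort -> 0.0, not NA
  eff0 <- rbind(efforts(ds),
                data.frame(mountain = "Toy", location = "3000",
                           trap_class = "ground", trap_nights = 100))
  ds0 <- new("SurveyDataset", records = records(ds), efforts = eff0,
             meta = speciesMeta(ds), provenance = "x")
  ts0 <- trapSuccess(ds0)
  expect_equal(ts0$percent[ts0$group == "Toy / 3000"], 0)
  ## captures without any effort is a consistency error
  eff_bad <- efforts(ds)[efforts(ds)$location != "1500", ]
  ds_bad <- new("SurveyDataset", records = records(ds), efforts = eff_bad,
                meta = speciesMeta(ds), provenance = "x")
  expect_error(trapSuccess(ds_bad), "zero trap nights")
})

test_that("accumulation curves are monotone and end at site richness", {
  ds <- readToySurvey()
  ac <- accumulationCurve(ds, "Toy / 500")
  expect_true(all(diff(ac$cum_trap_nights) >= 0))
  expect_true(all(diff(ac$cum_richness) >= 0))
  expect_equal(max(ac$cum_richness), 5)  # site richness, all trap classes

  ## no captures -> flat zero curve
  ac0 <- accumulationCurve(ds, "Toy / 9999", nTraps = 10, nDays = 3)
  expect_equal(ac0$cum_richness, c(0, 0, 0))

  ## missing capture_day is an explicit unsupported-input error
  rec <- records(ds)
  rec$capture_day[1] <- NA
  dsNA <- new("SurveyDataset", records = rec, efforts = efforts(ds),
              meta = speciesMeta(ds), provenance = "x")
  expect_error(accumulationCurve(dsNA, "Toy / 500"), "capture_day")

  ## property: random event logs replayed by a brute-force oracle
  set.seed(41)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    days <- sample.int(10, n, replace = TRUE)
    sp <- sample(letters[1:8], n, replace = TRUE)
    rec <- data.frame(species = sp, mountain = "X", location = "L",
                      elevation = 100, trap_class = "ground",
                      recapture = FALSE, capture_day = days)
    dsr <- suppressWarnings(surveyDataset(rec))
    ac <- accumulationCurve(dsr, "X / L", nTraps = 40, nDays = 10)
    oracle <- sapply(1:10, function(d) length(unique(sp[days <= d])))
    expect_equal(ac$cum_richness, oracle)
    expect_equal(ac$cum_richness[10], length(unique(sp)))
  }
})

test_that("camera relative abundance reproduces the published per-100-night rates", {
  out <- cameraRelativeAbundance(studyCameraTable())
  expect_equal(out$rate[out$species == "Macaca nemestrina"], 2.38)
  expect_equal(out$rate[out$common_name == "Common Porcupine"], 4.76)
  expect_equal(out$rate[out$camera_id == 4 & out$species == "Paguma larvata"],
               3.45)
  zero <- cameraRelativeAbundance(
    data.frame(camera_id = 1, elevation = 500, species = "x",
               n_series = 0, camera_nights = 42))
  expect_equal(zero$rate, 0)
  expect_error(cameraRelativeAbundance(
    data.frame(camera_id = 1, elevation = 1, species = "x",
               n_series = 1, camera_nights = 0)), "camera_nights")
})
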