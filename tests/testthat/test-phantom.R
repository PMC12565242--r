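test_that("PhantomSpec validity enforces the slice schedule", {
  expect_error(PhantomSpec(apicalOnset = 30L, bifurcation = 20L),
               "schedule")
  expect_error(PhantomSpec(disappearance = 80L, nSlices = 75L), "schedule")
  expect_error(PhantomSpec(fibrosisSeverity = 1.5), "fibrosisSeverity")
  expect_s4_class(tinySpec(), "PhantomSpec")
})

test_that("pmGroundTruth places the lower PM three slices above disappearance", {
  pm <- pmGroundTruth(PhantomSpec(apicalOnset = 6, bifurcation = 31,
                                  disappearance = 63))
  expect_identical(pmIndices(pm),
                   c(upper = 6L, middle = 31L, lower = 60L))
  expect_error(
    pmGroundTruth(PhantomSpec(apicalOnset = 2, bifurcation = 10,
                              disappearance = 12, nSlices = 20)),
    "compressed")
})

test_that("generatePhantomVolume is deterministic given the spec seed", {
  a <- generatePhantomVolume(tinySpec(seed = 7))
  b <- generatePhantomVolume(tinySpec(seed = 7))
  expect_identical(a@volume@slices, b@volume@slices)
  c <- generatePhantomVolume(tinySpec(seed = 8))
  expect_false(identical(a@volume@slices, c@volume@slices))
})

test_that("phantom renders the expected gross anatomy", {
  pc <- tinyCase(seed = 3)
  s <- pc@spec@imageSize
  sl <- getSlice(pc, pc@spec@bifurcation + 2L)
  expect_identical(dim(sl), c(s, s))
  expect_lt(sl[1, 1], -1500)                    # corner outside the FOV
  expect_gt(sl[round(s / 2), 2], -1100)         # FOV air at the border
  mid <- round((s + 1) / 2)
  lungX <- round(mid + 0.23 * s)
  expect_lt(sl[mid, lungX], -500)               # aerated lung
  preLung <- getSlice(pc, pc@spec@apicalOnset - 1L)
  expect_gt(preLung[mid, lungX], -500)          # body tissue before onset
})

test_that("aerated lung area follows the schedule and ignores tracheal air", {
  pc <- tinyCase(seed = 4)
  area <- aeratedLungArea(pc@volume)
  on <- pc@spec@apicalOnset; dis <- pc@spec@disappearance
  expect_true(all(area[seq_len(on - 1L)] == 0))
  expect_true(all(area[on:(dis - 1L)] > 0))
  expect_true(all(area[dis:length(area)] == 0))
})

test_that("derivePM recovers the generating schedule from voxels", {
  for (seed in c(11, 12)) {
    for (sev in c(0, 0.9)) {
      pc <- tinyCase(seed = seed, fibrosisSeverity = sev)
      expect_identical(pmIndices(derivePM(pc@volume)),
                       stats::setNames(pmIndices(pc@pmTruth),
                                       c("upper", "middle", "lower")))
    }
  }
})

test_that("fibrosis texture raises HU only in basal subpleural lung", {
  specPos <- tinySpec(seed = 5, fibrosisSeverity = 1)
  specNeg <- tinySpec(seed = 5, fibrosisSeverity = 0)
  pos <- generatePhantomVolume(specPos, label = 1L)
  neg <- generatePhantomVolume(specNeg, label = 0L)
  basal <- specPos@bifurcation +
    (specPos@disappearance - specPos@bifurcation) %/% 3L + 2L
  apicalish <- specPos@apicalOnset + 3L
  dBasal <- getSlice(pos, basal) - getSlice(neg, basal)
  dApex <- getSlice(pos, apicalish) - getSlice(neg, apicalish)
  expect_gt(max(dBasal), 100)
  expect_equal(max(abs(dApex)), 0)
})

test_that("generateCohort is deterministic, labelled and jittered", {
  base <- tinySpec()
  co <- generateCohort(8, prevalence = 0.5, baseSpec = base, seed = 3)
  co2 <- generateCohort(8, prevalence = 0.5, baseSpec = base, seed = 3)
  expect_identical(lapply(co, function(x) x@volume@slices),
                   lapply(co2, function(x) x@volume@slices))
  labs <- vapply(co, caseLabel, integer(1))
  expect_true(all(labs %in% c(0L, 1L)))
  sev <- vapply(co, function(x) x@spec@fibrosisSeverity, numeric(1))
  expect_true(all(sev[labs == 1L] >= 0.7))
  expect_true(all(sev[labs == 0L] == 0))
  ids <- vapply(co, caseID, character(1))
  expect_identical(ids, sprintf("case_%04d", 1:8))
  schedules <- t(vapply(co, function(x)
    c(x@spec@apicalOnset, x@spec@bifurcation, x@spec@disappearance),
    integer(3)))
  expect_gt(nrow(unique(schedules)), 1L)
})

test_that("phantom case round-trips through PNG + JSON on disk", {
  pc <- tinyCase(seed = 6, fibrosisSeverity = 0.8)
  dir <- withr::local_tempdir()
  writePhantomCase(pc, dir)
  back <- readPhantomCase(dir)
  expect_identical(caseID(back$volume), caseID(pc))
  expect_identical(pmIndices(back$pm), pmIndices(pc@pmTruth))
  expect_identical(back$label, pc@label)
  ## 16-bit quantisation: HU error bounded by half a step of 65535/2048 scale
  err <- max(abs(getSlice(back$volume, 10) - getSlice(pc, 10)))
  expect_lt(err, 0.51)
})
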