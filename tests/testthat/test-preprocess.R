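test_that("applyWindow matches the affine-clip formula and edge cases", {
  w <- WindowSpec(-700, 700, "enhanced_lung")
  ## below the lower edge -> 0; above the upper edge -> 255
  expect_identical(applyWindow(matrix(c(-1100, -1050)), w),
                   matrix(c(0L, 0L)))
  expect_identical(applyWindow(matrix(c(-350, 100)), w),
                   matrix(c(255L, 255L)))
  ## window level maps to the midpoint
  expect_identical(applyWindow(matrix(-700), w), matrix(128L))
  ## formula check against a hand computation
  hu <- matrix(c(-900, -800, -600, -400), 2)
  want <- roundHalfAway(255 * pmin(pmax((hu + 1050) / 700, 0), 1))
  got <- applyWindow(hu, w)
  expect_equal(as.numeric(got), as.numeric(want))
  ## monotone non-decreasing in HU
  hu <- matrix(sort(runif(100, -1200, 300)), 1)
  out <- applyWindow(hu, w)
  expect_true(all(diff(as.numeric(out)) >= 0))
})

test_that("the three identification windows have the stated parameters", {
  wins <- identificationWindows()
  lv <- vapply(wins, function(w) w@level, numeric(1))
  wd <- vapply(wins, function(w) w@width, numeric(1))
  expect_identical(lv, c(-700, 100, 40))
  expect_identical(wd, c(700, 700, 400))
})

test_that("rgbWindowing stacks the three windows in channel order", {
  pc <- tinyCase(seed = 2)
  hu <- getSlice(pc, 20)
  comp <- rgbWindowing(hu, size = nrow(hu))  # no resize
  expect_identical(dim(comp), c(nrow(hu), ncol(hu), 3L))
  wins <- identificationWindows()
  for (k in 1:3) {
    expect_identical(comp[, , k], applyWindow(hu, wins[[k]]))
  }
  expect_true(all(comp >= 0 & comp <= 255))
})

test_that("rgbWindowing resize orders are both available and 8-bit valid", {
  pc <- tinyCase(seed = 2)
  hu <- getSlice(pc, 20)
  a <- rgbWindowing(hu, size = 32L, order = "window_first")
  b <- rgbWindowing(hu, size = 32L, order = "resize_first")
  expect_identical(dim(a), c(32L, 32L, 3L))
  expect_identical(dim(b), c(32L, 32L, 3L))
  expect_true(all(a >= 0 & a <= 255) && all(b >= 0 & b <= 255))
  ## resize_first equals windowing of the resized HU image exactly
  hs <- as.matrix(EBImage::resize(hu, w = 32, h = 32))
  expect_identical(b[, , 1], applyWindow(hs, identificationWindows()[[1]]))
})

test_that("deriveScannerMask keeps the largest above-sentinel component", {
  pc <- tinyCase(seed = 2)
  mask <- deriveScannerMask(list(pc@volume), provenance = "test")
  expect_s4_class(mask, "ScannerMask")
  s <- nrow(mask@mask)
  mid <- round((s + 1) / 2)
  expect_identical(mask@mask[mid, mid], 1)      # centre inside the FOV
  expect_identical(mask@mask[1, 1], 0)          # corner outside
  expect_identical(mask@provenance, "test")
  ## single connected component
  lab <- EBImage::bwlabel(mask@mask)
  expect_identical(as.integer(max(lab)), 1L)
})

test_that("applyScannerMask fills outside pixels and resamples when needed", {
  pc <- tinyCase(seed = 2)
  mask <- deriveScannerMask(list(pc@volume))
  hu <- getSlice(pc, 20)
  out <- applyScannerMask(hu, mask)
  expect_identical(out[1, 1], -1024)
  inside <- mask@mask == 1
  expect_identical(out[inside], hu[inside])
  ## composed with a window whose low edge is above the fill value,
  ## a masked corner maps to 0 (fill -1024 < low edge -1000)
  expect_identical(applyWindow(out, WindowSpec(-500, 1000))[1, 1], 0L)
  ## shape mismatch: resampled by default, error when disallowed
  big <- matrix(-2000, 128, 128)
  expect_silent(applyScannerMask(big, mask))
  expect_error(applyScannerMask(big, mask, allowResample = FALSE), "shape")
})

test_that("DICOM series round-trips HU exactly and sorts by z position", {
  pc <- tinyCase(seed = 9)
  dir <- withr::local_tempdir()
  paths <- writeDicomSeries(pc@volume, dir)
  back <- loadDicomSeries(dir, siteTag = "roundtrip")
  expect_identical(nSlices(back), nSlices(pc))
  for (m in c(1L, 17L, nSlices(pc))) {
    expect_equal(getSlice(back, m), round(getSlice(pc, m)))
  }
  expect_identical(back@siteTag, "roundtrip")
  ## shuffled file names must not change the recovered order
  dir2 <- withr::local_tempdir()
  file.copy(list.files(dir, full.names = TRUE), dir2)
  files <- list.files(dir2, pattern = "\\.dcm$", full.names = TRUE)
  set.seed(4)
  file.rename(files, file.path(dir2, sprintf("shuf_%04d.dcm",
                                             sample(seq_along(files)))))
  back2 <- loadDicomSeries(dir2)
  expect_equal(back2@slices, back@slices)
})

test_that("loadDicomSeries rejects mixed series and bad geometry", {
  a <- tinyCase(seed = 9)
  dir <- withr::local_tempdir()
  writeDicomSeries(a@volume, dir, seriesUID = "1.2.3.1")
  sub <- generatePhantomVolume(tinySpec(seed = 10))
  tmp <- withr::local_tempdir()
  writeDicomSeries(sub@volume, tmp, seriesUID = "1.2.3.2")
  one <- list.files(tmp, full.names = TRUE)[1]
  file.copy(one, file.path(dir, "intruder.dcm"))
  expect_error(loadDicomSeries(dir), "more than one series")
})

test_that("rescale slope and intercept are honoured", {
  pc <- tinyCase(seed = 9)
  dir <- withr::local_tempdir()
  writeDicomSeries(pc@volume, dir, slope = 2, intercept = -1000)
  back <- loadDicomSeries(dir)
  want <- round((getSlice(pc, 5) + 1000) / 2) * 2 - 1000
  expect_equal(getSlice(back, 5), want)
})

test_that("exportPMSlices writes PNGs plus a manifest", {
  pc <- tinyCase(seed = 2)
  dir <- withr::local_tempdir()
  exportPMSlices(pc@volume, dir, size = 64L, pm = pc@pmTruth,
                 label = caseLabel(pc))
  pngs <- list.files(dir, pattern = "slice_\\d+\\.png$")
  expect_length(pngs, nSlices(pc))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_identical(man$case_id, caseID(pc))
  expect_identical(man$n_slices, nSlices(pc))
  expect_identical(man$pm$middle, pc@spec@bifurcation)
})
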