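test_that("extractRS reproduces the worked examples", {
  pm <- PMAnnotation(1, 31, 61)
  expect_identical(rsIndices(extractRS(pm, 3, M = 75)),
                   c(11L, 31L, 41L))
  expect_identical(rsIndices(extractRS(pm, 5, M = 75)),
                   c(11L, 21L, 31L, 41L, 51L))
  expect_identical(rsIndices(extractRS(pm, 9, M = 75)),
                   c(10L, 11L, 12L, 30L, 31L, 32L, 40L, 41L, 42L))
})

test_that("extractRS rounds fractional positions half away from zero", {
  ## intervals 5 and 7: 5/3 = 1.67 -> 2, 7/3 = 2.33 -> 2
  pm <- PMAnnotation(10, 15, 22)
  expect_identical(rsIndices(extractRS(pm, 3, M = 40)),
                   c(12L, 15L, 17L))
  ## 2*5/3 = 3.33 -> 3; 2*7/3 = 4.67 -> 5
  expect_identical(rsIndices(extractRS(pm, 5, M = 40)),
                   c(12L, 13L, 15L, 17L, 20L))
})

test_that("RS sets are translation equivariant", {
  pm <- PMAnnotation(4, 19, 37)
  for (k in c(1L, 5L, 11L)) {
    shifted <- PMAnnotation(4 + k, 19 + k, 37 + k)
    for (st in c(3, 5, 9)) {
      expect_identical(rsIndices(extractRS(shifted, st, M = 80)),
                       rsIndices(extractRS(pm, st, M = 80)) + k)
    }
  }
})

test_that("RS indices are contained in [upper, lower] and sorted", {
  set.seed(31)
  for (i in 1:50) {
    u <- sample(1:20, 1)
    m <- u + sample(6:25, 1)
    ## lower span >= 8 keeps the three 9-RS triplets disjoint
    l <- m + sample(8:25, 1)
    pm <- PMAnnotation(u, m, l)
    for (st in c(3, 5, 9)) {
      idx <- rsIndices(extractRS(pm, st, M = l + 3L))
      expect_true(all(idx >= u & idx <= l))
      expect_true(all(diff(idx) > 0))
      expect_length(idx, st)
    }
  }
})

test_that("RS3 is nested in RS5 and RS9", {
  set.seed(32)
  for (i in 1:25) {
    u <- sample(1:15, 1)
    m <- u + sample(9:21, 1)
    l <- m + sample(9:21, 1)
    pm <- PMAnnotation(u, m, l)
    r3 <- rsIndices(extractRS(pm, 3, M = 90))
    r5 <- rsIndices(extractRS(pm, 5, M = 90))
    r9 <- rsIndices(extractRS(pm, 9, M = 90))
    expect_true(all(r3 %in% r5))
    expect_true(all(r3 %in% r9))
    expect_identical(r3[2], m)  # shared middle PM
  }
})

test_that("degenerate PM spacing errors instead of silently repairing", {
  expect_error(extractRS(PMAnnotation(1, 2, 3), 5, M = 10), "too close")
  expect_error(extractRS(PMAnnotation(1, 2, 4), 9, M = 10), "too close")
  expect_error(extractRS(PMAnnotation(5, 10, 15), 4, M = 20), "3, 5 or 9")
  expect_error(extractRS(PMAnnotation(5, 10, 30), 3, M = 20), "outside")
})

test_that("9-RS stays in [1, M] at the volume border", {
  ## upper PM at slice 1, first 3-RS slice at 2: its upper neighbour is 1
  pm <- PMAnnotation(1, 5, 14)
  r9 <- rsIndices(extractRS(pm, 9, M = 17))
  expect_true(all(r9 >= 1L & r9 <= 17L))
  expect_identical(min(r9), 1L)
  ## a neighbour pushed past the border collapses onto the clamped slice,
  ## which is an error rather than a silent repair
  expect_error(extractRS(PMAnnotation(1, 2, 20), 9, M = 25), "too close")
})

test_that("stackRSVolume produces the T x size x size x 3 composite", {
  pc <- tinyCase(seed = 2)
  rs <- extractRS(pc@pmTruth, 3, M = nSlices(pc))
  st <- stackRSVolume(pc@volume, rs, size = 32L)
  expect_identical(dim(st), c(3L, 32L, 32L, 3L))
  expect_true(all(st >= 0 & st <= 255))
  ## slice t of the stack equals the composite of RS slice t
  idx <- rsIndices(rs)
  want <- rgbWindowing(getSlice(pc, idx[2]), size = 32L)
  expect_equal(array(st[2, , , ], dim(want)), want, tolerance = 1e-12)
})

test_that("randomSliceBaseline is seeded and strictly increasing", {
  a <- randomSliceBaseline(40, 5, seed = 3)
  b <- randomSliceBaseline(40, 5, seed = 3)
  expect_identical(a, b)
  expect_true(all(diff(a) > 0))
  expect_length(unique(randomSliceBaseline(9, 9, seed = 1)), 9L)
})
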