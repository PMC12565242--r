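test_that("roundHalfAway rounds halves away from zero", {
  expect_identical(roundHalfAway(c(0.5, 1.5, 2.5, -0.5, -1.5)),
                   c(1, 2, 3, -1, -2))
  expect_identical(roundHalfAway(c(0.49, -0.49, 2, -3)), c(0, 0, 2, -3))
  expect_identical(roundHalfAway(10 / 3), 3)
  expect_identical(roundHalfAway(20 / 3), 7)
})

test_that("withSeed restores the caller RNG state", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  x <- withSeed(99, runif(5))
  b <- runif(1)
  expect_identical(a, b)
  expect_identical(x, withSeed(99, runif(5)))
})

test_that("childSeed is deterministic and label-sensitive", {
  expect_identical(childSeed(1L, "a"), childSeed(1L, "a"))
  expect_false(childSeed(1L, "a") == childSeed(1L, "b"))
  expect_false(childSeed(1L, "a") == childSeed(2L, "a"))
  expect_true(childSeed(.Machine$integer.max, "x") < 2^31)
})
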