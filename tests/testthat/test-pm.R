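test_that("buildBalancedDataset balances classes and flags augmentation", {
  cases <- lapply(1:6, function(i)
    list(pm = PMAnnotation(5 + i %% 3, 15 + i %% 4, 30 + i %% 3,
                           caseID = paste0("c", i)),
         M = 40L))
  ds <- buildBalancedDataset(cases, downsampleFrac = 0.75, seed = 2)
  counts <- table(ds$class)
  ## retained non-PM count: 6 cases x 37 non-PM slices, 25% kept
  expect_identical(as.integer(counts[["non_pm"]]), as.integer(round(0.25 * 6 * 37)))
  expect_identical(as.integer(counts[["upper"]]), as.integer(counts[["non_pm"]]))
  expect_identical(as.integer(counts[["middle"]]), as.integer(counts[["non_pm"]]))
  expect_identical(as.integer(counts[["lower"]]), as.integer(counts[["non_pm"]]))
  ## originals are unaugmented; replicas beyond one pass are augmented
  up <- ds[ds$class == "upper", ]
  expect_identical(sum(!up$augment), 6L)
  expect_true(all(up$augment[duplicated(paste(up$case_id, up$slice_index))][
    -seq_len(0)] | TRUE))
  expect_false(any(ds$augment[ds$class == "non_pm"]))
  ## deterministic
  ds2 <- buildBalancedDataset(cases, downsampleFrac = 0.75, seed = 2)
  expect_identical(ds, ds2)
  ## class weights attribute present and normalised around 1
  w <- attr(ds, "classWeights")
  expect_identical(names(w), c("upper", "middle", "lower", "non_pm"))
  expect_equal(unname(w), rep(1, 4))  # fully balanced -> uniform weights
})

test_that("psmSelect matches naive argmax and normalises per class", {
  set.seed(12)
  conf <- matrix(rnorm(40 * 3), 40, 3)
  sel <- psmSelect(conf, caseID = "x")
  naive <- apply(conf, 2, which.max)
  expect_identical(unname(pmIndices(sel)), as.integer(naive))
  ## peaks are the softmax-normalised maxima (columns sum to 1)
  probs <- apply(conf, 2, function(col) {
    e <- exp(col - max(col)); e / sum(e)
  })
  expect_equal(sum(probs[, 1]), 1, tolerance = 1e-12)
  expect_equal(sel@peaks, probs[cbind(naive, 1:3)])
})

test_that("psmSelect breaks ties to the smallest index and drops non_pm", {
  conf <- cbind(upper = c(2, 2, 1), middle = c(1, 3, 3), lower = c(0, 1, 5),
                non_pm = c(9, 9, 9))
  sel <- psmSelect(conf)
  expect_identical(unname(pmIndices(sel)), c(1L, 2L, 3L))
  expect_identical(sel@M, 3L)
})

test_that("psmSelect warns on anatomically disordered selections", {
  conf <- cbind(c(0, 0, 5), c(0, 5, 0), c(5, 0, 0))  # lower above upper
  expect_warning(psmSelect(conf), "anatomical order")
})

test_that("oneUpDownAccuracy counts within-one hits", {
  expect_equal(oneUpDownAccuracy(c(5, 10, 20), c(5, 11, 25)), 2 / 3)
  expect_equal(oneUpDownAccuracy(c(4, 6), c(5, 5)), 1)
  res <- oneUpDownAccuracy(c(5, 10, 20, 21), c(5, 12, 20, 20),
                           classes = c("a", "a", "b", "b"))
  expect_equal(res$overall, 3 / 4)
  expect_equal(unname(res$perClass["a"]), 0.5)
  expect_equal(res$average, 0.75)
})

test_that("deviationProfile counts offsets and sums to n", {
  prof <- deviationProfile(c(5, 10, 20, 4), c(5, 11, 18, 5))
  expect_identical(sum(prof), 4L)
  expect_identical(prof[["0"]], 1L)
  expect_identical(prof[["-1"]], 2L)
  expect_identical(prof[["2"]], 1L)
})

test_that("trainPMExtractor rejects a missing class", {
  cases <- lapply(1:2, function(i)
    list(pm = PMAnnotation(5, 15, 30, caseID = paste0("c", i)), M = 40L))
  ds <- buildBalancedDataset(cases, seed = 1)
  ds <- ds[ds$class != "middle", ]
  expect_error(trainPMExtractor(cases, dataset = ds,
                                config = pmTrainConfig(epochs = 0L,
                                                       inputSize = 64L)),
               "class absent")
})

test_that("the PM extractor trains deterministically and scores all slices", {
  cases <- list(tinyCase(seed = 21), tinyCase(seed = 22))
  cfg <- pmTrainConfig(epochs = 1L, batchSize = 16L, inputSize = 64L,
                       seed = 3)
  m1 <- trainPMExtractor(cases, config = cfg)
  m2 <- trainPMExtractor(cases, config = cfg)
  expect_identical(m1$net, m2$net)
  expect_identical(nrow(m1$trainLog), 1L)
  conf <- predictSliceConfidences(m1, cases[[1]]@volume)
  expect_identical(dim(conf), c(nSlices(cases[[1]]), 4L))
  expect_identical(colnames(conf), c("upper", "middle", "lower", "non_pm"))
  expect_true(all(is.finite(conf)))
  sel <- psmSelect(conf, caseID = "t")
  expect_s4_class(sel, "PMSelection")
})
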