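## Pipeline orchestration: patient-level splitting and the staged phantom
## run (simulate -> preprocess -> train-pm -> psm -> select-rs -> train ->
## evaluate -> count-params) with manifests between stages, per-stage
## seeds, and resume-from-manifest semantics.

#' Patient-level stratified 70/15/15 split
#'
#' Validation and test sizes are \code{round(frac * n)}; train takes the
#' remainder (613 cases -> 429/92/92). Within each size the split is
#' stratified by label with largest-remainder apportionment, and case order
#' is randomised by the seed. No case ID appears in more than one split.
#'
#' @param caseIDs character vector of unique case identifiers.
#' @param labels binary labels aligned with \code{caseIDs}.
#' @param fractions train/val/test fractions summing to 1.
#' @param seed RNG seed.
#' @return list of character vectors: train, val, test.
#' @export
splitCases <- function(caseIDs, labels, fractions = c(0.70, 0.15, 0.15),
                       seed = 1L) {
  stopifnot(length(caseIDs) == length(labels),
            !anyDuplicated(caseIDs),
            abs(sum(fractions) - 1) < 1e-9)
  n <- length(caseIDs)
  labels <- as.integer(labels)
  nVal <- as.integer(round(fractions[2] * n))
  nTest <- as.integer(round(fractions[3] * n))
  if (nVal + nTest >= n) stop("split leaves no training cases")
  ## largest-remainder apportionment of a total over label strata
  apportion <- function(total, counts) {
    q <- total * counts / sum(counts)
    base <- floor(q)
    short <- total - sum(base)
    if (short > 0) {
      extra <- order(q - base, decreasing = TRUE)[seq_len(short)]
      base[extra] <- base[extra] + 1
    }
    as.integer(base)
  }
  labs <- sort(unique(labels))
  nL <- vapply(labs, function(l) sum(labels == l), integer(1))
  valL <- apportion(nVal, nL)
  testL <- apportion(nTest, nL)
  if (any(valL + testL > nL))
    stop("a label stratum is too small for the requested split")
  out <- list(train = character(0), val = character(0), test = character(0))
  withSeed(seed, {
    for (i in seq_along(labs)) {
      ids <- sample(caseIDs[labels == labs[i]])
      v <- seq_len(valL[i])
      te <- valL[i] + seq_len(testL[i])
      out$val <- c(out$val, ids[v])
      out$test <- c(out$test, ids[te])
      out$train <- c(out$train, ids[-c(v, te)])
    }
  })
  lapply(out, sort)
}

#' Default pipeline configuration
#'
#' Desk-scale defaults: a small phantom cohort, the compact CNN PM
#' extractor, a tiny ViT backbone and a matching Slider. Every field can
#' be overridden.
#'
#' @param outDir run directory (created if missing).
#' @param ... overrides of the default fields.
#' @return named list (PipelineConfig).
#' @export
pipelineConfig <- function(outDir, ...) {
  cfg <- list(
    outDir = outDir,
    seed = 1L,
    siteTag = "site_A",
    nCases = 24L,
    prevalence = 0.5,
    imageSize = 96L,
    nSlices = 48L,
    schedule = NULL,
    strategy = 5L,
    pmTrain = list(epochs = 4L, batchSize = 64L, inputSize = 96L),
    sliderTrain = list(epochs = 4L, batchSize = 8L),
    backbone = list(inputSize = 64L),
    reduction = 4L,
    fractions = c(0.70, 0.15, 0.15),
    stages = c("simulate", "preprocess", "train-pm", "psm", "select-rs",
               "train", "evaluate", "count-params"))
  utils::modifyList(cfg, list(...))
}

#' @keywords internal
#' @noRd
.stageOrder <- c("simulate", "preprocess", "train-pm", "psm", "select-rs",
                 "train", "evaluate", "count-params")

#' @keywords internal
#' @noRd
.manifestPath <- function(outDir, stage) {
  file.path(outDir, paste0("manifest_", gsub("-", "_", stage), ".json"))
}

#' @keywords internal
#' @noRd
.writeManifest <- function(outDir, stage, payload) {
  jsonlite::write_json(payload, .manifestPath(outDir, stage),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @keywords internal
#' @noRd
.requireManifest <- function(outDir, stage, neededBy) {
  p <- .manifestPath(outDir, stage)
  if (!file.exists(p))
    stop("stage '", neededBy, "' needs the manifest of upstream stage '",
         stage, "' (", p, "); run that stage first")
  jsonlite::read_json(p, simplifyVector = TRUE)
}

#' Run the phantom pipeline end to end
#'
#' Executes the configured stages in order, writing one manifest per stage
#' plus a structured log with per-stage timing and seeds. A stage whose
#' manifest already exists in \code{outDir} is skipped, so an interrupted
#' run resumes where it stopped; a stage whose upstream manifest is missing
#' fails with an error naming that stage. The summary report contains no
#' timestamps, so a rerun with the same seed into a fresh directory yields
#' an identical \code{summary.json}.
#'
#' @param config a \code{\link{pipelineConfig}} list.
#' @return invisibly, the summary list (also written to
#'   \code{outDir/summary.json}).
#' @export
runPipeline <- function(config) {
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "pipeline_log.csv")
  stages <- intersect(.stageOrder, config$stages)
  logStage <- function(stage, seed, seconds, status) {
    row <- data.frame(stage = stage, seed = seed,
                      seconds = round(seconds, 3), status = status)
    exists <- file.exists(logPath)
    utils::write.table(row, logPath, sep = ",", row.names = FALSE,
                       col.names = !exists, append = exists)
  }
  runStage <- function(stage, fn) {
    if (!(stage %in% stages)) return(invisible(NULL))
    seed <- childSeed(config$seed, stage)
    if (file.exists(.manifestPath(outDir, stage))) {
      logStage(stage, seed, 0, "skipped (manifest exists)")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    fn(seed)
    logStage(stage, seed, proc.time()[["elapsed"]] - t0, "done")
  }

  ## -- simulate: cohort + patient-level split -------------------------------
  runStage("simulate", function(seed) {
    ## marker schedule scales with the slice count unless given explicitly;
    ## the onset floor of 4 keeps the cohort jitter (+/- 3) inside [1, M]
    sched <- config$schedule
    if (is.null(sched))
      sched <- list(apicalOnset = max(4L, round(0.11 * config$nSlices)),
                    bifurcation = round(0.375 * config$nSlices),
                    disappearance = round(0.85 * config$nSlices))
    baseSpec <- PhantomSpec(imageSize = config$imageSize,
                            nSlices = config$nSlices,
                            apicalOnset = sched$apicalOnset,
                            bifurcation = sched$bifurcation,
                            disappearance = sched$disappearance)
    cases <- generateCohort(config$nCases, prevalence = config$prevalence,
                            baseSpec = baseSpec, seed = seed,
                            siteTag = config$siteTag)
    saveRDS(cases, file.path(outDir, "cohort.rds"))
    ids <- vapply(cases, function(cs) caseID(cs@volume), character(1))
    labs <- vapply(cases, caseLabel, numeric(1))
    sp <- splitCases(ids, labs, config$fractions,
                     seed = childSeed(seed, "split"))
    .writeManifest(outDir, "simulate", list(
      nCases = length(cases), caseIDs = ids, labels = labs,
      split = sp, seed = seed))
  })

  ## -- preprocess: scanner mask from training volumes -----------------------
  runStage("preprocess", function(seed) {
    sim <- .requireManifest(outDir, "simulate", "preprocess")
    cases <- readRDS(file.path(outDir, "cohort.rds"))
    ids <- vapply(cases, function(cs) caseID(cs@volume), character(1))
    trainVols <- lapply(cases[ids %in% sim$split$train],
                        function(cs) cs@volume)
    mask <- deriveScannerMask(trainVols,
                              provenance = paste0("pipeline:", outDir))
    saveRDS(mask, file.path(outDir, "scanner_mask.rds"))
    .writeManifest(outDir, "preprocess", list(
      maskPixels = sum(mask@mask), maskDim = dim(mask@mask),
      nReferenceVolumes = length(trainVols), seed = seed))
  })

  ## -- train-pm: slice-level PM extractor ------------------------------------
  runStage("train-pm", function(seed) {
    sim <- .requireManifest(outDir, "simulate", "train-pm")
    cases <- readRDS(file.path(outDir, "cohort.rds"))
    ids <- vapply(cases, function(cs) caseID(cs@volume), character(1))
    trainCases <- cases[ids %in% sim$split$train]
    pmCfg <- do.call(pmTrainConfig, c(config$pmTrain, list(seed = seed)))
    model <- trainPMExtractor(trainCases, config = pmCfg)
    saveRDS(model, file.path(outDir, "pm_model.rds"))
    utils::write.csv(model$trainLog,
                     file.path(outDir, "pm_train_log.csv"),
                     row.names = FALSE)
    .writeManifest(outDir, "train-pm", list(
      epochs = pmCfg$epochs, finalLoss = utils::tail(model$trainLog$loss, 1),
      seed = seed))
  })

  ## -- psm: peak slice mining on every case ----------------------------------
  runStage("psm", function(seed) {
    sim <- .requireManifest(outDir, "simulate", "psm")
    .requireManifest(outDir, "train-pm", "psm")
    model <- readRDS(file.path(outDir, "pm_model.rds"))
    cases <- readRDS(file.path(outDir, "cohort.rds"))
    rows <- lapply(cases, function(cs) {
      conf <- predictSliceConfidences(model, cs@volume)
      sel <- psmSelect(conf, caseID = caseID(cs@volume))
      truth <- pmIndices(cs@pmTruth)
      data.frame(case_id = caseID(cs@volume),
                 upper = pmIndices(sel)[["upper"]],
                 middle = pmIndices(sel)[["middle"]],
                 lower = pmIndices(sel)[["lower"]],
                 truth_upper = truth[["upper"]],
                 truth_middle = truth[["middle"]],
                 truth_lower = truth[["lower"]])
    })
    pmCsv <- do.call(rbind, rows)
    utils::write.csv(pmCsv, file.path(outDir, "pm_manifest.csv"),
                     row.names = FALSE)
    valRows <- pmCsv[pmCsv$case_id %in% sim$split$val, , drop = FALSE]
    acc <- if (nrow(valRows)) {
      oneUpDownAccuracy(
        as.matrix(valRows[, c("upper", "middle", "lower")]),
        as.matrix(valRows[, c("truth_upper", "truth_middle",
                              "truth_lower")]))
    } else NA_real_
    .writeManifest(outDir, "psm", list(valOneUpDown = acc, seed = seed))
  })

  ## -- select-rs: representative slices per case ------------------------------
  runStage("select-rs", function(seed) {
    .requireManifest(outDir, "psm", "select-rs")
    pmCsv <- utils::read.csv(file.path(outDir, "pm_manifest.csv"))
    rows <- lapply(seq_len(nrow(pmCsv)), function(i) {
      ## degenerate marker predictions (wrong order or too close for the
      ## strategy) fall back to evenly spaced slices, flagged per case
      idx <- tryCatch({
        pm <- PMAnnotation(pmCsv$upper[i], pmCsv$middle[i], pmCsv$lower[i],
                           caseID = pmCsv$case_id[i])
        rsIndices(extractRS(pm, config$strategy, M = config$nSlices))
      }, error = function(e) NULL)
      fallback <- is.null(idx)
      if (fallback)
        idx <- as.integer(round(seq(1, config$nSlices,
                                    length.out = config$strategy)))
      data.frame(case_id = pmCsv$case_id[i], strategy = config$strategy,
                 fallback = fallback,
                 indices = paste(idx, collapse = ";"))
    })
    rsCsv <- do.call(rbind, rows)
    utils::write.csv(rsCsv, file.path(outDir, "rs_manifest.csv"),
                     row.names = FALSE)
    .writeManifest(outDir, "select-rs", list(
      strategy = config$strategy, nCases = nrow(pmCsv),
      nFallback = sum(rsCsv$fallback), seed = seed))
  })

  ## -- train: the Slider identifier -------------------------------------------
  runStage("train", function(seed) {
    sim <- .requireManifest(outDir, "simulate", "train")
    .requireManifest(outDir, "select-rs", "train")
    rsCsv <- utils::read.csv(file.path(outDir, "rs_manifest.csv"))
    cases <- readRDS(file.path(outDir, "cohort.rds"))
    ids <- vapply(cases, function(cs) caseID(cs@volume), character(1))
    bb <- do.call(tinyBackboneConfig, config$backbone)
    sc <- SliderConfig(embedDim = bb$d, reduction = config$reduction,
                       nBlocks = bb$nBlocks, T = config$strategy,
                       patchGrid = c(bb$grid, bb$grid))
    stackFor <- function(id) {
      cs <- cases[[which(ids == id)]]
      idx <- as.integer(strsplit(
        rsCsv$indices[rsCsv$case_id == id], ";")[[1]])
      pm <- PMAnnotation(pmIndices(cs@pmTruth)[["upper"]],
                         pmIndices(cs@pmTruth)[["middle"]],
                         pmIndices(cs@pmTruth)[["lower"]], caseID = id)
      rs <- new("RSSet", strategy = as.integer(config$strategy),
                indices = idx,
                source = new("PMSelection", caseID = id,
                             indices = pmIndices(pm),
                             peaks = rep(NA_real_, 3),
                             M = nSlices(cs@volume)))
      stackRSVolume(cs@volume, rs, size = bb$inputSize)
    }
    trainIDs <- sim$split$train
    stacks <- lapply(trainIDs, stackFor)
    labs <- vapply(trainIDs, function(id)
      caseLabel(cases[[which(ids == id)]]), numeric(1))
    model <- assembleModel(bb, sc, mode = "slider", seed = seed)
    trCfg <- do.call(identifierTrainConfig,
                     c(config$sliderTrain, list(seed = seed)))
    model <- trainIdentifier(model, stacks, labs, trCfg)
    saveRDS(model, file.path(outDir, "slider_model.rds"))
    utils::write.csv(model$trainLog,
                     file.path(outDir, "slider_train_log.csv"),
                     row.names = FALSE)
    .writeManifest(outDir, "train", list(
      mode = "slider", epochs = trCfg$epochs,
      finalLoss = utils::tail(model$trainLog$loss, 1), seed = seed))
  })

  ## -- evaluate: test-set predictions + metrics --------------------------------
  runStage("evaluate", function(seed) {
    sim <- .requireManifest(outDir, "simulate", "evaluate")
    .requireManifest(outDir, "train", "evaluate")
    rsCsv <- utils::read.csv(file.path(outDir, "rs_manifest.csv"))
    model <- readRDS(file.path(outDir, "slider_model.rds"))
    cases <- readRDS(file.path(outDir, "cohort.rds"))
    ids <- vapply(cases, function(cs) caseID(cs@volume), character(1))
    bb <- model$backbone
    testIDs <- sim$split$test
    preds <- vapply(testIDs, function(id) {
      cs <- cases[[which(ids == id)]]
      idx <- as.integer(strsplit(
        rsCsv$indices[rsCsv$case_id == id], ";")[[1]])
      rs <- new("RSSet", strategy = as.integer(config$strategy),
                indices = idx,
                source = new("PMSelection", caseID = id,
                             indices = pmIndices(cs@pmTruth),
                             peaks = rep(NA_real_, 3),
                             M = nSlices(cs@volume)))
      predictCase(model, stackRSVolume(cs@volume, rs, size = bb$inputSize))
    }, numeric(1))
    labs <- vapply(testIDs, function(id)
      caseLabel(cases[[which(ids == id)]]), numeric(1))
    utils::write.csv(
      data.frame(case_id = testIDs, label = labs, score = preds),
      file.path(outDir, "predictions.csv"), row.names = FALSE)
    metrics <- list(accuracy = mean((preds >= 0.5) == labs))
    if (length(unique(labs)) == 2) {
      metrics$auroc <- auroc(labs, preds)
      metrics$auprc <- auprc(labs, preds)
    }
    .writeManifest(outDir, "evaluate", c(metrics, list(seed = seed)))
  })

  ## -- count-params: Table-shaped parameter report ------------------------------
  runStage("count-params", function(seed) {
    bb <- backboneConfig()
    rows <- lapply(c(1L, 2L, 4L, 6L, 8L, 12L), function(delta) {
      rep <- countTunableParams(bb, SliderConfig(reduction = delta),
                                "slider")
      list(mode = "slider", delta = delta, millions = paramMillions(rep))
    })
    rows <- c(rows, lapply(c("full", "partial", "linear_probe"),
                           function(m) {
      rep <- countTunableParams(bb, mode = m)
      list(mode = m, delta = NA,
           millions = if (m == "linear_probe") {
             round(paramCount(rep) / 1e6, 4)
           } else paramMillions(rep))
    }))
    .writeManifest(outDir, "count-params", list(table = rows, seed = seed))
  })

  ## -- summary -----------------------------------------------------------------
  summary <- list(seed = config$seed, stages = list())
  for (st in stages) {
    p <- .manifestPath(outDir, st)
    if (file.exists(p))
      summary$stages[[st]] <- jsonlite::read_json(p, simplifyVector = TRUE)
  }
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
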