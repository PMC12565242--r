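## Position-marker extraction: class-balanced slice dataset construction,
## the slice classifier, peak slice mining (PSM) and its evaluation.

.PM_CLASSES <- c("upper", "middle", "lower", "non_pm")

#' @keywords internal
#' @noRd
.asAnnotationList <- function(cases) {
  lapply(cases, function(cs) {
    if (is(cs, "PhantomCase")) {
      list(pm = cs@pmTruth, M = nSlices(cs), id = caseID(cs))
    } else if (is.list(cs) && !is.null(cs$pm)) {
      list(pm = cs$pm, M = cs$M, id = cs$pm@caseID)
    } else stop("cases must be PhantomCase objects or list(pm=, M=)")
  })
}

#' Build the class-balanced PM slice dataset
#'
#' Each case contributes exactly one slice per PM class; all remaining
#' slices are non-PM. Non-PM slices are randomly downsampled (default: 75%
#' removed, 25% retained) and each PM class is oversampled with replication
#' until its count matches the retained non-PM count; replicated records
#' beyond the first copy are flagged for augmentation. Deterministic given
#' \code{seed}.
#'
#' @param cases list of \linkS4class{PhantomCase} objects, or of
#'   \code{list(pm = PMAnnotation, M = slice count)}.
#' @param downsampleFrac fraction of non-PM slices removed (default 0.75).
#' @param seed RNG seed.
#' @return data.frame (case_id, slice_index, class, augment) with a
#'   \code{classWeights} attribute (inverse-frequency weights on the
#'   balanced set, in .PM_CLASSES order).
#' @export
buildBalancedDataset <- function(cases, downsampleFrac = 0.75, seed = 1L) {
  ann <- .asAnnotationList(cases)
  stopifnot(downsampleFrac >= 0, downsampleFrac < 1)
  recs <- lapply(ann, function(a) {
    if (a$M < 4L) stop("case ", a$id, " has fewer than 4 slices")
    pm <- pmIndices(a$pm)
    if (any(pm > a$M)) stop("case ", a$id, ": PM index exceeds slice count")
    cls <- rep("non_pm", a$M)
    cls[pm] <- names(pm)
    data.frame(case_id = a$id, slice_index = seq_len(a$M), class = cls,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, recs)
  nonPM <- all[all$class == "non_pm", ]
  pmRecs <- all[all$class != "non_pm", ]
  withSeed(childSeed(seed, "balance"), {
    nKeep <- round((1 - downsampleFrac) * nrow(nonPM))
    keep <- nonPM[sample.int(nrow(nonPM), nKeep), ]
    keep$augment <- FALSE
    balanced <- list(keep)
    for (cl in c("upper", "middle", "lower")) {
      orig <- pmRecs[pmRecs$class == cl, ]
      reps <- orig[rep(seq_len(nrow(orig)), length.out = nKeep), ]
      ## extra draws beyond one full pass get the augmentation flag
      reps$augment <- seq_len(nrow(reps)) > nrow(orig)
      balanced[[cl]] <- reps
    }
    out <- do.call(rbind, balanced)
    out <- out[sample.int(nrow(out)), ]
    rownames(out) <- NULL
    counts <- table(factor(out$class, levels = .PM_CLASSES))
    w <- as.numeric(sum(counts) / (length(counts) * pmax(counts, 1)))
    names(w) <- .PM_CLASSES
    attr(out, "classWeights") <- w
    out
  })
}

## Fetch one model-ready PM-path image: enhanced-lung window, [0, 1],
## resized to `size`, optional integer pixel shift (augmentation).
#' @keywords internal
#' @noRd
.pmSliceImage <- function(volume, m, size, shift = c(0L, 0L), mask = NULL) {
  hu <- getSlice(volume, m)
  if (!is.null(mask)) hu <- applyScannerMask(hu, mask)
  img <- applyWindow(hu, WindowSpec(-700, 700, "enhanced_lung")) / 255
  img <- .resizeMat(img, size)
  if (any(shift != 0L)) {
    s <- nrow(img)
    ri <- pmin(pmax(seq_len(s) + shift[1], 1L), s)
    ci <- pmin(pmax(seq_len(s) + shift[2], 1L), s)
    img <- img[ri, ci]
  }
  img
}

#' Default PM-extractor training configuration
#'
#' Production-scale defaults (20 epochs, batch 256, Adam at 1e-3, 256x256
#' inputs in [0, 1]); override any field for desk-scale runs.
#'
#' @param ... overrides (epochs, batchSize, lr, inputSize, channels, seed).
#' @return named list.
#' @export
pmTrainConfig <- function(...) {
  cfg <- list(epochs = 20L, batchSize = 256L, lr = 1e-3, inputSize = 256L,
              channels = c(8L, 16L), seed = 1L)
  utils::modifyList(cfg, list(...))
}

#' Train the PM extractor
#'
#' Trains the slice classifier (4 classes: upper, middle, lower, non-PM)
#' with weighted cross-entropy on a balanced dataset built by
#' \code{\link{buildBalancedDataset}}. Inputs are enhanced-lung-window
#' slices normalised to [0, 1]. Fully seeded; \code{epochs = 0} returns the
#' initialised classifier (prior-level confidences) so the downstream
#' pipeline can still run.
#'
#' @param cases list of \linkS4class{PhantomCase} objects providing volumes
#'   and PM ground truth.
#' @param dataset optional prebuilt balanced dataset; built from
#'   \code{cases} when NULL.
#' @param config see \code{\link{pmTrainConfig}}.
#' @param mask optional \linkS4class{ScannerMask}.
#' @return object of class \code{pmExtractor}: network weights, config and
#'   an epoch-loss training log.
#' @export
trainPMExtractor <- function(cases, dataset = NULL, config = pmTrainConfig(),
                             mask = NULL) {
  if (is.null(dataset)) dataset <- buildBalancedDataset(cases, seed = config$seed)
  if (nrow(dataset) == 0) stop("empty training dataset")
  present <- unique(dataset$class)
  if (length(present) < 2) stop("need at least 2 classes present for training")
  if (!all(.PM_CLASSES %in% present))
    stop("class absent from training split: ",
         paste(setdiff(.PM_CLASSES, present), collapse = ", "))
  volumes <- lapply(cases, function(cs) if (is(cs, "PhantomCase")) cs@volume else cs)
  names(volumes) <- vapply(volumes, caseID, character(1))

  size <- config$inputSize
  net <- cnnInit(size, nClasses = 4L, channels = config$channels,
                 seed = childSeed(config$seed, "init"))
  w <- attr(dataset, "classWeights")
  if (is.null(w)) w <- rep(1, 4)
  labels <- match(dataset$class, .PM_CLASSES)

  ## image cache over unique (case, slice) pairs
  key <- paste(dataset$case_id, dataset$slice_index)
  uniq <- !duplicated(key)
  cache <- new.env(parent = emptyenv())
  for (i in which(uniq)) {
    cache[[key[i]]] <- .pmSliceImage(volumes[[dataset$case_id[i]]],
                                     dataset$slice_index[i], size, mask = mask)
  }
  shifts <- withSeed(childSeed(config$seed, "augment"), {
    matrix(sample(-2:2, 2L * nrow(dataset), TRUE), ncol = 2L)
  })
  shifts[!dataset$augment, ] <- 0L

  log <- data.frame(epoch = integer(0), loss = numeric(0))
  if (config$epochs > 0) {
    opt <- adamInit(net)
    n <- nrow(dataset)
    for (ep in seq_len(config$epochs)) {
      ord <- withSeed(childSeed(config$seed, paste0("epoch", ep)),
                      sample.int(n))
      epLoss <- 0; nb <- 0L
      for (start in seq(1L, n, by = config$batchSize)) {
        idx <- ord[start:min(start + config$batchSize - 1L, n)]
        B <- length(idx)
        X <- array(0, c(B, size, size, 1L))
        for (j in seq_len(B)) {
          X[j, , , 1L] <- .pmSliceImage2(cache[[key[idx[j]]]], shifts[idx[j], ])
        }
        fw <- cnnForward(X, net, wantCache = TRUE)
        ce <- nnSoftmaxCE(fw$logits, labels[idx], classWeights = w)
        grads <- cnnBackward(ce$dLogits, fw$cache, net)
        cfgAttr <- attr(net, "cfg")
        upd <- adamStep(net, grads, opt, lr = config$lr)
        net <- upd$params; attr(net, "cfg") <- cfgAttr
        opt <- upd$state
        epLoss <- epLoss + ce$loss; nb <- nb + 1L
      }
      log <- rbind(log, data.frame(epoch = ep, loss = epLoss / nb))
    }
  }
  structure(list(net = net, config = config, classes = .PM_CLASSES,
                 trainLog = log, mask = mask),
            class = "pmExtractor")
}

## apply a cached image's per-record shift
#' @keywords internal
#' @noRd
.pmSliceImage2 <- function(img, shift) {
  if (all(shift == 0L)) return(img)
  s <- nrow(img)
  ri <- pmin(pmax(seq_len(s) + shift[1], 1L), s)
  ci <- pmin(pmax(seq_len(s) + shift[2], 1L), s)
  img[ri, ci]
}

#' Per-slice PM confidences for one case
#'
#' @param model a \code{pmExtractor}.
#' @param volume a \linkS4class{CTVolume}.
#' @return M x 4 logit matrix with columns (upper, middle, lower, non_pm).
#' @export
predictSliceConfidences <- function(model, volume) {
  stopifnot(inherits(model, "pmExtractor"))
  size <- model$config$inputSize
  M <- nSlices(volume)
  X <- array(0, c(M, size, size, 1L))
  for (m in seq_len(M)) {
    X[m, , , 1L] <- .pmSliceImage(volume, m, size, mask = model$mask)
  }
  logits <- cnnForward(X, model$net)$logits
  colnames(logits) <- model$classes
  logits
}

#' @export
print.pmExtractor <- function(x, ...) {
  cat(sprintf("pmExtractor: %dx%d input, %d epochs trained, final loss %s\n",
              x$config$inputSize, x$config$inputSize,
              nrow(x$trainLog),
              if (nrow(x$trainLog)) sprintf("%.4f", utils::tail(x$trainLog$loss, 1))
              else "NA"))
  invisible(x)
}

#' Peak slice mining: one peak slice per PM class
#'
#' For each PM class column the confidences are normalised across slices by
#' a softmax (so per-class probabilities over the case sum to 1) and the
#' argmax slice is selected; ties break to the smallest index. Selection is
#' performed on the raw logits (softmax is monotone, so the reported
#' probabilities never change the argmax). A non-PM column named
#' \code{non_pm} (or a 4th unnamed column) is excluded before selection. A
#' warning is emitted if the selected indices are not anatomically ordered
#' (upper < middle < lower); no ordering constraint is imposed.
#'
#' @param conf M x 3 (or M x 4) matrix of per-slice class confidences.
#' @param caseID case identifier.
#' @return a \linkS4class{PMSelection}.
#' @export
psmSelect <- function(conf, caseID = "case") {
  conf <- as.matrix(conf)
  if (!all(is.finite(conf))) stop("non-finite confidences")
  if (ncol(conf) == 4L) {
    drop <- if (!is.null(colnames(conf))) which(colnames(conf) == "non_pm") else 4L
    conf <- conf[, -drop, drop = FALSE]
  }
  if (ncol(conf) != 3L) stop("expected 3 PM class columns (plus optional non_pm)")
  if (nrow(conf) < 1L) stop("need at least one slice")
  probs <- apply(conf, 2L, function(col) {
    e <- exp(col - max(col)); e / sum(e)
  })
  probs <- matrix(probs, nrow = nrow(conf))
  idx <- apply(conf, 2L, which.max)        # first max = smallest index
  peaks <- probs[cbind(idx, seq_len(3L))]
  idx <- as.integer(idx)
  names(idx) <- c("upper", "middle", "lower")
  if (!(idx[1] < idx[2] && idx[2] < idx[3]))
    warning("selected PM indices are not in anatomical order: ",
            paste(idx, collapse = ", "))
  new("PMSelection", caseID = as.character(caseID), indices = idx,
      peaks = as.numeric(peaks), M = nrow(conf))
}

#' 1-Up-Down accuracy
#'
#' Fraction of predictions within one slice of the ground truth, i.e.
#' the mean of the indicator |predicted - truth| <= 1. When \code{classes}
#' is given, per-class accuracies and their unweighted average are also
#' reported.
#'
#' @param predicted integer vector of predicted slice indices.
#' @param truth equal-length vector of ground-truth indices.
#' @param classes optional class label per pair.
#' @return with \code{classes} NULL, a single fraction; otherwise a list
#'   with \code{overall}, \code{perClass} and \code{average}.
#' @export
oneUpDownAccuracy <- function(predicted, truth, classes = NULL) {
  if (length(predicted) != length(truth)) stop("paired lists must match")
  if (length(predicted) == 0) stop("need at least one pair")
  hit <- abs(predicted - truth) <= 1
  if (is.null(classes)) return(mean(hit))
  perClass <- tapply(hit, classes, mean)
  list(overall = mean(hit), perClass = perClass,
       average = mean(perClass))
}

#' Deviation profile of PM predictions
#'
#' @param predicted,truth paired slice-index vectors.
#' @return named integer vector of counts per integer offset
#'   (predicted - truth); counts sum to the number of pairs.
#' @export
deviationProfile <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("paired lists must match")
  off <- predicted - truth
  tab <- table(off)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
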