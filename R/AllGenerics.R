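#' @import methods
NULL

#' Number of slices in a volume or case
#' @param x a CTVolume or PhantomCase.
#' @return integer slice count M.
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname nSlices
#' @export
setMethod("nSlices", "CTVolume", function(x) length(x@slices))

#' @rdname nSlices
#' @export
setMethod("nSlices", "PhantomCase", function(x) length(x@volume@slices))

#' Case identifier
#' @param x an object carrying a case id.
#' @return character id.
#' @export
setGeneric("caseID", function(x) standardGeneric("caseID"))

#' @rdname caseID
#' @export
setMethod("caseID", "CTVolume", function(x) x@caseID)

#' @rdname caseID
#' @export
setMethod("caseID", "PhantomCase", function(x) x@volume@caseID)

#' @rdname caseID
#' @export
setMethod("caseID", "PMAnnotation", function(x) x@caseID)

#' Extract one HU slice
#' @param x a CTVolume or PhantomCase.
#' @param m 1-based slice index.
#' @return numeric HU matrix.
#' @export
setGeneric("getSlice", function(x, m) standardGeneric("getSlice"))

#' @rdname getSlice
#' @export
setMethod("getSlice", "CTVolume", function(x, m) {
  m <- as.integer(m)
  if (m < 1L || m > length(x@slices)) stop("slice index out of range")
  x@slices[[m]]
})

#' @rdname getSlice
#' @export
setMethod("getSlice", "PhantomCase", function(x, m) getSlice(x@volume, m))

#' Position-marker indices as a named vector
#' @param x a PMAnnotation or PMSelection.
#' @return named integer vector (upper, middle, lower).
#' @export
setGeneric("pmIndices", function(x) standardGeneric("pmIndices"))

#' @rdname pmIndices
#' @export
setMethod("pmIndices", "PMAnnotation", function(x) {
  c(upper = x@upper, middle = x@middle, lower = x@lower)
})

#' @rdname pmIndices
#' @export
setMethod("pmIndices", "PMSelection", function(x) x@indices)

#' Representative-slice indices
#' @param x an RSSet.
#' @return increasing integer vector of slice indices.
#' @export
setGeneric("rsIndices", function(x) standardGeneric("rsIndices"))

#' @rdname rsIndices
#' @export
setMethod("rsIndices", "RSSet", function(x) x@indices)

#' Case label
#' @param x a PhantomCase.
#' @return integer 0/1 PF-ILD label.
#' @export
setGeneric("caseLabel", function(x) standardGeneric("caseLabel"))

#' @rdname caseLabel
#' @export
setMethod("caseLabel", "PhantomCase", function(x) x@label)

#' Exact tunable-parameter count
#' @param x a ParamReport.
#' @return numeric exact count.
#' @export
setGeneric("paramCount", function(x) standardGeneric("paramCount"))

#' @rdname paramCount
#' @export
setMethod("paramCount", "ParamReport", function(x) x@count)

#' Tunable parameters in millions (two decimals)
#' @param x a ParamReport.
#' @return numeric millions.
#' @export
setGeneric("paramMillions", function(x) standardGeneric("paramMillions"))

#' @rdname paramMillions
#' @export
setMethod("paramMillions", "ParamReport", function(x) x@millions)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@slices[[1]])
  cat(sprintf("CTVolume '%s': %d slices of %dx%d px, %.1f mm spacing, site '%s'\n",
              object@caseID, length(object@slices), d[1], d[2],
              object@sliceSpacingMM, object@siteTag))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: M=%d (%dpx), onset=%d, bifurcation=%d, ",
                     "disappearance=%d, fibrosis=%.2f, noise=%.1f HU, seed=%d\n"),
              object@nSlices, object@imageSize, object@apicalOnset,
              object@bifurcation, object@disappearance,
              object@fibrosisSeverity, object@noiseSD, object@seed))
})

setMethod("show", "PhantomCase", function(object) {
  cat(sprintf("PhantomCase '%s': label=%d, PMs (%d, %d, %d), %d slices\n",
              caseID(object), object@label, object@pmTruth@upper,
              object@pmTruth@middle, object@pmTruth@lower, nSlices(object)))
})

setMethod("show", "PMAnnotation", function(object) {
  cat(sprintf("PMAnnotation '%s': upper=%d, middle=%d, lower=%d\n",
              object@caseID, object@upper, object@middle, object@lower))
})

setMethod("show", "PMSelection", function(object) {
  cat(sprintf("PMSelection '%s' (M=%d): upper=%d (p=%.3f), middle=%d (p=%.3f), lower=%d (p=%.3f)\n",
              object@caseID, object@M,
              object@indices[1], object@peaks[1],
              object@indices[2], object@peaks[2],
              object@indices[3], object@peaks[3]))
})

setMethod("show", "RSSet", function(object) {
  cat(sprintf("RSSet (%d-RS): %s\n", object@strategy,
              paste(object@indices, collapse = ", ")))
})

setMethod("show", "WindowSpec", function(object) {
  cat(sprintf("WindowSpec '%s': level %g HU, width %g HU\n",
              object@name, object@level, object@width))
})

setMethod("show", "ScannerMask", function(object) {
  cat(sprintf("ScannerMask %dx%d (%.1f%% foreground), provenance '%s'\n",
              nrow(object@mask), ncol(object@mask),
              100 * mean(object@mask), object@provenance))
})

setMethod("show", "SliderConfig", function(object) {
  cat(sprintf(paste0("SliderConfig: d=%d, delta=%d (p=%d), kernel %dx%dx%d, ",
                     "%d blocks, T=%d, grid %dx%d, %s\n"),
              object@embedDim, object@reduction,
              object@embedDim %/% object@reduction,
              object@kernel[1], object@kernel[2], object@kernel[3],
              object@nBlocks, object@T, object@patchGrid[1],
              object@patchGrid[2], object@activation))
})

setMethod("show", "ParamReport", function(object) {
  cat(sprintf("ParamReport [%s]: %s tunable parameters (%.2f M)\n",
              object@mode, format(object@count, big.mark = ","),
              object@millions))
  for (nm in names(object@breakdown)) {
    cat(sprintf("  %-22s %s\n", nm,
                format(object@breakdown[[nm]], big.mark = ",")))
  }
})

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet: %d cases (%d positive), threshold %.2f\n",
              length(object@labels), sum(object@labels), object@threshold))
})
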