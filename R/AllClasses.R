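## Central S4 containers. Slice indices are 1-based (1 .. M, superior to
## inferior) everywhere in this package.

#' CTVolume: an ordered stack of Hounsfield-unit slices for one case
#'
#' Slices are stored superior to inferior as a list of numeric matrices of
#' identical dimension, values in Hounsfield units (HU; air about -1000,
#' water 0).
#'
#' @slot caseID single case identifier.
#' @slot slices list of H x W numeric HU matrices, superior first.
#' @slot sliceSpacingMM axial slice spacing in millimetres.
#' @slot siteTag facility tag used for multi-site bookkeeping.
#' @export
setClass("CTVolume", representation(
  caseID = "character",
  slices = "list",
  sliceSpacingMM = "numeric",
  siteTag = "character"
))

setValidity("CTVolume", function(object) {
  if (length(object@caseID) != 1L) return("caseID must be length 1")
  M <- length(object@slices)
  if (M < 3L) return("a CT volume needs at least 3 slices")
  dims <- vapply(object@slices, function(s) {
    if (!is.matrix(s) || !is.numeric(s)) return(c(NA_integer_, NA_integer_))
    dim(s)
  }, integer(2))
  if (anyNA(dims)) return("all slices must be numeric matrices")
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all slices must share one matrix dimension")
  if (!all(vapply(object@slices, function(s) all(is.finite(s)), logical(1))))
    return("HU values must be finite")
  if (length(object@sliceSpacingMM) != 1L || object@sliceSpacingMM <= 0)
    return("sliceSpacingMM must be a single positive number")
  TRUE
})

#' Construct a CTVolume
#'
#' @param slices list of numeric HU matrices, superior to inferior.
#' @param caseID case identifier.
#' @param sliceSpacingMM axial spacing in mm (default 4, i.e. roughly 75
#'   slices over an adult thorax).
#' @param siteTag facility tag.
#' @return a \linkS4class{CTVolume}.
#' @export
CTVolume <- function(slices, caseID = "case", sliceSpacingMM = 4,
                     siteTag = "synthetic") {
  new("CTVolume", caseID = as.character(caseID), slices = slices,
      sliceSpacingMM = as.numeric(sliceSpacingMM),
      siteTag = as.character(siteTag))
}

#' PhantomSpec: geometry and signal parameters for one synthetic case
#'
#' Encodes the anatomical schedule of a cartoon chest CT: the slice where
#' aerated lung parenchyma first appears, the first tracheal bifurcation
#' slice, and the first slice where parenchyma is absent bilaterally,
#' plus the fibrosis-like texture strength for positive cases.
#'
#' @slot nSlices number of axial slices M.
#' @slot apicalOnset first slice (1-based) with aerated lung parenchyma.
#' @slot bifurcation first slice with two separated bronchial lumens.
#' @slot disappearance first slice with no aerated parenchyma bilaterally.
#' @slot lungGeometry base lung-ellipse half-axes as fractions of image size
#'   (width, height).
#' @slot fibrosisSeverity fibrosis texture strength in [0, 1].
#' @slot noiseSD additive Gaussian noise SD in HU.
#' @slot imageSize square image side in pixels.
#' @slot seed RNG seed for this case.
#' @export
setClass("PhantomSpec", representation(
  nSlices = "integer",
  apicalOnset = "integer",
  bifurcation = "integer",
  disappearance = "integer",
  lungGeometry = "numeric",
  fibrosisSeverity = "numeric",
  noiseSD = "numeric",
  imageSize = "integer",
  seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  a <- object@apicalOnset; b <- object@bifurcation; d <- object@disappearance
  if (!(1L <= a && a < b && b < d && d <= object@nSlices))
    return("slice schedule must satisfy 1 <= apicalOnset < bifurcation < disappearance <= nSlices")
  if (object@fibrosisSeverity < 0 || object@fibrosisSeverity > 1)
    return("fibrosisSeverity must be in [0, 1]")
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  if (object@imageSize < 32L) return("imageSize must be >= 32 pixels")
  if (length(object@lungGeometry) != 2L || any(object@lungGeometry <= 0) ||
      any(object@lungGeometry >= 0.5))
    return("lungGeometry must be two positive fractions < 0.5")
  TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults mirror a 4 mm-spacing adult chest series of about 75 slices.
#'
#' @param nSlices number of slices (default 75).
#' @param apicalOnset,bifurcation,disappearance 1-based anatomical schedule.
#' @param lungGeometry lung half-axes as fractions of image size.
#' @param fibrosisSeverity fibrosis texture strength in [0, 1] (0 = none).
#' @param noiseSD HU noise SD (default 15).
#' @param imageSize square image side in pixels (default 256).
#' @param seed per-case RNG seed.
#' @return a \linkS4class{PhantomSpec}.
#' @export
PhantomSpec <- function(nSlices = 75L, apicalOnset = 8L, bifurcation = 28L,
                        disappearance = 66L, lungGeometry = c(0.17, 0.26),
                        fibrosisSeverity = 0, noiseSD = 15, imageSize = 256L,
                        seed = 1L) {
  new("PhantomSpec", nSlices = as.integer(nSlices),
      apicalOnset = as.integer(apicalOnset),
      bifurcation = as.integer(bifurcation),
      disappearance = as.integer(disappearance),
      lungGeometry = as.numeric(lungGeometry),
      fibrosisSeverity = as.numeric(fibrosisSeverity),
      noiseSD = as.numeric(noiseSD), imageSize = as.integer(imageSize),
      seed = as.integer(seed))
}

#' PMAnnotation: the three position-marker slice indices for one case
#'
#' @slot caseID case identifier.
#' @slot upper apical-lung-onset slice (1-based).
#' @slot middle tracheal-bifurcation slice.
#' @slot lower upper-diaphragm slice (three slices superior to bilateral
#'   parenchyma disappearance).
#' @export
setClass("PMAnnotation", representation(
  caseID = "character", upper = "integer", middle = "integer",
  lower = "integer"
))

setValidity("PMAnnotation", function(object) {
  u <- object@upper; m <- object@middle; l <- object@lower
  if (!(1L <= u && u < m && m < l))
    return("position markers must satisfy 1 <= upper < middle < lower")
  TRUE
})

#' Construct a PMAnnotation
#' @param upper,middle,lower 1-based PM slice indices.
#' @param caseID case identifier.
#' @return a \linkS4class{PMAnnotation}.
#' @export
PMAnnotation <- function(upper, middle, lower, caseID = "case") {
  new("PMAnnotation", caseID = as.character(caseID),
      upper = as.integer(upper), middle = as.integer(middle),
      lower = as.integer(lower))
}

#' PhantomCase: one synthetic patient
#'
#' @slot volume the generated \linkS4class{CTVolume}.
#' @slot pmTruth ground-truth \linkS4class{PMAnnotation}.
#' @slot label binary PF-ILD flag (0/1).
#' @slot spec the generating \linkS4class{PhantomSpec}.
#' @export
setClass("PhantomCase", representation(
  volume = "CTVolume", pmTruth = "PMAnnotation", label = "integer",
  spec = "PhantomSpec"
))

setValidity("PhantomCase", function(object) {
  if (!(object@label %in% c(0L, 1L))) return("label must be 0 or 1")
  TRUE
})

#' WindowSpec: a Hounsfield display window
#'
#' @slot level window centre in HU.
#' @slot width window width in HU (> 0).
#' @slot name window name.
#' @export
setClass("WindowSpec", representation(
  level = "numeric", width = "numeric", name = "character"
))

setValidity("WindowSpec", function(object) {
  if (object@width <= 0) return("window width must be > 0")
  TRUE
})

#' Construct a WindowSpec
#' @param level window centre (HU).
#' @param width window width (HU, > 0).
#' @param name window name.
#' @return a \linkS4class{WindowSpec}.
#' @export
WindowSpec <- function(level, width, name = "window") {
  new("WindowSpec", level = as.numeric(level), width = as.numeric(width),
      name = as.character(name))
}

#' ScannerMask: binary field-of-view mask shared across scanners
#'
#' @slot mask binary (0/1) matrix.
#' @slot provenance identifier of the reference dataset it was derived from.
#' @export
setClass("ScannerMask", representation(
  mask = "matrix", provenance = "character"
))

setValidity("ScannerMask", function(object) {
  if (!all(object@mask %in% c(0, 1))) return("mask must be binary")
  if (sum(object@mask) < 1) return("mask must contain foreground")
  TRUE
})

#' PMSelection: the peak slice per PM class for one case
#'
#' @slot caseID case identifier.
#' @slot indices named integer vector (upper, middle, lower), 1-based.
#' @slot peaks per-class peak softmax probabilities.
#' @slot M number of slices in the scored case.
#' @export
setClass("PMSelection", representation(
  caseID = "character", indices = "integer", peaks = "numeric",
  M = "integer"
))

setValidity("PMSelection", function(object) {
  if (length(object@indices) != 3L ||
      !identical(names(object@indices), c("upper", "middle", "lower")))
    return("indices must be named (upper, middle, lower)")
  if (any(object@indices < 1L) || any(object@indices > object@M))
    return("selected indices must lie in [1, M]")
  TRUE
})

#' RSSet: representative slices under a 3/5/9-slice strategy
#'
#' @slot strategy 3, 5 or 9.
#' @slot indices strictly increasing 1-based slice indices.
#' @slot source the \linkS4class{PMSelection} the set was derived from.
#' @export
setClass("RSSet", representation(
  strategy = "integer", indices = "integer", source = "PMSelection"
))

setValidity("RSSet", function(object) {
  if (!(object@strategy %in% c(3L, 5L, 9L))) return("strategy must be 3, 5 or 9")
  if (length(object@indices) != object@strategy)
    return("index count must equal the strategy size")
  if (any(diff(object@indices) <= 0L))
    return("indices must be strictly increasing")
  if (any(object@indices < 1L)) return("indices must be >= 1")
  TRUE
})

#' SliderConfig: architecture of the slice-level 3D adapter
#'
#' The adapter bottleneck is p = d / delta; the depth-wise 3D convolution
#' kernel (kT, kH, kW) acts over the slice axis and the patch grid.
#'
#' @slot embedDim transformer embedding dimension d.
#' @slot reduction reduction factor delta (d must be divisible by it).
#' @slot kernel integer kernel shape (kT, kH, kW), all odd.
#' @slot nBlocks number of transformer blocks carrying an adapter.
#' @slot activation activation name ("gelu", "relu" or "identity").
#' @slot nClasses classifier classes (default 2).
#' @slot T slices per case fed to the model.
#' @slot patchGrid patch-grid height and width (H, W).
#' @export
setClass("SliderConfig", representation(
  embedDim = "integer", reduction = "integer", kernel = "integer",
  nBlocks = "integer", activation = "character", nClasses = "integer",
  T = "integer", patchGrid = "integer"
))

setValidity("SliderConfig", function(object) {
  if (object@embedDim %% object@reduction != 0L)
    return("embedDim must be divisible by the reduction factor")
  if (length(object@kernel) != 3L || any(object@kernel %% 2L == 0L))
    return("kernel must be three odd integers")
  if (object@nBlocks < 0L) return("nBlocks must be >= 0")
  if (object@nClasses < 2L) return("nClasses must be >= 2")
  TRUE
})

#' Construct a SliderConfig
#'
#' @param embedDim embedding dimension d (default 768, ViT-B).
#' @param reduction reduction factor delta (default 4, bottleneck 192).
#' @param kernel depth-wise 3D kernel shape; default c(3, 1, 1), i.e. purely
#'   slice-wise mixing.
#' @param nBlocks adapter-carrying transformer blocks (default 12).
#' @param activation nonlinearity (default "gelu").
#' @param nClasses output classes (default 2).
#' @param T slices per case (default 5, the 5-RS strategy).
#' @param patchGrid patch-grid (H, W); default c(37, 37), a 518-pixel input
#'   with 14-pixel patches.
#' @return a \linkS4class{SliderConfig}.
#' @export
SliderConfig <- function(embedDim = 768L, reduction = 4L, kernel = c(3L, 1L, 1L),
                         nBlocks = 12L, activation = "gelu", nClasses = 2L,
                         T = 5L, patchGrid = c(37L, 37L)) {
  new("SliderConfig", embedDim = as.integer(embedDim),
      reduction = as.integer(reduction), kernel = as.integer(kernel),
      nBlocks = as.integer(nBlocks), activation = as.character(activation),
      nClasses = as.integer(nClasses), T = as.integer(T),
      patchGrid = as.integer(patchGrid))
}

#' ParamReport: exact tunable-parameter accounting
#'
#' @slot mode one of "slider", "full", "partial", "linear_probe".
#' @slot count exact integer count (stored as double).
#' @slot millions count / 1e6 rounded to two decimals.
#' @slot breakdown named per-component counts.
#' @export
setClass("ParamReport", representation(
  mode = "character", count = "numeric", millions = "numeric",
  breakdown = "list"
))

setValidity("ParamReport", function(object) {
  if (abs(object@millions - round(object@count / 1e6, 2)) > 1e-12)
    return("millions must equal round(count / 1e6, 2)")
  if (abs(object@count - sum(unlist(object@breakdown))) > 0.5)
    return("breakdown must sum to count")
  TRUE
})

#' PredictionSet: paired case labels and model scores
#'
#' @slot caseIDs case identifiers.
#' @slot labels binary labels (0 = non-PF-ILD, 1 = PF-ILD).
#' @slot scores positive-class probabilities in [0, 1].
#' @slot threshold decision threshold (default 0.5; score >= threshold is
#'   called positive).
#' @export
setClass("PredictionSet", representation(
  caseIDs = "character", labels = "integer", scores = "numeric",
  threshold = "numeric"
))

setValidity("PredictionSet", function(object) {
  n <- length(object@labels)
  if (length(object@scores) != n || length(object@caseIDs) != n)
    return("caseIDs, labels and scores must have equal length")
  if (n < 1L) return("need at least one case")
  if (!all(object@labels %in% c(0L, 1L))) return("labels must be 0/1")
  if (any(!is.finite(object@scores)) || any(object@scores < 0) ||
      any(object@scores > 1))
    return("scores must lie in [0, 1]")
  TRUE
})

#' Construct a PredictionSet
#' @param labels binary 0/1 labels.
#' @param scores positive-class scores in [0, 1].
#' @param caseIDs case identifiers (default case_1..case_N).
#' @param threshold decision threshold (default 0.5).
#' @return a \linkS4class{PredictionSet}.
#' @export
PredictionSet <- function(labels, scores, caseIDs = NULL, threshold = 0.5) {
  n <- length(labels)
  if (is.null(caseIDs)) caseIDs <- paste0("case_", seq_len(n))
  new("PredictionSet", caseIDs = as.character(caseIDs),
      labels = as.integer(labels), scores = as.numeric(scores),
      threshold = as.numeric(threshold))
}
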