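## Representative-slice geometry: deterministic fractional positions
## between the three position markers.

#' Extract representative slices from position markers
#'
#' Fractional positions are measured from the superior endpoint of each
#' PM interval and rounded half away from zero:
#' \itemize{
#'   \item 3-RS: upper + (middle-upper)/3, the middle PM itself,
#'     middle + (lower-middle)/3;
#'   \item 5-RS: the 1/3 and 2/3 points of both intervals plus the middle
#'     PM;
#'   \item 9-RS: the 3-RS slices plus the immediate neighbour above and
#'     below each, clamped to [1, M].
#' }
#' Duplicate indices after clamping are an error (the PMs are too close for
#' the requested strategy), not silently repaired.
#'
#' @param pm a \linkS4class{PMSelection} or \linkS4class{PMAnnotation} with
#'   upper < middle < lower.
#' @param strategy 3, 5 or 9.
#' @param M number of slices in the case.
#' @return an \linkS4class{RSSet}.
#' @export
#' @examples
#' pm <- PMAnnotation(1, 31, 61)
#' rsIndices(extractRS(pm, 3, M = 75))   # 11, 31, 41
#' rsIndices(extractRS(pm, 5, M = 75))   # 11, 21, 31, 41, 51
extractRS <- function(pm, strategy, M) {
  strategy <- as.integer(strategy)
  if (!(strategy %in% c(3L, 5L, 9L))) stop("strategy must be 3, 5 or 9")
  idx <- pmIndices(pm)
  ru <- idx[["upper"]]; rm <- idx[["middle"]]; rl <- idx[["lower"]]
  if (!(ru < rm && rm < rl)) stop("PM ordering violated: need upper < middle < lower")
  if (ru < 1L || rl > M) stop("PM indices outside [1, M]")
  rs3 <- c(ru + roundHalfAway((rm - ru) / 3),
           rm,
           rm + roundHalfAway((rl - rm) / 3))
  sel <- switch(as.character(strategy),
    "3" = rs3,
    "5" = c(ru + roundHalfAway((rm - ru) / 3),
            ru + roundHalfAway(2 * (rm - ru) / 3),
            rm,
            rm + roundHalfAway((rl - rm) / 3),
            rm + roundHalfAway(2 * (rl - rm) / 3)),
    "9" = pmin(pmax(c(outer(c(-1L, 0L, 1L), rs3, "+")), 1L), M))
  sel <- sort(as.integer(sel))
  if (length(unique(sel)) < strategy)
    stop("PMs too close: ", strategy, "-RS collapses to ",
         length(unique(sel)), " distinct slices")
  src <- if (is(pm, "PMSelection")) pm else {
    new("PMSelection", caseID = caseID(pm),
        indices = c(upper = as.integer(ru), middle = as.integer(rm),
                    lower = as.integer(rl)),
        peaks = rep(NA_real_, 3), M = as.integer(M))
  }
  new("RSSet", strategy = strategy, indices = sel, source = src)
}

#' Assemble the model-ready slice stack for one case
#'
#' Orders the representative slices superior to inferior, passes each
#' through the scanner mask (if given) and the three-window RGB composite,
#' and stacks them as T x size x size x 3.
#'
#' @param volume a \linkS4class{CTVolume}.
#' @param rs an \linkS4class{RSSet} valid for the volume.
#' @param size composite side in pixels (default 518).
#' @param mask optional \linkS4class{ScannerMask}.
#' @param order windowing/resize order, see \code{\link{rgbWindowing}}.
#' @return numeric array T x size x size x 3 with 8-bit channel values.
#' @export
stackRSVolume <- function(volume, rs, size = 518L, mask = NULL,
                          order = "window_first") {
  stopifnot(is(volume, "CTVolume"), is(rs, "RSSet"))
  idx <- rsIndices(rs)
  if (any(idx < 1L) || any(idx > nSlices(volume)))
    stop("RS index out of volume range")
  out <- array(0, c(length(idx), size, size, 3L))
  for (t in seq_along(idx)) {
    hu <- getSlice(volume, idx[t])
    if (!is.null(mask)) hu <- applyScannerMask(hu, mask)
    out[t, , , ] <- rgbWindowing(hu, size = size, order = order)
  }
  out
}

#' Random-slice baseline selector
#'
#' Draws strictly increasing random slice indices; used only as the
#' comparison baseline against PM-anchored representative slices.
#'
#' @param M slice count.
#' @param strategy number of slices (3, 5 or 9).
#' @param seed RNG seed.
#' @return integer vector of sorted slice indices.
#' @export
randomSliceBaseline <- function(M, strategy, seed = 1L) {
  stopifnot(M >= strategy)
  withSeed(seed, sort(sample.int(M, strategy)))
}
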