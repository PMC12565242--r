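## HU preprocessing: display windowing, multi-window RGB fusion, scanner
## field-of-view masking, and slice export for the two model paths (single
## lung window for the PM extractor, three-window composite for the
## identifier).

#' The three fixed identification windows
#'
#' Enhanced lung (-700/700), pulmonary-embolism-specific (100/700) and
#' mediastinal (40/400) level/width pairs, stacked in this channel order by
#' \code{\link{rgbWindowing}}.
#'
#' @return list of three \linkS4class{WindowSpec} objects.
#' @export
identificationWindows <- function() {
  list(WindowSpec(-700, 700, "enhanced_lung"),
       WindowSpec(100, 700, "pe_specific"),
       WindowSpec(40, 400, "mediastinal"))
}

#' Apply a Hounsfield display window
#'
#' Maps HU to 8-bit via
#' \code{round(255 * clip((HU - (level - width/2)) / width, 0, 1))}
#' with round-half-away-from-zero quantisation; monotone non-decreasing in
#' HU. A pixel at the window level maps to 128.
#'
#' @param huImage numeric HU matrix.
#' @param window a \linkS4class{WindowSpec}.
#' @return integer matrix with values in 0..255.
#' @export
#' @examples
#' applyWindow(matrix(c(-1050, -700, -350), 1), WindowSpec(-700, 700))
applyWindow <- function(huImage, window) {
  stopifnot(is(window, "WindowSpec"))
  validObject(window)
  lowEdge <- window@level - window@width / 2
  out <- roundHalfAway(255 * clip01((huImage - lowEdge) / window@width))
  storage.mode(out) <- "integer"
  out
}

#' @keywords internal
#' @noRd
.resizeMat <- function(m, size) {
  if (nrow(m) == size && ncol(m) == size) return(m)
  as.matrix(EBImage::resize(m, w = size, h = size))
}

#' Three-window RGB composite of one HU slice
#'
#' Applies the enhanced-lung, PE-specific and mediastinal windows to a
#' single HU slice and stacks the three 8-bit channels, resized to
#' \code{size} x \code{size}. The default order windows first and then
#' resizes the 8-bit channel bilinearly; \code{order = "resize_first"}
#' resizes the HU image before windowing, making each channel exactly
#' \code{applyWindow(resize(x), window_k)}.
#'
#' @param huImage numeric HU matrix.
#' @param size output side in pixels (default 518).
#' @param order "window_first" (default) or "resize_first".
#' @return integer array \code{size x size x 3}, values 0..255, channels
#'   (enhanced-lung, PE-specific, mediastinal).
#' @export
rgbWindowing <- function(huImage, size = 518L,
                         order = c("window_first", "resize_first")) {
  order <- match.arg(order)
  wins <- identificationWindows()
  out <- array(0L, dim = c(size, size, 3L))
  for (k in 1:3) {
    ch <- if (order == "window_first") {
      ch8 <- applyWindow(huImage, wins[[k]])
      roundHalfAway(pmin(pmax(.resizeMat(ch8, size), 0), 255))
    } else {
      applyWindow(.resizeMat(huImage, size), wins[[k]])
    }
    storage.mode(ch) <- "integer"
    out[, , k] <- ch
  }
  out
}

#' Derive a unified scanner field-of-view mask
#'
#' Foreground is every pixel that rises above the outside-FOV sentinel in
#' at least one reference slice; the mask is then restricted to the largest
#' connected component (the circular reconstruction field of view).
#' Deterministic.
#'
#' @param referenceVolumes list of \linkS4class{CTVolume} objects (>= 1)
#'   from the reference facility.
#' @param sentinel HU value separating outside-FOV padding from anatomy
#'   (default -1500; scanner padding is typically about -2000 HU).
#' @param provenance reference dataset identifier.
#' @return a \linkS4class{ScannerMask}.
#' @export
deriveScannerMask <- function(referenceVolumes, sentinel = -1500,
                              provenance = "reference") {
  if (is(referenceVolumes, "CTVolume")) referenceVolumes <- list(referenceVolumes)
  stopifnot(length(referenceVolumes) >= 1)
  d <- dim(referenceVolumes[[1]]@slices[[1]])
  ever <- matrix(FALSE, d[1], d[2])
  for (vol in referenceVolumes) {
    for (sl in vol@slices) ever <- ever | (sl > sentinel)
  }
  if (!any(ever)) stop("empty foreground: no pixel above the sentinel")
  lab <- EBImage::bwlabel(ever * 1)
  sizes <- tabulate(as.integer(lab[lab > 0]))
  keep <- (as.matrix(lab) == which.max(sizes)) * 1
  new("ScannerMask", mask = keep, provenance = provenance)
}

#' Apply a scanner mask to an HU image
#'
#' Pixels outside the mask are set to -1024 HU (air); pixels inside are
#' unchanged. If grids differ the mask is resampled to the image grid by
#' nearest neighbour (disable with \code{allowResample = FALSE}).
#'
#' @param huImage numeric HU matrix.
#' @param mask a \linkS4class{ScannerMask}.
#' @param allowResample resample the mask if shapes differ (default TRUE).
#' @param fill HU value outside the mask (default -1024).
#' @return masked HU matrix.
#' @export
applyScannerMask <- function(huImage, mask, allowResample = TRUE,
                             fill = -1024) {
  stopifnot(is(mask, "ScannerMask"))
  m <- mask@mask
  if (!all(dim(m) == dim(huImage))) {
    if (!allowResample) stop("mask shape does not match image")
    ri <- roundHalfAway(seq(1, nrow(m), length.out = nrow(huImage)))
    ci <- roundHalfAway(seq(1, ncol(m), length.out = ncol(huImage)))
    m <- m[ri, ci, drop = FALSE]
  }
  out <- huImage
  out[m == 0] <- fill
  out
}

#' Export a case for the PM-extractor path
#'
#' Single enhanced-lung window (-700/700), 8-bit grayscale PNG per slice at
#' \code{size} x \code{size}, named sequentially from the apical lung to
#' the diaphragm, plus a JSON manifest.
#'
#' @param volume a \linkS4class{CTVolume}.
#' @param dir output directory.
#' @param size output side (default 256).
#' @param mask optional \linkS4class{ScannerMask} applied before windowing.
#' @param pm optional \linkS4class{PMAnnotation} recorded in the manifest.
#' @param label optional case label recorded in the manifest.
#' @return the directory, invisibly.
#' @export
exportPMSlices <- function(volume, dir, size = 256L, mask = NULL, pm = NULL,
                           label = NA_integer_) {
  stopifnot(is(volume, "CTVolume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lungWin <- WindowSpec(-700, 700, "enhanced_lung")
  for (m in seq_len(nSlices(volume))) {
    hu <- volume@slices[[m]]
    if (!is.null(mask)) hu <- applyScannerMask(hu, mask)
    img <- .resizeMat(applyWindow(hu, lungWin), size)
    img <- pmin(pmax(roundHalfAway(img), 0), 255)
    EBImage::writeImage(t(img) / 255,
                        file.path(dir, sprintf("slice_%03d.png", m)),
                        type = "png", bits = 8L)
  }
  manifest <- list(case_id = volume@caseID, n_slices = nSlices(volume),
                   size = size, site_tag = volume@siteTag,
                   label = label,
                   pm = if (is.null(pm)) NULL else as.list(pmIndices(pm)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
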