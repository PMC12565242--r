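## Minimal DICOM I/O: single-frame CT images, uncompressed, explicit VR
## little endian (transfer syntax 1.2.840.10008.1.2.1). Covers exactly what
## the pipeline needs -- HU recovery via rescale slope/intercept, axial
## ordering via ImagePositionPatient, and single-series validation.

.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"

#' @keywords internal
#' @noRd
.dcmPad <- function(raw, padByte = as.raw(0x20)) {
  if (length(raw) %% 2L == 1L) c(raw, padByte) else raw
}

#' @keywords internal
#' @noRd
.dcmUint <- function(value, size) {
  writeBin(as.integer(value), raw(), size = size, endian = "little")
}

## One explicit-VR element as raw bytes.
#' @keywords internal
#' @noRd
.dcmElement <- function(group, element, vr, value) {
  body <- switch(vr,
    US = .dcmUint(value, 2L),
    UL = .dcmUint(value, 4L),
    OW = value,  # already raw
    {  # string VRs: UI padded with NUL, the rest with space
      pad <- if (vr == "UI") as.raw(0) else as.raw(0x20)
      .dcmPad(charToRaw(as.character(value)), pad)
    })
  head <- c(.dcmUint(group, 2L), .dcmUint(element, 2L), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), .dcmUint(length(body), 4L), body)
  } else {
    c(head, .dcmUint(length(body), 2L), body)
  }
}

#' Write a CT volume as a DICOM series
#'
#' Emits one explicit-VR little-endian single-frame CT file per slice, with
#' stored values related to HU by \code{HU = stored * slope + intercept}.
#' Slices are positioned superior to inferior along decreasing patient z.
#'
#' @param volume a \linkS4class{CTVolume}.
#' @param dir output directory (created if missing).
#' @param slope,intercept rescale slope/intercept written to each file.
#' @param seriesUID series instance UID (one per call).
#' @return character vector of file paths, invisibly.
#' @export
writeDicomSeries <- function(volume, dir, slope = 1, intercept = -1024,
                             seriesUID = paste0("1.2.826.0.1.3680043.9999.",
                                                abs(sum(utf8ToInt(volume@caseID))))) {
  stopifnot(is(volume, "CTVolume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  M <- nSlices(volume)
  d <- dim(volume@slices[[1]])
  z0 <- M * volume@sliceSpacingMM
  paths <- character(M)
  for (m in seq_len(M)) {
    stored <- round((volume@slices[[m]] - intercept) / slope)
    if (any(stored < -32768 | stored > 32767))
      stop("stored pixel values exceed signed 16-bit range")
    pix <- writeBin(as.integer(as.vector(t(stored))), raw(), size = 2L,
                    endian = "little")
    z <- z0 - (m - 1) * volume@sliceSpacingMM  # superior slices: larger z
    sopUID <- paste0(seriesUID, ".", m)
    meta <- c(
      .dcmElement(0x0002, 0x0002, "UI", .SOP_CT),
      .dcmElement(0x0002, 0x0003, "UI", sopUID),
      .dcmElement(0x0002, 0x0010, "UI", .TS_EXPLICIT_LE))
    dataset <- c(
      .dcmElement(0x0008, 0x0016, "UI", .SOP_CT),
      .dcmElement(0x0008, 0x0018, "UI", sopUID),
      .dcmElement(0x0008, 0x0060, "CS", "CT"),
      .dcmElement(0x0020, 0x000D, "UI", paste0(seriesUID, ".0")),
      .dcmElement(0x0020, 0x000E, "UI", seriesUID),
      .dcmElement(0x0020, 0x0013, "IS", as.character(m)),
      .dcmElement(0x0020, 0x0032, "DS", sprintf("0\\0\\%g", z)),
      .dcmElement(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      .dcmElement(0x0028, 0x0002, "US", 1L),
      .dcmElement(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .dcmElement(0x0028, 0x0010, "US", d[1]),
      .dcmElement(0x0028, 0x0011, "US", d[2]),
      .dcmElement(0x0028, 0x0100, "US", 16L),
      .dcmElement(0x0028, 0x0101, "US", 16L),
      .dcmElement(0x0028, 0x0102, "US", 15L),
      .dcmElement(0x0028, 0x0103, "US", 1L),
      .dcmElement(0x0028, 0x1052, "DS", as.character(intercept)),
      .dcmElement(0x0028, 0x1053, "DS", as.character(slope)),
      .dcmElement(0x7FE0, 0x0010, "OW", pix))
    groupLen <- .dcmElement(0x0002, 0x0000, "UL", length(meta))
    paths[m] <- file.path(dir, sprintf("IM_%04d.dcm", m))
    con <- file(paths[m], "wb")
    writeBin(c(raw(128), charToRaw("DICM"), groupLen, meta, dataset), con)
    close(con)
  }
  invisible(paths)
}

## Parse one DICOM file; returns the tags the loader needs.
#' @keywords internal
#' @noRd
.readDicomFile <- function(path) {
  bytes <- readBin(path, raw(), n = file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file: ", path)
  pos <- 133L
  u16 <- function(i) sum(as.integer(bytes[i:(i + 1)]) * c(1, 256))
  u32 <- function(i) sum(as.integer(bytes[i:(i + 3)]) * c(1, 256, 65536, 16777216))
  out <- list()
  n <- length(bytes)
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L); body0 <- pos + 12L
    } else {
      len <- u16(pos + 6L); body0 <- pos + 8L
    }
    body <- if (len > 0) bytes[body0:(body0 + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, element)
    out[[key]] <- list(vr = vr, body = body)
    pos <- body0 + len
    if (group == 0x7FE0 && element == 0x0010) break
  }
  out
}

#' @keywords internal
#' @noRd
.dcmString <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  body <- el$body[el$body != as.raw(0)]  # strip padding nulls
  sub(" +$", "", rawToChar(body))
}

#' Load a DICOM series as a CTVolume
#'
#' Reads all \code{.dcm} files in a directory, checks that they form a
#' single axial series, recovers HU as \code{stored * slope + intercept}
#' and orders slices superior to inferior by the z component of
#' ImagePositionPatient (file order is irrelevant).
#'
#' @param path directory containing exactly one series.
#' @param siteTag facility tag attached to the volume.
#' @return a \linkS4class{CTVolume}.
#' @export
loadDicomSeries <- function(path, siteTag = "unknown") {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) < 3) stop("need at least 3 DICOM files in ", path)
  parsed <- lapply(files, .readDicomFile)
  series <- vapply(parsed, .dcmString, character(1), key = "0020,000E")
  if (length(unique(series)) != 1)
    stop("directory contains more than one series: ",
         paste(unique(series), collapse = ", "))
  zs <- vapply(parsed, function(tg) {
    ipp <- .dcmString(tg, "0020,0032")
    if (is.null(ipp)) stop("slice missing ImagePositionPatient geometry")
    as.numeric(strsplit(ipp, "\\\\")[[1]][3])
  }, numeric(1))
  ord <- order(zs, decreasing = TRUE)  # superior (head) first
  slices <- lapply(parsed[ord], function(tg) {
    rows <- readBin(tg[["0028,0010"]]$body, integer(), size = 2L,
                    endian = "little", signed = FALSE)
    cols <- readBin(tg[["0028,0011"]]$body, integer(), size = 2L,
                    endian = "little", signed = FALSE)
    slope <- as.numeric(.dcmString(tg, "0028,1053"))
    intercept <- as.numeric(.dcmString(tg, "0028,1052"))
    stored <- readBin(tg[["7FE0,0010"]]$body, integer(), n = rows * cols,
                      size = 2L, endian = "little", signed = TRUE)
    matrix(stored * slope + intercept, nrow = rows, ncol = cols, byrow = TRUE)
  })
  spacing <- if (length(zs) > 1) {
    dz <- abs(diff(sort(zs)))
    stats::median(dz)
  } else 4
  CTVolume(slices, caseID = basename(path), sliceSpacingMM = spacing,
           siteTag = siteTag)
}
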