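## Synthetic chest-CT phantoms. Geometry is defined in fractions of the
## image side so the same anatomy renders at any resolution. All HU values
## are cartoon-level: body soft tissue ~ +40, aerated lung ~ -850, tracheal
## air -1000, liver ~ +60, outside the scanner field of view -2000.

.PHANTOM <- list(
  fovRadius = 0.495, bodyRadius = 0.44,
  lungDX = 0.23, lungDY = 0.04,        # lung ellipse centres vs body centre
  tracheaDY = -0.16, tracheaR = 0.035, # single lumen above the carina
  bronchusR = 0.028, bronchusSep0 = 0.045, bronchusSepStep = 0.008,
  bronchusDepth = 9L,                  # slices the paired lumens stay visible
  columnHalfWidth = 0.08,              # mediastinal column used by derivePM
  liverDY = 0.30, liverAX = 0.30, liverAY = 0.22,
  huBody = 40, huLung = -850, huAir = -1000, huLiver = 60, huOutside = -2000,
  lungRampUp = 8L, lungOnsetScale = 0.3, lungEndScale = 0.15
)

## Lung-size multiplier g(z) in [0, 1]: 0 before onset and from the
## disappearance slice on; a steep ramp after onset, plateau, then decline.
#' @keywords internal
#' @noRd
.lungProfile <- function(z, onset, disappearance) {
  p <- .PHANTOM
  if (z < onset || z >= disappearance) return(0)
  rampEnd <- min(onset + p$lungRampUp, disappearance - 1L)
  declineStart <- max(rampEnd, disappearance - 12L)
  if (z <= rampEnd) {
    f <- if (rampEnd == onset) 1 else (z - onset) / (rampEnd - onset)
    p$lungOnsetScale + (1 - p$lungOnsetScale) * f
  } else if (z < declineStart) {
    1
  } else {
    f <- (z - declineStart) / (disappearance - declineStart)
    1 - (1 - p$lungEndScale) * f
  }
}

## Band-limited random field in [-1, 1]: coarse grid, bilinear upsampling.
#' @keywords internal
#' @noRd
.smoothField <- function(s, coarse = 8L) {
  g <- matrix(stats::runif(coarse * coarse, -1, 1), coarse, coarse)
  as.matrix(EBImage::resize(g, w = s, h = s))
}

#' Derive position-marker ground truth from a phantom schedule
#'
#' The upper PM is the apical-onset slice; the middle PM is the first
#' bifurcation slice; the lower PM sits exactly three slices superior to
#' the bilateral-disappearance slice.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return a \linkS4class{PMAnnotation}.
#' @export
#' @examples
#' pmGroundTruth(PhantomSpec(apicalOnset = 6, bifurcation = 31,
#'                           disappearance = 63))
pmGroundTruth <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  lower <- spec@disappearance - 3L
  if (lower <= spec@bifurcation)
    stop("phantom too compressed: lower PM (disappearance - 3) must lie ",
         "below the bifurcation")
  PMAnnotation(upper = spec@apicalOnset, middle = spec@bifurcation,
               lower = lower, caseID = "spec")
}

## Render one axial slice (deterministic given the RNG state).
#' @keywords internal
#' @noRd
.renderSlice <- function(z, spec, fibrosisField) {
  p <- .PHANTOM
  s <- spec@imageSize
  cx <- (s + 1) / 2; cy <- (s + 1) / 2
  x <- matrix(seq_len(s), s, s, byrow = TRUE)
  y <- matrix(seq_len(s), s, s)

  hu <- matrix(p$huOutside, s, s)
  fov <- (x - cx)^2 + (y - cy)^2 <= (p$fovRadius * s)^2
  hu[fov] <- p$huAir
  body <- (x - cx)^2 + (y - cy)^2 <= (p$bodyRadius * s)^2
  hu[body] <- p$huBody

  ## liver/diaphragm dome rising toward the base
  liverStart <- spec@disappearance - 5L
  if (z >= liverStart) {
    q <- min(1.2, 0.3 + 0.9 * (z - liverStart) / 7)
    lax <- p$liverAX * q * s; lay <- p$liverAY * q * s
    dome <- ((x - cx) / lax)^2 + ((y - (cy + p$liverDY * s)) / lay)^2 <= 1
    hu[dome & body] <- p$huLiver
  }

  ## lungs
  g <- .lungProfile(z, spec@apicalOnset, spec@disappearance)
  if (g > 0) {
    ax <- max(1.5, spec@lungGeometry[1] * g * s)
    ay <- max(1.5, spec@lungGeometry[2] * g * s)
    ly <- cy + p$lungDY * s
    for (sideSign in c(-1, 1)) {
      lx <- cx + sideSign * p$lungDX * s
      rho2 <- ((x - lx) / ax)^2 + ((y - ly) / ay)^2
      lung <- rho2 <= 1
      hu[lung] <- p$huLung
      ## subpleural fibrosis-like texture, basal-predominant, positive cases
      basalStart <- spec@bifurcation +
        (spec@disappearance - spec@bifurcation) %/% 3L
      if (spec@fibrosisSeverity > 0 && z >= basalStart &&
          z < spec@disappearance) {
        rim <- lung & rho2 >= 0.55^2
        hu[rim] <- hu[rim] + spec@fibrosisSeverity *
          (300 + 100 * fibrosisField[rim])
      }
    }
  }

  ## trachea (single lumen) then paired main-bronchus lumens from the carina
  ty <- cy + p$tracheaDY * s
  if (z < spec@bifurcation) {
    tr <- (x - cx)^2 + (y - ty)^2 <= (p$tracheaR * s)^2
    hu[tr] <- p$huAir
  } else if (z <= min(spec@bifurcation + p$bronchusDepth,
                      spec@disappearance - 2L)) {
    sep <- (p$bronchusSep0 + p$bronchusSepStep * (z - spec@bifurcation)) * s
    for (sideSign in c(-1, 1)) {
      bx <- cx + sideSign * sep
      br <- (x - bx)^2 + (y - ty)^2 <= (p$bronchusR * s)^2
      hu[br] <- p$huAir
    }
  }

  if (spec@noiseSD > 0) {
    noise <- matrix(stats::rnorm(s * s, 0, spec@noiseSD), s, s)
    hu[fov] <- hu[fov] + noise[fov]
  }
  hu
}

#' Generate one synthetic chest-CT phantom case
#'
#' Renders a deterministic (given the spec seed) stack of axial HU slices:
#' a circular body in a circular scanner field of view (corners at
#' -2000 HU), a single tracheal air lumen above the bifurcation slice and
#' two separated bronchial lumens from it downward, two lung ellipses whose
#' size follows the apical-onset/disappearance schedule, a liver dome near
#' the base, and -- for PF-ILD-positive cases -- an additive subpleural,
#' basal-predominant high-attenuation texture scaled by
#' \code{fibrosisSeverity}.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param label binary PF-ILD flag; positive cases receive the fibrosis
#'   texture (a positive label with \code{fibrosisSeverity = 0} renders no
#'   texture).
#' @param caseID case identifier.
#' @param siteTag facility tag recorded in the volume.
#' @return a \linkS4class{PhantomCase}.
#' @export
#' @examples
#' pc <- generatePhantomVolume(PhantomSpec(imageSize = 64, seed = 7))
#' pmIndices(pc@pmTruth)
generatePhantomVolume <- function(spec, label = as.integer(spec@fibrosisSeverity > 0),
                                  caseID = sprintf("phantom_%04d", spec@seed),
                                  siteTag = "synthetic") {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  pm <- pmGroundTruth(spec)
  pm@caseID <- caseID
  slices <- withSeed(spec@seed, {
    field <- .smoothField(spec@imageSize)
    lapply(seq_len(spec@nSlices), .renderSlice, spec = spec,
           fibrosisField = field)
  })
  vol <- CTVolume(slices, caseID = caseID, sliceSpacingMM = 4,
                  siteTag = siteTag)
  new("PhantomCase", volume = vol, pmTruth = pm, label = as.integer(label),
      spec = spec)
}

#' Aerated-lung pixel count per slice
#'
#' Counts pixels below -500 HU inside the body disk, excluding the central
#' mediastinal column so that tracheal/bronchial air is ignored, following
#' the labelling rule that air in the trachea does not count as lung
#' parenchyma.
#'
#' @param volume a \linkS4class{CTVolume}.
#' @return integer vector of per-slice aerated-lung pixel counts.
#' @export
aeratedLungArea <- function(volume) {
  stopifnot(is(volume, "CTVolume"))
  p <- .PHANTOM
  s <- nrow(volume@slices[[1]])
  cx <- (s + 1) / 2; cy <- (s + 1) / 2
  x <- matrix(seq_len(s), s, s, byrow = TRUE)
  y <- matrix(seq_len(s), s, s)
  body <- (x - cx)^2 + (y - cy)^2 <= (p$bodyRadius * s)^2
  column <- abs(x - cx) <= p$columnHalfWidth * s
  zone <- body & !column
  vapply(volume@slices, function(sl) sum(sl[zone] < -500), integer(1))
}

## Count air lumens inside the mediastinal column of one slice.
#' @keywords internal
#' @noRd
.lumenCount <- function(sl) {
  p <- .PHANTOM
  s <- nrow(sl)
  cx <- (s + 1) / 2; cy <- (s + 1) / 2
  x <- matrix(seq_len(s), s, s, byrow = TRUE)
  y <- matrix(seq_len(s), s, s)
  column <- abs(x - cx) <= p$columnHalfWidth * s &
    y >= cy - 0.28 * s & y <= cy - 0.04 * s
  air <- matrix(0, s, s)
  air[column & sl < -900] <- 1
  lab <- EBImage::bwlabel(air)
  tab <- tabulate(as.integer(lab[lab > 0]))
  sum(tab >= 4)  # ignore specks below 4 px
}

#' Re-derive position markers from voxel content
#'
#' Applies the labelling rules directly to a rendered volume: the upper PM
#' is the first slice with aerated lung parenchyma (tracheal air ignored);
#' the middle PM is the first slice whose mediastinal column contains two
#' distinct air lumens; the lower PM is three slices superior to the first
#' slice where aerated parenchyma is absent bilaterally.
#'
#' @param volume a \linkS4class{CTVolume}.
#' @return a \linkS4class{PMAnnotation}.
#' @export
derivePM <- function(volume) {
  stopifnot(is(volume, "CTVolume"))
  area <- aeratedLungArea(volume)
  withLung <- which(area > 0)
  if (length(withLung) == 0) stop("no aerated lung found in volume")
  upper <- withLung[1]
  after <- which(seq_along(area) > upper & area == 0)
  if (length(after) == 0)
    stop("parenchyma never disappears; cannot place the lower PM")
  disappearance <- after[1]
  lumens <- vapply(volume@slices, .lumenCount, numeric(1))
  twoLumen <- which(lumens >= 2)
  if (length(twoLumen) == 0) stop("no bifurcation found in volume")
  PMAnnotation(upper = upper, middle = twoLumen[1],
               lower = disappearance - 3L, caseID = volume@caseID)
}

#' Generate a cohort of phantom cases
#'
#' Labels are Bernoulli draws at the given prevalence; the anatomical
#' schedule of each case is jittered uniformly within the supplied ranges;
#' positive cases draw a fibrosis severity from \code{severityRange} and
#' negative cases render no fibrosis texture. Deterministic given
#' \code{seed}: each case derives a named child seed.
#'
#' @param nCases number of cases (>= 1).
#' @param prevalence PF-ILD prevalence in [0, 1].
#' @param baseSpec template \linkS4class{PhantomSpec}.
#' @param jitter named list of integer half-ranges for
#'   \code{apicalOnset}, \code{bifurcation}, \code{disappearance}.
#' @param severityRange fibrosis severity range for positive cases.
#' @param seed cohort seed.
#' @param siteTag facility tag.
#' @return list of \linkS4class{PhantomCase} objects.
#' @export
generateCohort <- function(nCases, prevalence, baseSpec = PhantomSpec(),
                           jitter = list(apicalOnset = 3L, bifurcation = 4L,
                                         disappearance = 4L),
                           severityRange = c(0.7, 1), seed = 1L,
                           siteTag = "synthetic") {
  stopifnot(nCases >= 1, prevalence >= 0, prevalence <= 1)
  draws <- withSeed(childSeed(seed, "cohort"), {
    list(labels = stats::rbinom(nCases, 1L, prevalence),
         dOn = sample(-jitter$apicalOnset:jitter$apicalOnset, nCases, TRUE),
         dBi = sample(-jitter$bifurcation:jitter$bifurcation, nCases, TRUE),
         dDi = sample(-jitter$disappearance:jitter$disappearance, nCases, TRUE),
         sev = stats::runif(nCases, severityRange[1], severityRange[2]))
  })
  lapply(seq_len(nCases), function(i) {
    onset <- baseSpec@apicalOnset + draws$dOn[i]
    bif <- baseSpec@bifurcation + draws$dBi[i]
    dis <- baseSpec@disappearance + draws$dDi[i]
    if (!(1L <= onset && onset < bif && bif < dis - 3L &&
          dis <= baseSpec@nSlices))
      stop("jitter range produced an invalid slice schedule for case ", i)
    spec <- PhantomSpec(
      nSlices = baseSpec@nSlices, apicalOnset = onset, bifurcation = bif,
      disappearance = dis, lungGeometry = baseSpec@lungGeometry,
      fibrosisSeverity = if (draws$labels[i] == 1L) draws$sev[i] else 0,
      noiseSD = baseSpec@noiseSD, imageSize = baseSpec@imageSize,
      seed = childSeed(seed, paste0("case", i)))
    generatePhantomVolume(spec, label = draws$labels[i],
                          caseID = sprintf("case_%04d", i),
                          siteTag = siteTag)
  })
}

#' Write a phantom case to disk
#'
#' On-disk layout: one 16-bit grayscale TIFF per slice
#' (\code{slice_###.tif}, stored value = round(HU) + 2048, clamped to
#' [0, 65535]) plus \code{meta.json} holding the case id, slice count,
#' ground-truth PMs, label, spacing and the HU offset.
#'
#' @param case a \linkS4class{PhantomCase}.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writePhantomCase <- function(case, dir) {
  stopifnot(is(case, "PhantomCase"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  offset <- 2048
  for (m in seq_len(nSlices(case))) {
    stored <- pmin(pmax(round(getSlice(case, m)) + offset, 0), 65535)
    ## (0.5 offset keeps exact integers stable under the writer's
    ## truncating quantisation)
    EBImage::writeImage(pmin(t(stored + 0.5) / 65535, 1),
                        file.path(dir, sprintf("slice_%03d.tif", m)),
                        type = "tiff", bits.per.sample = 16L)
  }
  meta <- list(case_id = caseID(case), n_slices = nSlices(case),
               pm = as.list(pmIndices(case@pmTruth)), label = case@label,
               slice_spacing_mm = case@volume@sliceSpacingMM,
               site_tag = case@volume@siteTag, hu_offset = offset,
               image_size = nrow(getSlice(case, 1)))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a phantom case written by \code{writePhantomCase}
#'
#' @param dir case directory containing slice PNGs and \code{meta.json}.
#' @return a list with elements \code{volume} (\linkS4class{CTVolume}),
#'   \code{pm} (\linkS4class{PMAnnotation}) and \code{label}.
#' @export
readPhantomCase <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  files <- file.path(dir, sprintf("slice_%03d.tif", seq_len(meta$n_slices)))
  slices <- lapply(files, function(f) {
    img <- EBImage::readImage(f)
    round(t(as.matrix(img)) * 65535) - meta$hu_offset
  })
  vol <- CTVolume(slices, caseID = meta$case_id,
                  sliceSpacingMM = meta$slice_spacing_mm,
                  siteTag = meta$site_tag)
  pm <- PMAnnotation(meta$pm$upper, meta$pm$middle, meta$pm$lower,
                     caseID = meta$case_id)
  list(volume = vol, pm = pm, label = as.integer(meta$label))
}
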