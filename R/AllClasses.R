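#' @import methods
NULL

#' Set of named elliptical regions of interest
#'
#' An ordered collection of axis-aligned elliptical ROIs, the unit of eye
#' segmentation. Each ROI is described by its bounding box in 0-based pixel
#' coordinates (origin top-left, x rightward, y downward) and carries a
#' colon-delimited name encoding the experimental factors
#' (\code{sex:genotype:replicate:user[:extras...]}). Bounding boxes may
#' extend past image edges; extraction clips to image bounds. Order is
#' preserved exactly as read, because pixel extraction iterates ROIs in set
#' order.
#'
#' @slot name character vector of unique ROI names.
#' @slot x0,y0 integer vectors, left/top of each bounding box (0-based).
#' @slot width,height integer vectors, bounding box extent in pixels
#'   (both >= 1).
#' @slot source scalar character, provenance of the set (file path or
#'   \code{"synthetic"}).
#'
#' @seealso [RoiSet()] (constructor), [readRois()], [writeRois()],
#'   [containedPixels()]
#' @export
setClass("RoiSet",
  representation(
    name = "character",
    x0 = "integer", y0 = "integer",
    width = "integer", height = "integer",
    source = "character"
  ),
  prototype(
    name = character(0),
    x0 = integer(0), y0 = integer(0),
    width = integer(0), height = integer(0),
    source = "unknown"
  )
)

setValidity("RoiSet", function(object) {
  n <- length(object@name)
  msg <- character(0)
  if (length(object@x0) != n || length(object@y0) != n ||
      length(object@width) != n || length(object@height) != n)
    msg <- c(msg, "coordinate slots must have the same length as 'name'")
  if (anyDuplicated(object@name))
    msg <- c(msg, sprintf(
      "duplicate ROI names: %s",
      paste(unique(object@name[duplicated(object@name)]), collapse = ", ")))
  if (n > 0 && (any(object@width < 1L) || any(object@height < 1L)))
    msg <- c(msg, "ROI width and height must be >= 1 pixel")
  if (length(object@source) != 1L)
    msg <- c(msg, "'source' must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a RoiSet
#'
#' @param name character vector of unique ROI names.
#' @param x0,y0 left/top bounding-box corner, 0-based pixels.
#' @param width,height bounding-box extent in pixels (>= 1).
#' @param source provenance string (file path or \code{"synthetic"}).
#' @return A [RoiSet-class] object.
#' @examples
#' RoiSet(c("F:wt:1:A", "M:wt:1:A"), x0 = c(0, 50), y0 = c(0, 0),
#'        width = c(40, 40), height = c(30, 30))
#' @export
RoiSet <- function(name = character(0), x0 = integer(0), y0 = integer(0),
                   width = integer(0), height = integer(0),
                   source = "unknown") {
  new("RoiSet",
      name = as.character(name),
      x0 = as.integer(round(x0)), y0 = as.integer(round(y0)),
      width = as.integer(round(width)), height = as.integer(round(height)),
      source = as.character(source))
}

#' Bootstrap mean-difference effect size
#'
#' The mean pigment difference between two groups of eyes (mean of per-eye
#' means in group B minus group A) with a bootstrap 95\% confidence interval
#' and full resampling provenance, following the estimation-statistics
#' framing (effect sizes and CIs rather than p-values).
#'
#' @slot groupA,groupB group labels.
#' @slot diff point estimate, pigment units (mean B - mean A).
#' @slot ciLow,ciHigh bootstrap 95\% CI bounds.
#' @slot nA,nB number of eyes per group.
#' @slot nBoot number of bootstrap resamples.
#' @slot seed RNG seed used for resampling.
#' @slot method \code{"bca"} or \code{"percentile"}.
#'
#' @seealso [meanDifference()]
#' @export
setClass("EffectSize",
  representation(
    groupA = "character", groupB = "character",
    diff = "numeric", ciLow = "numeric", ciHigh = "numeric",
    nA = "integer", nB = "integer",
    nBoot = "integer", seed = "integer", method = "character"
  )
)

setValidity("EffectSize", function(object) {
  msg <- character(0)
  if (!(object@method %in% c("bca", "percentile")))
    msg <- c(msg, "method must be 'bca' or 'percentile'")
  if (object@ciLow > object@diff + 1e-8 || object@ciHigh < object@diff - 1e-8)
    msg <- c(msg, "confidence interval must contain the point estimate")
  if (object@nA < 2L || object@nB < 2L)
    msg <- c(msg, "each group needs at least 2 eyes")
  if (length(msg)) msg else TRUE
})

#' Synthetic genotype (pigment distribution) specification
#'
#' Declares how a synthetic eye of a given genotype is filled with pigment
#' intensities: a constant value, per-pixel Gaussian noise, a spatially
#' clustered two-component mixture (emulating position-effect variegation
#' mosaics), or a dorsoventral gradient.
#'
#' @slot name genotype label (must not contain the name delimiter).
#' @slot distribution a distribution descriptor from [distConstant()],
#'   [distNormal()], [distMixture()] or [distGradient()].
#' @slot eyeAxes numeric(2), ellipse semi-axes (a, b) in pixels.
#'
#' @seealso [genotypeSpec()], [genotypePresets()], [renderPlate()]
#' @export
setClass("GenotypeSpec",
  representation(name = "character", distribution = "list",
                 eyeAxes = "numeric")
)

setValidity("GenotypeSpec", function(object) {
  msg <- character(0)
  d <- object@distribution
  if (is.null(d$kind) ||
      !(d$kind %in% c("constant", "normal", "mixture", "gradient")))
    msg <- c(msg, "unknown distribution kind")
  vals <- switch(d$kind %||% "",
    constant = d$v, normal = d$mu,
    mixture = c(d$v1, d$v2), gradient = c(d$vTop, d$vBottom),
    numeric(0))
  if (length(vals) && (any(vals < 0) || any(vals > 255)))
    msg <- c(msg, "target intensities must lie in [0, 255]")
  if (identical(d$kind, "mixture") && (d$p <= 0 || d$p >= 1))
    msg <- c(msg, "mixture proportion must lie in (0, 1)")
  if (length(object@eyeAxes) != 2L || any(object@eyeAxes < 1))
    msg <- c(msg, "eyeAxes must be two semi-axes >= 1 pixel")
  if (length(msg)) msg else TRUE
})

#' Synthetic plate specification
#'
#' Describes a plate image of elliptical "eyes" arranged on a grid with a
#' uniform background (the sample tray) and an optional neutral color-checker
#' strip, mimicking the physical layout of flies on a grooved tray with a
#' color control.
#'
#' @slot nrow,ncol grid dimensions.
#' @slot cellSize integer(2), (height, width) of each grid cell in pixels.
#' @slot assignment character vector of genotype names, length nrow*ncol,
#'   filled row by row; \code{NA} leaves a cell empty.
#' @slot background background pigment intensity (0-255).
#' @slot checker logical, render a grayscale patch strip along the top.
#' @slot seed integer RNG seed; rendering is deterministic given the seed.
#'
#' @seealso [plateSpec()], [renderPlate()]
#' @export
setClass("PlateSpec",
  representation(nrow = "integer", ncol = "integer", cellSize = "integer",
                 assignment = "character", background = "numeric",
                 checker = "logical", seed = "integer")
)

setValidity("PlateSpec", function(object) {
  msg <- character(0)
  if (object@nrow < 1L || object@ncol < 1L)
    msg <- c(msg, "grid must be at least 1x1")
  if (length(object@assignment) != object@nrow * object@ncol)
    msg <- c(msg, "assignment length must equal nrow * ncol")
  if (object@background < 0 || object@background > 255)
    msg <- c(msg, "background intensity must lie in [0, 255]")
  if (length(object@cellSize) != 2L || any(object@cellSize < 8L))
    msg <- c(msg, "cellSize must be two pixel counts >= 8")
  if (length(msg)) msg else TRUE
})

#' Operator segmentation jitter parameters
#'
#' Models inter-operator variability in manual ellipse placement: each
#' simulated operator re-draws every ROI with its center perturbed by
#' Gaussian noise and its semi-axes rescaled by a Gaussian relative factor.
#'
#' @slot centerSd SD of the center perturbation per axis, pixels (>= 0).
#' @slot axisRelSd SD of the relative axis rescaling, in [0, 0.5).
#' @slot nOperators number of simulated operators.
#' @slot seed integer RNG seed.
#'
#' @seealso [jitterParams()], [jitterRois()]
#' @export
setClass("JitterParams",
  representation(centerSd = "numeric", axisRelSd = "numeric",
                 nOperators = "integer", seed = "integer")
)

setValidity("JitterParams", function(object) {
  msg <- character(0)
  if (object@centerSd < 0) msg <- c(msg, "centerSd must be >= 0")
  if (object@axisRelSd < 0 || object@axisRelSd >= 0.5)
    msg <- c(msg, "axisRelSd must lie in [0, 0.5)")
  if (object@nOperators < 1L) msg <- c(msg, "need at least 1 operator")
  if (length(msg)) msg else TRUE
})

#' Synthetic defocus stack specification
#'
#' Describes a z-stack acquired over a 3-D sample: each slice is focused at a
#' plane \code{i * stepSize} and every pixel is blurred in proportion to the
#' distance between its depth and the focal plane.
#'
#' @slot nSteps number of rail steps (slice count is nSteps + 1).
#' @slot stepSize step size in micrometres (> 0).
#' @slot depthMap numeric matrix of per-pixel depths in micrometres, same
#'   height/width as the image.
#' @slot blurScale defocus coefficient: Gaussian blur sigma in pixels per
#'   micrometre of defocus.
#'
#' @seealso [stackSpec()], [renderStack()], [focusStack()]
#' @export
setClass("StackSpec",
  representation(nSteps = "integer", stepSize = "numeric",
                 depthMap = "matrix", blurScale = "numeric")
)

setValidity("StackSpec", function(object) {
  msg <- character(0)
  if (object@nSteps < 1L) msg <- c(msg, "nSteps must be >= 1")
  if (object@stepSize <= 0) msg <- c(msg, "stepSize must be > 0")
  if (object@blurScale < 0) msg <- c(msg, "blurScale must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Focus-stack acquisition plan
#'
#' Arithmetic of a motorized-rail acquisition: travelling a depth range in
#' fixed steps produces \code{nSteps = ceiling(range / step)} steps and
#' \code{nSteps + 1} images at offsets \code{0, step, ..., nSteps * step}.
#'
#' @slot depthRange total rail travel, micrometres.
#' @slot stepSize step size, micrometres.
#' @slot nSteps number of steps.
#' @slot nImages number of images (nSteps + 1).
#' @slot positions numeric vector of focal offsets in micrometres.
#'
#' @seealso [planAcquisition()]
#' @export
setClass("AcquisitionPlan",
  representation(depthRange = "numeric", stepSize = "numeric",
                 nSteps = "integer", nImages = "integer",
                 positions = "numeric")
)

setValidity("AcquisitionPlan", function(object) {
  msg <- character(0)
  if (object@nImages != object@nSteps + 1L)
    msg <- c(msg, "nImages must equal nSteps + 1")
  if (length(object@positions) != object@nImages)
    msg <- c(msg, "positions must have one entry per image")
  if (length(msg)) msg else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a
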