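#' @describeIn RoiSet-class number of ROIs in the set.
#' @param x a \code{RoiSet}.
#' @export
setMethod("length", "RoiSet", function(x) length(x@name))

#' ROI names
#'
#' @param x a [RoiSet-class].
#' @return Character vector of ROI names, in set order.
#' @export
roiNames <- function(x) {
  stopifnot(is(x, "RoiSet"))
  x@name
}

#' ROI bounding boxes as a data frame
#'
#' @param x a [RoiSet-class].
#' @return \code{data.frame} with columns \code{name, x0, y0, width, height}
#'   in set order (0-based pixel coordinates).
#' @export
roiBounds <- function(x) {
  stopifnot(is(x, "RoiSet"))
  data.frame(name = x@name, x0 = x@x0, y0 = x@y0,
             width = x@width, height = x@height,
             stringsAsFactors = FALSE)
}

#' Provenance of a RoiSet
#'
#' @param x a [RoiSet-class].
#' @return Scalar character: the file the set was read from, or
#'   \code{"synthetic"}.
#' @export
roiSource <- function(x) {
  stopifnot(is(x, "RoiSet"))
  x@source
}

#' @describeIn RoiSet-class subset ROIs by position, name or logical index;
#'   order of \code{i} is preserved.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "RoiSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    idx <- match(i, x@name)
    if (anyNA(idx))
      stop("unknown ROI name(s): ", paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  initialize(x, name = x@name[i], x0 = x@x0[i], y0 = x@y0[i],
             width = x@width[i], height = x@height[i])
})

setMethod("show", "RoiSet", function(object) {
  cat(sprintf("RoiSet of %d elliptical ROI%s (source: %s)\n",
              length(object), if (length(object) == 1L) "" else "s",
              object@source))
  if (length(object)) {
    df <- roiBounds(object)
    show_n <- min(nrow(df), 6L)
    print(df[seq_len(show_n), ], row.names = FALSE)
    if (nrow(df) > show_n)
      cat(sprintf("... and %d more\n", nrow(df) - show_n))
  }
})

#' @describeIn RoiSet-class coerce to the bounding-box data frame (same as
#'   [roiBounds()]).
#' @param row.names,optional passed on as usual.
#' @export
setMethod("as.data.frame", "RoiSet",
  function(x, row.names = NULL, optional = FALSE, ...) roiBounds(x))

setMethod("show", "EffectSize", function(object) {
  cat(sprintf(
    "Mean pigment difference %s vs %s: %.3f [95%%CI %.3f, %.3f]\n",
    object@groupB, object@groupA, object@diff, object@ciLow, object@ciHigh))
  cat(sprintf("  n = %d vs %d eyes; %d bootstrap resamples (%s), seed %d\n",
              object@nB, object@nA, object@nBoot, object@method,
              object@seed))
})

#' Point estimate of an effect size
#' @param x an [EffectSize-class].
#' @return The mean difference (group B minus group A), pigment units.
#' @export
effectEstimate <- function(x) {
  stopifnot(is(x, "EffectSize"))
  x@diff
}

#' Bootstrap confidence interval of an effect size
#' @param x an [EffectSize-class].
#' @return Numeric(2): lower and upper 95\% CI bounds.
#' @export
effectCI <- function(x) {
  stopifnot(is(x, "EffectSize"))
  c(lower = x@ciLow, upper = x@ciHigh)
}

#' @describeIn EffectSize-class one-row data frame of all fields.
#' @param x an \code{EffectSize}.
#' @param row.names,optional,... passed on as usual.
#' @export
setMethod("as.data.frame", "EffectSize",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(groupA = x@groupA, groupB = x@groupB, diff = x@diff,
               ciLow = x@ciLow, ciHigh = x@ciHigh, nA = x@nA, nB = x@nB,
               nBoot = x@nBoot, seed = x@seed, method = x@method,
               stringsAsFactors = FALSE)
  })

setMethod("show", "AcquisitionPlan", function(object) {
  cat(sprintf(
    "Acquisition plan: %.0f um travel in %d steps of %.0f um -> %d images\n",
    object@depthRange, object@nSteps, object@stepSize, object@nImages))
})

setMethod("show", "GenotypeSpec", function(object) {
  d <- object@distribution
  desc <- switch(d$kind,
    constant = sprintf("constant(%g)", d$v),
    normal = sprintf("normal(mu = %g, sigma = %g)", d$mu, d$sigma),
    mixture = sprintf("mixture(%g, %g, p = %g, patchScale = %g)",
                      d$v1, d$v2, d$p, d$patchScale),
    gradient = sprintf("gradient(top = %g, bottom = %g)", d$vTop, d$vBottom))
  cat(sprintf("GenotypeSpec '%s': %s, eye semi-axes (%g, %g) px\n",
              object@name, desc, object@eyeAxes[1], object@eyeAxes[2]))
})

setMethod("show", "PlateSpec", function(object) {
  cat(sprintf(
    "PlateSpec: %d x %d grid, cell %d x %d px, background %g, checker %s, seed %d\n",
    object@nrow, object@ncol, object@cellSize[1], object@cellSize[2],
    object@background, object@checker, object@seed))
})
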