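# Distribution descriptors for synthetic eyes --------------------------------

#' Pigment distribution descriptors for synthetic eyes
#'
#' Constructors for the four per-eye pigment patterns the generator can
#' render: a constant intensity, per-pixel Gaussian noise, a spatially
#' clustered two-level mixture (the mosaic pattern of position-effect
#' variegation, modelled as thresholded smoothed noise with correlation
#' length \code{patchScale}), and a top-to-bottom linear gradient
#' (dorsoventrally patterned eyes).
#'
#' @param v,mu,v1,v2,vTop,vBottom target pigment intensities in [0, 255].
#' @param sigma per-pixel Gaussian SD, pigment units.
#' @param p proportion of the eye at intensity \code{v1}, in (0, 1).
#' @param patchScale spatial correlation length of the mosaic patches,
#'   pixels.
#' @return A distribution descriptor list for [genotypeSpec()].
#' @name distributions
#' @export
distConstant <- function(v) list(kind = "constant", v = v)

#' @rdname distributions
#' @export
distNormal <- function(mu, sigma) list(kind = "normal", mu = mu,
                                       sigma = sigma)

#' @rdname distributions
#' @export
distMixture <- function(v1, v2, p = 0.5, patchScale = 6)
  list(kind = "mixture", v1 = v1, v2 = v2, p = p, patchScale = patchScale)

#' @rdname distributions
#' @export
distGradient <- function(vTop, vBottom)
  list(kind = "gradient", vTop = vTop, vBottom = vBottom)

#' Construct a GenotypeSpec
#'
#' @param name genotype label (no delimiter characters).
#' @param distribution a descriptor from [distConstant()] and friends.
#' @param eyeAxes numeric(2), ellipse semi-axes (a, b) in pixels.
#' @return A [GenotypeSpec-class].
#' @export
genotypeSpec <- function(name, distribution, eyeAxes = c(34, 26)) {
  new("GenotypeSpec", name = name, distribution = distribution,
      eyeAxes = as.numeric(eyeAxes))
}

#' Default genotype presets
#'
#' Seven synthetic stocks mirroring the phenotypic range of a typical eye
#' pigmentation experiment: a white-eyed null (\code{yw}, constant at the
#' white reference intensity 35), a light mini-white transgene, a strongly
#' variegating stock with bimodal mosaic patches, a dorsoventrally graded
#' "dorsal eye" stock, the classic intermediate variegating \code{wm4}
#' inversion, and two wild-type stocks centred at the wild-type reference
#' intensity 140 (one constant, one with biological scatter). The two
#' reference-anchored targets (35, 140) are the workflow's published
#' calibration constants; the intermediate targets are generator
#' parameters, not measured claims.
#'
#' @return Named list of seven [GenotypeSpec-class] objects.
#' @export
genotypePresets <- function() {
  refs <- referenceLines()
  specs <- list(
    genotypeSpec("yw", distConstant(refs[["white"]])),
    genotypeSpec("mini-white", distNormal(60, 8)),
    genotypeSpec("strongPEV", distMixture(35, 110, p = 0.6, patchScale = 6)),
    genotypeSpec("dorsal-eye", distGradient(150, 45)),
    genotypeSpec("wm4", distMixture(50, 140, p = 0.5, patchScale = 8)),
    genotypeSpec("wt1", distConstant(refs[["wildtype"]])),
    genotypeSpec("wt2", distNormal(refs[["wildtype"]], 7)))
  names(specs) <- vapply(specs, function(s) s@name, character(1))
  specs
}

#' Construct a PlateSpec
#'
#' @param nrow,ncol grid dimensions.
#' @param assignment character vector (length nrow*ncol, row-major) of
#'   genotype names; \code{NA} leaves a cell empty. A shorter vector is
#'   recycled column-wise so that each column holds one genotype.
#' @param cellSize (height, width) of a grid cell, pixels.
#' @param background tray pigment intensity.
#' @param checker render a neutral patch strip along the top.
#' @param seed RNG seed.
#' @return A [PlateSpec-class].
#' @export
plateSpec <- function(nrow, ncol, assignment, cellSize = c(96, 110),
                      background = 12, checker = TRUE, seed = 1L) {
  assignment <- rep(as.character(assignment),
                    length.out = nrow * ncol)
  new("PlateSpec", nrow = as.integer(nrow), ncol = as.integer(ncol),
      cellSize = as.integer(cellSize), assignment = assignment,
      background = background, checker = checker, seed = as.integer(seed))
}

# Gaussian blur whose kernel never exceeds the image (EBImage's filter2
# requires filter dims <= image dims).
.gblurSafe <- function(x, sigma) {
  radius <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  maxOdd <- min(dim(x)[1:2])
  if (maxOdd %% 2L == 0L) maxOdd <- maxOdd - 1L
  EBImage::gblur(x, sigma = sigma, radius = min(radius, maxOdd))
}

# RGB ramp with an exact pigment-value inverse --------------------------------

.rampCache <- new.env(parent = emptyenv())

.buildRamp <- function() {
  if (!is.null(.rampCache$lut)) return(.rampCache$lut)
  lut <- matrix(NA_integer_, nrow = 256, ncol = 3)
  for (v in 0:255) {
    # continuous white -> red -> black ramp in inverted space
    if (v <= 179) {
      riC <- 0
      biC <- min(255, v * 255 / 179 * 1.3)
      giC <- min(255, max(0, (v - 0.114 * biC) / 0.587))
    } else {
      riC <- min(255, max(0, (v - 178.755) / 0.299))
      giC <- 255; biC <- 255
    }
    cand <- NULL
    deltas <- expand.grid(dr = -2:2, dg = -3:3, db = -12:12)
    deltas <- deltas[order(abs(deltas$dr) * 6 + abs(deltas$dg) * 3 +
                             abs(deltas$db)), ]
    for (j in seq_len(nrow(deltas))) {
      ri <- round(riC) + deltas$dr[j]
      gi <- round(giC) + deltas$dg[j]
      bi <- round(biC) + deltas$db[j]
      if (ri < 0 || ri > 255 || gi < 0 || gi > 255 || bi < 0 || bi > 255)
        next
      if (.roundHalfUp(0.299 * ri + 0.587 * gi + 0.114 * bi) == v) {
        cand <- c(ri, gi, bi)
        break
      }
    }
    if (is.null(cand)) {
      # exhaustive fallback: sweep gi, solve bi near its continuous value
      found <- FALSE
      for (gi in 0:255) {
        for (bi in 0:255) {
          ri <- round(riC)
          if (.roundHalfUp(0.299 * ri + 0.587 * gi + 0.114 * bi) == v) {
            cand <- c(ri, gi, bi); found <- TRUE; break
          }
        }
        if (found) break
      }
      if (!found) stop("no RGB triple found for intensity ", v)
    }
    lut[v + 1, ] <- 255L - as.integer(cand)
  }
  .rampCache$lut <- lut
  lut
}

#' Map a pigment intensity to an RGB color
#'
#' Inverse of [pigmentValue()] along a white-to-red-to-dark-brown eye-color
#' ramp: for every integer intensity \code{v} in 0..255,
#' \code{pigmentValue(intensityToRgb(v)) == v} exactly under the package's
#' rounding convention. The red channel saturates first, mimicking the
#' dark-red pigmented phenotype. Endpoints: 0 maps to pure white, 255 to
#' pure black.
#'
#' @param v integer pigment intensity (vectorized), in [0, 255].
#' @return Integer matrix with one row per input and columns
#'   \code{r, g, b}.
#' @export
intensityToRgb <- function(v) {
  if (any(v < 0 | v > 255 | v != floor(v)))
    stop("intensity must be an integer in [0, 255]")
  lut <- .buildRamp()
  out <- lut[v + 1, , drop = FALSE]
  colnames(out) <- c("r", "g", "b")
  out
}

# Plate rendering -------------------------------------------------------------

.sampleIntensities <- function(dist, px, bbox) {
  n <- nrow(px)
  switch(dist$kind,
    constant = rep(as.integer(round(dist$v)), n),
    normal = as.integer(.roundHalfUp(
      pmin(255, pmax(0, stats::rnorm(n, dist$mu, dist$sigma))))),
    gradient = {
      span <- max(1L, bbox$height - 1L)
      frac <- (px$y - bbox$y0) / span
      as.integer(.roundHalfUp(
        pmin(255, pmax(0, dist$vTop + frac * (dist$vBottom - dist$vTop)))))
    },
    mixture = {
      field <- matrix(stats::rnorm(bbox$height * bbox$width),
                      nrow = bbox$height)
      if (dist$patchScale > 0)
        field <- .gblurSafe(field, dist$patchScale)
      thr <- stats::quantile(field, dist$p)
      vals <- ifelse(field <= thr, dist$v1, dist$v2)
      as.integer(round(vals[cbind(px$y - bbox$y0 + 1L,
                                  px$x - bbox$x0 + 1L)]))
    },
    stop("unknown distribution kind: ", dist$kind))
}

.distTargetMean <- function(dist) {
  switch(dist$kind,
    constant = dist$v,
    normal = dist$mu,
    mixture = dist$p * dist$v1 + (1 - dist$p) * dist$v2,
    gradient = (dist$vTop + dist$vBottom) / 2)
}

#' Render a synthetic plate image with ground truth
#'
#' Draws a plate of elliptical "eyes" on a uniform tray background, each
#' filled according to its genotype's pigment distribution and colored
#' through the exact-inverse ramp of [intensityToRgb()] (so a constant eye
#' extracts back to its target intensity exactly). Eyes sit on a grid, one
#' per cell, fully inside the image and non-overlapping; an optional
#' neutral patch strip emulates the color control. Ground-truth ROIs are
#' named \code{sex:genotype:replicate:truth}. Rendering is deterministic
#' given the plate spec's seed.
#'
#' @param spec a [PlateSpec-class].
#' @param genotypes named list of [GenotypeSpec-class] (default
#'   [genotypePresets()]); every name in the plate assignment must be
#'   present.
#' @return List with elements \code{image} (integer RGB array),
#'   \code{rois} (ground-truth [RoiSet-class]) and \code{metadata}
#'   (data.frame: name, genotype, row, col, targetMean).
#' @seealso [extractPixels()], [jitterRois()]
#' @export
renderPlate <- function(spec, genotypes = genotypePresets()) {
  stopifnot(is(spec, "PlateSpec"))
  validObject(spec)
  used <- unique(spec@assignment[!is.na(spec@assignment)])
  missing <- setdiff(used, names(genotypes))
  if (length(missing))
    stop("unknown genotype(s) in assignment: ",
         paste(missing, collapse = ", "))
  cellH <- spec@cellSize[1]; cellW <- spec@cellSize[2]
  for (g in used) {
    ax <- genotypes[[g]]@eyeAxes
    if (2 * ax[1] > cellW - 4 || 2 * ax[2] > cellH - 4)
      stop("eye of genotype '", g, "' does not fit its cell: ",
           "overlapping layout")
  }
  band <- if (spec@checker) 24L else 0L
  H <- band + spec@nrow * cellH
  W <- spec@ncol * cellW
  bg <- intensityToRgb(as.integer(round(spec@background)))
  img <- array(0L, dim = c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- bg[ch]
  if (spec@checker) {
    grays <- as.integer(round(seq(255, 0, length.out = 6)))
    for (k in seq_along(grays)) {
      xs <- (4 + (k - 1) * 20):(4 + (k - 1) * 20 + 15)
      if (max(xs) < W) img[5:20, xs + 1, ] <- grays[k]
    }
  }
  roiName <- character(0); roiX0 <- roiY0 <- roiW <- roiH <- integer(0)
  meta <- list()
  repCount <- integer(0)
  withr::with_seed(spec@seed, {
    for (r in seq_len(spec@nrow)) {
      for (cc in seq_len(spec@ncol)) {
        idx <- (r - 1) * spec@ncol + cc
        g <- spec@assignment[idx]
        if (is.na(g)) next
        gs <- genotypes[[g]]
        a <- gs@eyeAxes[1]; b <- gs@eyeAxes[2]
        cx <- (cc - 1) * cellW + cellW / 2
        cy <- band + (r - 1) * cellH + cellH / 2
        x0 <- as.integer(round(cx - a)); w <- as.integer(round(2 * a))
        y0 <- as.integer(round(cy - b)); h <- as.integer(round(2 * b))
        bbox <- list(x0 = x0, y0 = y0, width = w, height = h)
        px <- containedPixels(bbox, W, H)
        vals <- .sampleIntensities(gs@distribution, px, bbox)
        rgb <- intensityToRgb(vals)
        for (ch in 1:3)
          img[cbind(px$y + 1L, px$x + 1L, ch)] <- rgb[, ch]
        repCount[g] <- (if (is.na(repCount[g])) 0L else repCount[g]) + 1L
        rep_i <- repCount[[g]]
        sex <- if (rep_i %% 2L == 1L) "F" else "M"
        nm <- paste(sex, g, rep_i, "truth", sep = ":")
        roiName <- c(roiName, nm)
        roiX0 <- c(roiX0, x0); roiY0 <- c(roiY0, y0)
        roiW <- c(roiW, w); roiH <- c(roiH, h)
        meta[[length(meta) + 1L]] <- data.frame(
          name = nm, genotype = g, row = r, col = cc,
          targetMean = .distTargetMean(gs@distribution),
          stringsAsFactors = FALSE)
      }
    }
  })
  list(image = img,
       rois = RoiSet(roiName, roiX0, roiY0, roiW, roiH,
                     source = "synthetic"),
       metadata = do.call(rbind, meta))
}

# Operator jitter --------------------------------------------------------------

#' Construct JitterParams
#'
#' Defaults (\code{centerSd} = 2 px, \code{axisRelSd} = 0.05, 5 operators)
#' model the placement scatter of trained human operators re-drawing the
#' same ellipse.
#'
#' @param centerSd SD of the center perturbation per axis, pixels.
#' @param axisRelSd SD of the relative semi-axis rescaling.
#' @param nOperators number of simulated operators.
#' @param seed RNG seed.
#' @return A [JitterParams-class].
#' @export
jitterParams <- function(centerSd = 2, axisRelSd = 0.05, nOperators = 5L,
                         seed = 1L) {
  new("JitterParams", centerSd = centerSd, axisRelSd = axisRelSd,
      nOperators = as.integer(nOperators), seed = as.integer(seed))
}

#' Simulate operators independently re-segmenting the same image
#'
#' For each simulated operator, every ground-truth ROI is re-drawn with its
#' center perturbed by N(0, centerSd^2) per axis and each semi-axis scaled
#' by (1 + N(0, axisRelSd^2)); jitter that would produce a non-positive
#' axis is resampled with a warning. ROI names are preserved except that
#' the \code{user} field is set to the operator id (\code{"op1"},
#' \code{"op2"}, ...). Deterministic given the params' seed.
#'
#' @param truth ground-truth [RoiSet-class].
#' @param params a [JitterParams-class].
#' @param schema name schema used to locate the \code{user} field.
#' @return List of [RoiSet-class], one per operator.
#' @export
jitterRois <- function(truth, params = jitterParams(),
                       schema = c("sex", "genotype", "replicate", "user")) {
  stopifnot(is(truth, "RoiSet"), is(params, "JitterParams"))
  validObject(params)
  lapply(seq_len(params@nOperators), function(k) {
    op <- sprintf("op%d", k)
    withr::with_seed(params@seed + k, {
      n <- length(truth)
      x0 <- y0 <- w <- h <- integer(n)
      for (i in seq_len(n)) {
        cx <- truth@x0[i] + truth@width[i] / 2 +
          stats::rnorm(1, 0, params@centerSd)
        cy <- truth@y0[i] + truth@height[i] / 2 +
          stats::rnorm(1, 0, params@centerSd)
        a <- truth@width[i] / 2; b <- truth@height[i] / 2
        repeat {
          aj <- a * (1 + stats::rnorm(1, 0, params@axisRelSd))
          bj <- b * (1 + stats::rnorm(1, 0, params@axisRelSd))
          if (aj > 0.5 && bj > 0.5) break
          warning("resampling jitter that produced a non-positive axis")
        }
        x0[i] <- as.integer(round(cx - aj))
        y0[i] <- as.integer(round(cy - bj))
        w[i] <- max(1L, as.integer(round(2 * aj)))
        h[i] <- max(1L, as.integer(round(2 * bj)))
      }
      nms <- vapply(truth@name, function(nm) {
        key <- parseRoiName(nm, schema = schema)
        key$user <- op
        formatRoiName(key)
      }, character(1), USE.NAMES = FALSE)
      RoiSet(nms, x0, y0, w, h, source = sprintf("synthetic:%s", op))
    })
  })
}

# Defocus stacks ----------------------------------------------------------------

#' Construct a StackSpec
#'
#' @param nSteps number of rail steps (slices = nSteps + 1).
#' @param stepSize step size, micrometres.
#' @param depthMap numeric matrix of per-pixel depths, micrometres.
#' @param blurScale blur sigma in pixels per micrometre of defocus.
#' @return A [StackSpec-class].
#' @export
stackSpec <- function(nSteps = 55L, stepSize = 50, depthMap,
                      blurScale = 0.004) {
  new("StackSpec", nSteps = as.integer(nSteps), stepSize = stepSize,
      depthMap = depthMap, blurScale = blurScale)
}

#' Render a synthetic defocus z-stack
#'
#' Emulates the image stack a camera on a motorized rail produces over a
#' 3-D sample: slice i is focused at depth \code{i * stepSize} and every
#' pixel is Gaussian-blurred with sigma
#' \code{blurScale * |depth - focalPlane|} pixels. Blur sigmas are
#' quantized to 0.25-px steps so that each slice needs only a handful of
#' full-image convolutions. A pixel whose depth equals the focal plane is
#' reproduced exactly.
#'
#' @param sharp integer RGB array, the all-in-focus ground truth.
#' @param spec a [StackSpec-class] whose depth map matches the image.
#' @return List with \code{slices} (list of nSteps + 1 integer RGB arrays)
#'   and \code{sharp} (the ground truth, unchanged).
#' @seealso [focusStack()]
#' @export
renderStack <- function(sharp, spec) {
  stopifnot(is(spec, "StackSpec"))
  validObject(spec)
  d <- dim(sharp)
  if (!identical(dim(spec@depthMap), d[1:2]))
    stop("depth map dimensions must match the image")
  focal <- (0:spec@nSteps) * spec@stepSize
  slices <- lapply(focal, function(f) {
    sigma <- spec@blurScale * abs(spec@depthMap - f)
    sigmaQ <- round(sigma * 4) / 4
    out <- array(0, dim = d)
    for (s in sort(unique(as.vector(sigmaQ)))) {
      mask <- sigmaQ == s
      if (s == 0) {
        for (ch in 1:3) {
          plane <- out[, , ch]; src <- sharp[, , ch]
          plane[mask] <- src[mask]; out[, , ch] <- plane
        }
      } else {
        for (ch in 1:3) {
          blurred <- .gblurSafe(sharp[, , ch], s)
          plane <- out[, , ch]
          plane[mask] <- blurred[mask]; out[, , ch] <- plane
        }
      }
    }
    out <- .roundHalfUp(pmin(pmax(out, 0), 255))
    dim(out) <- d
    storage.mode(out) <- "integer"
    out
  })
  list(slices = slices, sharp = sharp)
}

#' Simulate per-eye mean intensities for a group
#'
#' Draws per-eye mean pigment intensities from a normal distribution
#' (clipped to the 0-255 scale), the generating model used for effect-size
#' parameter-recovery checks.
#'
#' @param n number of eyes.
#' @param mu true group mean, pigment units.
#' @param sd between-eye SD, pigment units.
#' @param seed RNG seed.
#' @return Numeric vector of n per-eye means.
#' @export
simulateEyeMeans <- function(n, mu, sd = 10, seed = 1L) {
  withr::with_seed(as.integer(seed),
    pmin(255, pmax(0, stats::rnorm(n, mu, sd))))
}
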