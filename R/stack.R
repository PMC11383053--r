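#' Plan a focus-stack acquisition
#'
#' Rail arithmetic for a z-stack: travelling \code{depthRange} micrometres
#' in \code{stepSize}-micrometre increments takes
#' \code{ceiling(depthRange / stepSize)} steps and captures one image at
#' every position including the start, i.e. \code{nSteps + 1} images.
#' Ceiling division guarantees the plan never under-travels the sample.
#'
#' @param depthRange total depth to cover, micrometres (> 0).
#' @param stepSize step size, micrometres (> 0).
#' @return An [AcquisitionPlan-class].
#' @examples
#' planAcquisition(2750, 50)  # 55 steps, 56 images
#' @export
planAcquisition <- function(depthRange, stepSize) {
  if (depthRange <= 0 || stepSize <= 0)
    stop("depthRange and stepSize must be positive")
  nSteps <- as.integer(ceiling(depthRange / stepSize))
  new("AcquisitionPlan", depthRange = depthRange, stepSize = stepSize,
      nSteps = nSteps, nImages = nSteps + 1L,
      positions = (0:nSteps) * stepSize)
}

.grayMatrix <- function(image) {
  if (length(dim(image)) == 3L)
    0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  else image * 1.0
}

.boxKernel <- function(window) {
  matrix(1 / (window * window), nrow = window, ncol = window)
}

#' Per-pixel sharpness map
#'
#' Local focus measure used to decide, pixel by pixel, which slice of a
#' z-stack is sharpest: the variance of the Laplacian of the grayscale
#' image within a window x window neighbourhood. Perfectly flat regions
#' score exactly zero; edges and texture score high, and defocus blur
#' lowers the score monotonically.
#'
#' @param image RGB array or grayscale matrix.
#' @param window odd neighbourhood size, >= 3.
#' @return Non-negative numeric matrix of per-pixel sharpness values.
#' @export
sharpnessMap <- function(image, window = 9L) {
  if (window %% 2 == 0 || window < 3)
    stop("window must be odd and >= 3")
  gray <- .grayMatrix(image)
  if (window > min(dim(gray)))
    stop("window larger than image")
  lap <- EBImage::filter2(gray,
    matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), nrow = 3),
    boundary = "replicate")
  box <- .boxKernel(window)
  mu <- EBImage::filter2(lap, box, boundary = "replicate")
  mu2 <- EBImage::filter2(lap^2, box, boundary = "replicate")
  pmax(mu2 - mu^2, 0)
}

#' Composite the sharpest regions of a z-stack
#'
#' Generic focus stacking: each slice's sharpness map ([sharpnessMap()])
#' is Gaussian-smoothed with the given radius (which regularises the
#' per-pixel slice choice into coherent regions), and every output pixel is
#' copied from the slice with the maximal smoothed sharpness there. Ties
#' are broken toward the earlier (shallower) slice, so the operation is
#' deterministic and idempotent; a single-slice stack is returned
#' unchanged.
#'
#' @param slices list of >= 1 RGB arrays of identical dimension.
#' @param window odd sharpness window, see [sharpnessMap()].
#' @param smoothing Gaussian smoothing radius for the decision maps,
#'   pixels (0 disables smoothing).
#' @return Integer RGB array, the all-in-focus composite.
#' @seealso [renderStack()], [imageRmse()]
#' @export
focusStack <- function(slices, window = 9L, smoothing = 4) {
  if (!length(slices)) stop("empty slice list")
  d <- dim(slices[[1]])
  for (s in slices)
    if (!identical(dim(s), d)) stop("slice dimension mismatch")
  if (length(slices) == 1L) return(slices[[1]])
  best <- matrix(-Inf, nrow = d[1], ncol = d[2])
  pick <- matrix(1L, nrow = d[1], ncol = d[2])
  for (i in seq_along(slices)) {
    sm <- sharpnessMap(slices[[i]], window)
    if (smoothing > 0) sm <- .gblurSafe(sm, smoothing)
    better <- sm > best          # strict: ties keep the earlier slice
    best[better] <- sm[better]
    pick[better] <- i
  }
  out <- array(0L, dim = d)
  for (i in unique(as.vector(pick))) {
    mask <- pick == i
    for (ch in 1:3) {
      plane <- out[, , ch]; src <- slices[[i]][, , ch]
      plane[mask] <- src[mask]; out[, , ch] <- plane
    }
  }
  storage.mode(out) <- "integer"
  out
}

#' Root-mean-square error between two images
#'
#' @param a,b arrays of identical dimension.
#' @return Scalar RMSE over all channels.
#' @export
imageRmse <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sqrt(mean((as.numeric(a) - as.numeric(b))^2))
}
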