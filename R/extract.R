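.roundHalfUp <- function(x) floor(x + 0.5)

.checkChannels <- function(...) {
  for (ch in list(...)) {
    if (any(ch < 0 | ch > 255 | is.na(ch)))
      stop("channel values must lie in [0, 255]")
  }
}

#' Weighted 8-bit grayscale conversion
#'
#' The standard luminance-weighted RGB-to-grayscale conversion (ITU-R 601
#' weights 0.299, 0.587, 0.114, as used by ImageJ's "weighted" conversion),
#' rounded half-up to an integer and clipped to [0, 255].
#'
#' @param r,g,b channel values in [0, 255]; vectors recycle as usual.
#' @return Integer grayscale value(s) in [0, 255].
#' @examples
#' weightedGray(255, 255, 255)  # 255
#' weightedGray(255, 0, 0)      # 0.299*255 = 76.245 -> 76
#' @seealso [pigmentValue()]
#' @export
weightedGray <- function(r, g, b) {
  .checkChannels(r, g, b)
  v <- .roundHalfUp(0.299 * r + 0.587 * g + 0.114 * b)
  as.integer(pmin(255, pmax(0, v)))
}

#' Pigment value of an RGB pixel
#'
#' The workflow's readout: colors are inverted first (so darker, more
#' pigmented eyes score higher) and then converted to weighted 8-bit
#' grayscale, giving a single value per pixel between 0 (white) and 255
#' (black) that correlates with eye pigmentation. Equivalent to
#' \code{255 - weightedGray(r, g, b)} up to one unit of rounding.
#'
#' @inheritParams weightedGray
#' @return Integer pigment value(s) in [0, 255].
#' @examples
#' pigmentValue(255, 255, 255)  # pure white -> 0
#' pigmentValue(0, 0, 0)        # pure black -> 255
#' pigmentValue(255, 0, 0)      # pure red -> 179
#' @export
pigmentValue <- function(r, g, b) {
  weightedGray(255 - r, 255 - g, 255 - b)
}

#' Read an 8-bit RGB image
#'
#' Reads TIFF, PNG or JPEG into the package's image representation: an
#' integer array of dimension (height, width, 3) with values in [0, 255].
#' An alpha channel is dropped with a warning; 16-bit images are rejected
#' (the workflow is 8-bit end to end); single-channel images are rejected.
#'
#' @param path image file path.
#' @return Integer array (height x width x 3), with the source path in the
#'   \code{"provenance"} attribute.
#' @export
readRgbImage <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = {
      x <- tiff::readTIFF(path, info = TRUE)
      bps <- attr(x, "bits.per.sample")
      if (!is.null(bps) && bps > 8)
        stop("16-bit images are not supported: ", path)
      round(x * 255)
    },
    png = {
      info <- attr(png::readPNG(path, info = TRUE), "info")
      if (!is.null(info$bit.depth) && info$bit.depth > 8)
        stop("16-bit images are not supported: ", path)
      round(png::readPNG(path) * 255)
    },
    jpg = , jpeg = round(jpeg::readJPEG(path) * 255),
    stop("unsupported image format '", ext, "': ", path))
  if (length(dim(img)) != 3L)
    stop("image is not RGB (single channel): ", path)
  if (dim(img)[3] == 4L) {
    warning("dropping alpha channel: ", path)
    img <- img[, , 1:3, drop = FALSE]
  }
  if (dim(img)[3] != 3L)
    stop("image is not 3-channel RGB: ", path)
  storage.mode(img) <- "integer"
  attr(img, "provenance") <- path
  img
}

#' Write an 8-bit RGB image
#'
#' @param image integer array (height x width x 3), values in [0, 255].
#' @param path output path; format chosen by extension (.png or .tif/.tiff).
#' @export
writeRgbImage <- function(image, path) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  x <- image / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = , tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop("unsupported output format '", ext, "'"))
  invisible(path)
}

#' Extract per-pixel pigment values for every ROI
#'
#' The in-package equivalent of the ImageJ extraction macro: for each ROI in
#' set order, every contained pixel (row-major scan within the bounding
#' box) contributes one row with the ROI's name and the pixel's inverted
#' weighted-grayscale pigment value. The source image is never modified. A
#' ROI that lies entirely outside the image contributes zero rows, with a
#' warning.
#'
#' @param image integer RGB array from [readRgbImage()] or [renderPlate()].
#' @param rois a non-empty [RoiSet-class].
#' @return The long-format pixel table: \code{data.frame} with columns
#'   \code{ROI} (character) and \code{pixel} (integer, 0-255), ordered by
#'   ROI set order then scan order.
#' @seealso [writePixelCsv()], [summarizeEyes()]
#' @export
extractPixels <- function(image, rois) {
  stopifnot(is(rois, "RoiSet"))
  if (length(rois) == 0L) stop("empty RoiSet: nothing to extract")
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("image must be a height x width x 3 RGB array")
  h <- d[1]; w <- d[2]
  parts <- vector("list", length(rois))
  for (i in seq_along(rois@name)) {
    px <- containedPixels(rois[i], w, h)
    if (nrow(px) == 0L) {
      warning("ROI '", rois@name[i], "' contains no image pixels")
      parts[[i]] <- data.frame(ROI = character(0), pixel = integer(0))
      next
    }
    ri <- cbind(px$y + 1L, px$x + 1L)
    vals <- pigmentValue(image[cbind(ri, 1L)],
                         image[cbind(ri, 2L)],
                         image[cbind(ri, 3L)])
    parts[[i]] <- data.frame(ROI = rep(rois@name[i], nrow(px)),
                             pixel = vals, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Write a pixel table to CSV
#'
#' Writes the long-format pixel table with a leading 1-based index column
#' (empty header name), imitating the ImageJ Results-table export that the
#' extraction macro produces: columns \code{(index, ROI, pixel)}, comma
#' separated, UTF-8, Unix newlines.
#'
#' @param table pixel table from [extractPixels()].
#' @param path output CSV path.
#' @export
writePixelCsv <- function(table, path) {
  stopifnot(all(c("ROI", "pixel") %in% names(table)))
  con <- file(path, "wb")
  on.exit(close(con))
  lines <- c(",ROI,pixel",
             if (nrow(table))
               paste(seq_len(nrow(table)), table$ROI, table$pixel, sep = ","))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read and concatenate pixel CSVs, parsing names into factors
#'
#' Reads one or more pixel CSVs (as written by [writePixelCsv()] or the
#' ImageJ macro), concatenates them preserving file order then row order,
#' and splits each delimited ROI name into factor columns so any pixel can
#' be grouped by sex, genotype, replicate, user, etc.
#'
#' @param paths character vector of CSV paths (identical column layout).
#' @param schema field names for [parseRoiNames()]; \code{NULL} skips
#'   factor parsing.
#' @param delimiter name delimiter.
#' @return \code{data.frame} with columns \code{ROI}, \code{pixel}, plus
#'   one factor column per schema field and \code{extras}.
#' @export
readPixelCsv <- function(paths,
                         schema = c("sex", "genotype", "replicate", "user"),
                         delimiter = ":") {
  stopifnot(length(paths) >= 1L)
  header <- NULL
  parts <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("pixel CSV not found: ", p)
    hdr <- readLines(p, n = 1L)
    if (is.null(header)) header <<- hdr
    else if (!identical(hdr, header))
      stop("inconsistent CSV headers: '", p, "' has '", hdr, "'")
    df <- utils::read.csv(p, stringsAsFactors = FALSE)
    if (!all(c("ROI", "pixel") %in% names(df)))
      stop("missing ROI/pixel columns in ", p)
    bad <- which(is.na(df$pixel) | df$pixel < 0 | df$pixel > 255 |
                   df$pixel != floor(df$pixel))
    if (length(bad))
      stop(sprintf("malformed pixel value in %s, line %d", p, bad[1] + 1L))
    df[c("ROI", "pixel")]
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out$pixel <- as.integer(out$pixel)
  if (!is.null(schema) && nrow(out)) {
    uniq <- unique(out$ROI)
    keys <- parseRoiNames(uniq, schema = schema, delimiter = delimiter)
    idx <- match(out$ROI, uniq)
    for (col in names(keys)) {
      vals <- keys[[col]][idx]
      out[[col]] <- if (col == "extras") vals else factor(vals)
    }
  }
  out
}
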