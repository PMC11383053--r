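#' Parse a colon-delimited ROI name into experimental factors
#'
#' ROI names follow a standardized delimited convention encoding the
#' experimental factors for every pixel inside the ROI, by default
#' \code{sex:genotype:replicate:user}. Tokens are assigned positionally per
#' \code{schema}; surplus tokens are kept (in order) as \code{extras};
#' missing trailing tokens become \code{NA}, never silently dropped.
#'
#' @param name a single ROI name (non-empty).
#' @param schema character vector of field names, in order.
#' @param delimiter single delimiter character (default \code{":"}).
#' @return A named list with one element per schema field plus
#'   \code{extras}, a character vector of surplus tokens.
#' @examples
#' parseRoiName("F:wm4:1:HP")
#' parseRoiName("F:wm4:1:HP:plate2")$extras
#' @seealso [formatRoiName()], [parseRoiNames()]
#' @export
parseRoiName <- function(name,
                         schema = c("sex", "genotype", "replicate", "user"),
                         delimiter = ":") {
  if (length(name) != 1L || is.na(name) || !nzchar(name))
    stop("ROI name must be a single non-empty string")
  tokens <- strsplit(name, delimiter, fixed = TRUE)[[1]]
  nf <- length(schema)
  fields <- as.list(c(tokens, rep(NA_character_, max(0L, nf - length(tokens))))[
    seq_len(nf)])
  names(fields) <- schema
  fields$extras <- if (length(tokens) > nf) tokens[-seq_len(nf)] else character(0)
  fields
}

#' Format experimental factors back into an ROI name
#'
#' Inverse of [parseRoiName()]: for delimiter-free fields,
#' \code{formatRoiName(parseRoiName(x))} is the identity. Trailing
#' \code{NA} fields (from short names) are dropped; an interior \code{NA}
#' or a field containing the delimiter is an error.
#'
#' @param key a named list as returned by [parseRoiName()].
#' @param delimiter single delimiter character.
#' @return The delimited name string.
#' @export
formatRoiName <- function(key, delimiter = ":") {
  extras <- key$extras %||% character(0)
  fields <- unlist(key[setdiff(names(key), "extras")], use.names = FALSE)
  tokens <- c(fields, extras)
  # drop trailing NAs (short names round-trip); interior NA is ambiguous
  while (length(tokens) && is.na(tokens[length(tokens)]))
    tokens <- tokens[-length(tokens)]
  if (anyNA(tokens))
    stop("cannot format a key with missing interior fields")
  if (any(grepl(delimiter, tokens, fixed = TRUE)))
    stop("fields must not contain the delimiter '", delimiter, "'")
  paste(tokens, collapse = delimiter)
}

#' Parse many ROI names into a factor data frame
#'
#' Vectorized companion to [parseRoiName()]: one row per name, one column
#' per schema field (surplus tokens re-joined into an \code{extras}
#' column).
#'
#' @param names character vector of ROI names.
#' @inheritParams parseRoiName
#' @return \code{data.frame} with columns \code{schema...} and
#'   \code{extras} (empty string when none).
#' @export
parseRoiNames <- function(names,
                          schema = c("sex", "genotype", "replicate", "user"),
                          delimiter = ":") {
  keys <- lapply(names, parseRoiName, schema = schema, delimiter = delimiter)
  out <- as.data.frame(
    do.call(rbind, lapply(keys, function(k)
      unlist(k[schema], use.names = FALSE))),
    stringsAsFactors = FALSE)
  names(out) <- schema
  out$extras <- vapply(keys, function(k)
    paste(k$extras, collapse = delimiter), character(1))
  out
}

.roiOne <- function(roi, i = 1L) {
  if (is(roi, "RoiSet")) {
    stopifnot(length(roi) >= i)
    list(x0 = roi@x0[i], y0 = roi@y0[i],
         width = roi@width[i], height = roi@height[i])
  } else {
    stopifnot(all(c("x0", "y0", "width", "height") %in% names(roi)))
    lapply(roi[c("x0", "y0", "width", "height")], as.numeric)
  }
}

#' Pixels contained in an elliptical ROI
#'
#' Enumerates the image pixels inside the ellipse inscribed in the ROI's
#' bounding box, in the exact scan order of the extraction loop: row-major
#' within the bounding box (y outer, x inner). A pixel (x, y) is contained
#' iff its center satisfies
#' \deqn{((x + 0.5 - c_x)/a)^2 + ((y + 0.5 - c_y)/b)^2 \le 1}
#' with \eqn{c_x = x_0 + w/2}, \eqn{c_y = y_0 + h/2}, \eqn{a = w/2},
#' \eqn{b = h/2}. Coordinates outside the image are excluded; a fully
#' off-image ROI yields zero rows.
#'
#' @param roi a single-ROI [RoiSet-class] (or a list with \code{x0, y0,
#'   width, height}).
#' @param imageWidth,imageHeight image dimensions in pixels (positive).
#' @return \code{data.frame} with integer columns \code{x, y} (0-based), in
#'   scan order.
#' @examples
#' containedPixels(list(x0 = 0, y0 = 0, width = 1, height = 1), 10, 10)
#' @export
containedPixels <- function(roi, imageWidth, imageHeight) {
  if (imageWidth < 1 || imageHeight < 1)
    stop("image dimensions must be positive")
  r <- .roiOne(roi)
  xs <- seq(max(0, r$x0), min(imageWidth - 1, r$x0 + r$width - 1))
  ys <- seq(max(0, r$y0), min(imageHeight - 1, r$y0 + r$height - 1))
  if (!length(xs) || !length(ys) || xs[1] > xs[length(xs)] ||
      ys[1] > ys[length(ys)])
    return(data.frame(x = integer(0), y = integer(0)))
  cx <- r$x0 + r$width / 2
  cy <- r$y0 + r$height / 2
  a <- r$width / 2
  b <- r$height / 2
  grid <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)  # x fastest
  inside <- ((grid$x + 0.5 - cx) / a)^2 + ((grid$y + 0.5 - cy) / b)^2 <= 1
  out <- grid[inside, , drop = FALSE]
  rownames(out) <- NULL
  out$x <- as.integer(out$x)
  out$y <- as.integer(out$y)
  out
}

#' Read elliptical ROIs from a file
#'
#' Reads either the ImageJ binary format (a single \code{.roi} file or a
#' \code{RoiSet.zip} archive of them, as produced by the ROI Manager; only
#' the oval subtype is accepted) or a plain-text dialect (CSV with header
#' \code{name,x0,y0,width,height}). ROIs are returned in file order, which
#' downstream extraction preserves.
#'
#' @param path path to a \code{.roi}, \code{.zip} or text ROI file.
#' @param dialect \code{"imagej"} or \code{"text"}; default guesses from
#'   the file extension.
#' @return A [RoiSet-class].
#' @seealso [writeRois()]
#' @export
readRois <- function(path, dialect = c("auto", "imagej", "text")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("ROI file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(roi|zip)$", path, ignore.case = TRUE))
      "imagej" else "text"
  }
  if (dialect == "text") return(.readRoisText(path))
  .readRoisImageJ(path)
}

#' Write elliptical ROIs to a file
#'
#' Inverse of [readRois()]: the written file reads back to an identical
#' set. The \code{imagej} dialect writes standard binary \code{.roi}
#' entries (oval type) -- a single \code{.roi} file for a one-ROI set with a
#' \code{.roi} path, otherwise a stored \code{.zip} archive openable by the
#' ImageJ ROI Manager.
#'
#' @param rois a [RoiSet-class].
#' @param path output path (\code{.roi}/\code{.zip} for imagej dialect).
#' @param dialect \code{"imagej"} or \code{"text"}; default guesses from
#'   the extension.
#' @export
writeRois <- function(rois, path, dialect = c("auto", "imagej", "text")) {
  stopifnot(is(rois, "RoiSet"))
  validObject(rois)
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(roi|zip)$", path, ignore.case = TRUE))
      "imagej" else "text"
  }
  if (dialect == "text") .writeRoisText(rois, path) else
    .writeRoisImageJ(rois, path)
  invisible(path)
}

.readRoisText <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", rep("integer", 4)))
  expected <- c("name", "x0", "y0", "width", "height")
  if (!identical(names(df), expected))
    stop("text ROI file must have header '", paste(expected, collapse = ","),
         "': ", path)
  RoiSet(df$name, df$x0, df$y0, df$width, df$height, source = path)
}

.writeRoisText <- function(rois, path) {
  if (any(grepl("[,\n]", rois@name)))
    stop("ROI names must not contain ',' or newlines in the text dialect")
  utils::write.csv(roiBounds(rois), path, row.names = FALSE, quote = FALSE)
}
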