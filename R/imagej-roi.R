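# ImageJ binary .roi codec (oval subtype) and a minimal stored-ZIP writer.
#
# The .roi layout: a 64-byte big-endian header ("Iout" magic, version,
# type byte at offset 6, top/left/bottom/right as signed shorts at 8..15,
# header2 offset at 60), a 64-byte second header whose offsets 16/20 hold
# the name offset and length, and the name as 16-bit big-endian chars.
# Only what oval ROIs need is written; unused fields stay zero.

.IJ_TYPE_OVAL <- 2L
.IJ_TYPES <- c("polygon", "rectangle", "oval", "line", "freeline",
               "polyline", "noRoi", "freehand", "traced", "angle", "point")

.encodeRoi <- function(name, x0, y0, width, height) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(charToRaw("Iout"), con)
  writeBin(228L, con, size = 2, endian = "big")            # version
  writeBin(as.raw(c(.IJ_TYPE_OVAL, 0L)), con)              # type, pad
  writeBin(as.integer(c(y0, x0, y0 + height, x0 + width)), # top,left,bottom,right
           con, size = 2, endian = "big")
  writeBin(raw(60 - 16), con)                              # zero to offset 60
  writeBin(64L, con, size = 4, endian = "big")             # header2 offset
  h2 <- raw(64)
  nameOffset <- 64L + 64L
  nameChars <- utf8ToInt(name)
  h2[17:20] <- .intToRaw4(nameOffset)
  h2[21:24] <- .intToRaw4(length(nameChars))
  writeBin(h2, con)
  if (length(nameChars))
    writeBin(as.integer(nameChars), con, size = 2, endian = "big")
  rawConnectionValue(con)
}

.intToRaw4 <- function(x) {
  rev(as.raw(c(x %% 256, (x %/% 256) %% 256,
               (x %/% 65536) %% 256, (x %/% 16777216) %% 256)))
}

.rawToInt <- function(bytes) {
  # big-endian unsigned
  sum(as.integer(bytes) * 256^((length(bytes) - 1):0))
}

.rawToShortSigned <- function(bytes) {
  v <- .rawToInt(bytes)
  if (v >= 32768) v - 65536L else v
}

.decodeRoi <- function(bytes, fallbackName) {
  if (length(bytes) < 64 || rawToChar(bytes[1:4]) != "Iout")
    stop("not an ImageJ ROI file (bad magic): ", fallbackName)
  type <- as.integer(bytes[7])
  if (type != .IJ_TYPE_OVAL) {
    label <- if (type + 1L <= length(.IJ_TYPES)) .IJ_TYPES[type + 1L]
             else as.character(type)
    stop(sprintf(
      "unsupported ROI type '%s' in entry '%s': only oval/elliptical ROIs are supported",
      label, fallbackName))
  }
  top    <- .rawToShortSigned(bytes[9:10])
  left   <- .rawToShortSigned(bytes[11:12])
  bottom <- .rawToShortSigned(bytes[13:14])
  right  <- .rawToShortSigned(bytes[15:16])
  name <- fallbackName
  h2off <- .rawToInt(bytes[61:64])
  if (h2off > 0 && h2off + 24 <= length(bytes)) {
    nameOffset <- .rawToInt(bytes[(h2off + 17):(h2off + 20)])
    nameLength <- .rawToInt(bytes[(h2off + 21):(h2off + 24)])
    if (nameLength > 0 && nameOffset + 2 * nameLength <= length(bytes)) {
      chars <- bytes[(nameOffset + 1):(nameOffset + 2 * nameLength)]
      codes <- vapply(seq_len(nameLength), function(i)
        .rawToInt(chars[(2 * i - 1):(2 * i)]), numeric(1))
      name <- intToUtf8(codes)
    }
  }
  list(name = name, x0 = left, y0 = top,
       width = right - left, height = bottom - top)
}

.readRoisImageJ <- function(path) {
  if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    entries <- utils::unzip(path, list = TRUE)$Name
    entries <- entries[grepl("\\.roi$", entries, ignore.case = TRUE)]
    if (!length(entries)) stop("no .roi entries in archive: ", path)
    exdir <- tempfile("roiset")
    dir.create(exdir)
    on.exit(unlink(exdir, recursive = TRUE))
    utils::unzip(path, files = entries, exdir = exdir)
    rois <- lapply(entries, function(e) {
      f <- file.path(exdir, e)
      .decodeRoi(readBin(f, "raw", file.size(f)),
                 sub("\\.roi$", "", basename(e), ignore.case = TRUE))
    })
  } else {
    rois <- list(.decodeRoi(readBin(path, "raw", file.size(path)),
                            sub("\\.roi$", "", basename(path),
                                ignore.case = TRUE)))
  }
  RoiSet(vapply(rois, `[[`, character(1), "name"),
         vapply(rois, `[[`, numeric(1), "x0"),
         vapply(rois, `[[`, numeric(1), "y0"),
         vapply(rois, `[[`, numeric(1), "width"),
         vapply(rois, `[[`, numeric(1), "height"),
         source = path)
}

.writeRoisImageJ <- function(rois, path) {
  blobs <- lapply(seq_along(rois@name), function(i)
    .encodeRoi(rois@name[i], rois@x0[i], rois@y0[i],
               rois@width[i], rois@height[i]))
  if (grepl("\\.roi$", path, ignore.case = TRUE)) {
    if (length(blobs) != 1L)
      stop("a .roi path holds exactly one ROI; use .zip for a set")
    writeBin(blobs[[1]], path)
  } else {
    entryNames <- paste0(.safeEntryName(rois@name), ".roi")
    .writeStoredZip(path, entryNames, blobs)
  }
}

# zip entry names must be unique and filesystem-safe; the authoritative ROI
# name lives inside each .roi blob, so mangling here is harmless.
.safeEntryName <- function(names) {
  safe <- gsub("[^A-Za-z0-9._-]", "_", names)
  make.unique(safe, sep = "-")
}

# --- minimal stored (method 0) ZIP writer ---------------------------------

.crcTable <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      poly <- -306674912L  # 0xEDB88320 as a signed 32-bit pattern
      t <- integer(256)
      for (i in 0:255) {
        crc <- i
        for (k in 1:8) {
          crc <- if (bitwAnd(crc, 1L) != 0L)
            bitwXor(bitwShiftR(crc, 1L), poly) else bitwShiftR(crc, 1L)
        }
        t[i + 1L] <- crc
      }
      tab <<- t
    }
    tab
  }
})

.crc32 <- function(bytes) {
  tab <- .crcTable()
  crc <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

.le <- function(x, size) {
  # little-endian raw encoding of a non-negative (or signed 32-bit) value
  if (size == 4 && is.integer(x)) {
    v <- as.double(x)
    if (v < 0) v <- v + 4294967296
  } else v <- as.double(x)
  as.raw(vapply(0:(size - 1), function(i) (v %/% 256^i) %% 256, numeric(1)))
}

.writeStoredZip <- function(path, entryNames, blobs) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(blobs))
  pos <- 0L
  crcs <- integer(length(blobs))
  for (i in seq_along(blobs)) {
    data <- blobs[[i]]
    fn <- charToRaw(entryNames[i])
    crcs[i] <- .crc32(data)
    offsets[i] <- pos
    header <- c(
      as.raw(c(0x50, 0x4b, 0x03, 0x04)), .le(20, 2), .le(0, 2), .le(0, 2),
      .le(0, 2), .le(0x21, 2),            # dummy DOS time/date
      .le(crcs[i], 4), .le(length(data), 4), .le(length(data), 4),
      .le(length(fn), 2), .le(0, 2))
    writeBin(c(header, fn, data), con)
    pos <- pos + length(header) + length(fn) + length(data)
  }
  cdStart <- pos
  for (i in seq_along(blobs)) {
    fn <- charToRaw(entryNames[i])
    cd <- c(
      as.raw(c(0x50, 0x4b, 0x01, 0x02)), .le(20, 2), .le(20, 2), .le(0, 2),
      .le(0, 2), .le(0, 2), .le(0x21, 2),
      .le(crcs[i], 4), .le(length(blobs[[i]]), 4), .le(length(blobs[[i]]), 4),
      .le(length(fn), 2), .le(0, 2), .le(0, 2), .le(0, 2), .le(0, 2),
      .le(0, 4), .le(offsets[i], 4))
    writeBin(c(cd, fn), con)
    pos <- pos + length(cd) + length(fn)
  }
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), .le(0, 2), .le(0, 2),
            .le(length(blobs), 2), .le(length(blobs), 2),
            .le(pos - cdStart, 4), .le(cdStart, 4), .le(0, 2))
  writeBin(eocd, con)
}
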