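test_that("name parsing assigns fields positionally with extras and NAs", {
  k <- parseRoiName("F:wm4:1:HP")
  expect_identical(k[c("sex", "genotype", "replicate", "user")],
                   list(sex = "F", genotype = "wm4", replicate = "1",
                        user = "HP"))
  expect_identical(k$extras, character(0))
  expect_identical(parseRoiName("F:wm4:1:HP:plate2")$extras, "plate2")
  short <- parseRoiName("F:wm4")
  expect_true(is.na(short$replicate) && is.na(short$user))
  expect_error(parseRoiName(""), "non-empty")
  # custom schema
  k2 <- parseRoiName("a:b", schema = c("one", "two"))
  expect_identical(k2$two, "b")
})

test_that("parse/format round-trips 1000 random names", {
  withr::with_seed(42, {
    for (i in 1:1000) {
      nm <- randomName()
      expect_identical(formatRoiName(parseRoiName(nm)), nm)
    }
  })
  # short names round-trip through the trailing-NA rule
  expect_identical(formatRoiName(parseRoiName("F:wt")), "F:wt")
  expect_error(formatRoiName(list(sex = "a:b", genotype = "c",
                                  replicate = "1", user = "u")),
               "delimiter")
})

test_that("containedPixels matches the pixel-center ellipse rule", {
  expect_identical(
    containedPixels(list(x0 = 0, y0 = 0, width = 1, height = 1), 10, 10),
    data.frame(x = 0L, y = 0L))
  # brute-force oracle on small fixed cases and on random ROIs
  for (roi in list(c(0, 0, 4, 4), c(3, 7, 9, 5), c(10, 2, 7, 13))) {
    got <- containedPixels(list(x0 = roi[1], y0 = roi[2], width = roi[3],
                                height = roi[4]), 50, 50)
    want <- bruteForcePixels(roi[1], roi[2], roi[3], roi[4], 50, 50)
    expect_equal(got$x, want$x)
    expect_equal(got$y, want$y)
  }
  rs <- randomRoiSet(20, seed = 7)
  for (i in seq_len(20)) {
    got <- containedPixels(rs[i], 200, 150)
    b <- roiBounds(rs[i])
    want <- bruteForcePixels(b$x0, b$y0, b$width, b$height, 200, 150)
    expect_identical(got$x, as.integer(want$x))
    expect_identical(got$y, as.integer(want$y))
  }
})

test_that("containment clips to image bounds and may be empty", {
  px <- containedPixels(list(x0 = -2, y0 = -2, width = 4, height = 4),
                        10, 10)
  expect_true(all(px$x >= 0) && all(px$y >= 0))
  off <- containedPixels(list(x0 = 100, y0 = 100, width = 5, height = 5),
                         10, 10)
  expect_identical(nrow(off), 0L)
  expect_error(containedPixels(list(x0 = 0, y0 = 0, width = 2, height = 2),
                               0, 10), "positive")
})

test_that("containment is translation-equivariant and circle-area bounded", {
  base <- containedPixels(list(x0 = 5, y0 = 6, width = 9, height = 7),
                          100, 100)
  shifted <- containedPixels(list(x0 = 5 + 13, y0 = 6 + 21, width = 9,
                                  height = 7), 100, 100)
  expect_identical(shifted$x, base$x + 13L)
  expect_identical(shifted$y, base$y + 21L)
  for (r in 2:12) {
    n <- nrow(containedPixels(list(x0 = 0, y0 = 0, width = 2 * r,
                                   height = 2 * r), 100, 100))
    expect_gte(n, pi * (r - 1)^2)
    expect_lte(n, pi * (r + 1)^2)
  }
})

test_that("scan order is row-major within the bounding box", {
  px <- containedPixels(list(x0 = 2, y0 = 3, width = 8, height = 6), 50, 50)
  # y must be non-decreasing; x strictly increasing within each y
  expect_true(all(diff(px$y) >= 0))
  for (yy in unique(px$y))
    expect_true(all(diff(px$x[px$y == yy]) > 0))
})

test_that("text dialect round-trips, including the empty set", {
  rs <- randomRoiSet(15, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  writeRois(rs, f, dialect = "text")
  back <- readRois(f, dialect = "text")
  expect_identical(roiBounds(back), roiBounds(rs))
  empty <- RoiSet()
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeRois(empty, f2, dialect = "text")
  expect_identical(readLines(f2), "name,x0,y0,width,height")
  expect_identical(length(readRois(f2, dialect = "text")), 0L)
})

test_that("ImageJ binary dialect round-trips through .roi and .zip", {
  one <- RoiSet("F:wt:1:A", 0, 0, 10, 20)
  f <- withr::local_tempfile(fileext = ".roi")
  writeRois(one, f)
  back <- readRois(f)
  expect_identical(roiBounds(back), roiBounds(one))

  # order preservation in a two-ROI archive
  two <- RoiSet(c("F:wt:1:A", "M:wt:1:A"), c(5, 40), c(5, 8),
                c(20, 22), c(15, 17))
  fz <- withr::local_tempfile(fileext = ".zip")
  writeRois(two, fz)
  expect_identical(roiNames(readRois(fz)), c("F:wt:1:A", "M:wt:1:A"))

  # randomized 60-ROI sets round-trip exactly, incl. negative corners
  for (seed in 1:3) {
    rs <- randomRoiSet(60, seed = seed)
    rs@x0[1] <- -3L; rs@y0[2] <- -5L
    fz2 <- withr::local_tempfile(fileext = ".zip")
    writeRois(rs, fz2)
    expect_identical(roiBounds(readRois(fz2)), roiBounds(rs))
  }
})

test_that("non-oval ROI entries are rejected by name", {
  one <- RoiSet("F:wt:1:A", 0, 0, 10, 20)
  f <- withr::local_tempfile(fileext = ".roi")
  writeRois(one, f)
  bytes <- readBin(f, "raw", file.size(f))
  bytes[7] <- as.raw(1)  # rectangle type
  f2 <- withr::local_tempfile(fileext = ".roi")
  writeBin(bytes, f2)
  expect_error(readRois(f2), "unsupported ROI type 'rectangle'")
})

test_that("RoiSet enforces unique names and positive extents", {
  expect_error(RoiSet(c("a", "a"), c(0, 0), c(0, 0), c(5, 5), c(5, 5)),
               "duplicate")
  expect_error(RoiSet("a", 0, 0, 0, 5), "width and height")
  rs <- randomRoiSet(5, seed = 1)
  expect_identical(roiNames(rs["F:g3:A" == roiNames(rs)]), character(0))
  expect_error(rs["nope"], "unknown ROI name")
})
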