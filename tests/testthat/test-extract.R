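test_that("weighted grayscale and pigment endpoints behave as defined", {
  expect_identical(weightedGray(255, 255, 255), 255L)
  expect_identical(weightedGray(0, 0, 0), 0L)
  # 0.299*255 = 76.245 rounds half-up to 76
  expect_identical(weightedGray(255, 0, 0), 76L)
  expect_identical(pigmentValue(255, 255, 255), 0L)   # white
  expect_identical(pigmentValue(0, 0, 0), 255L)       # black
  # pure red inverts to cyan: 0.587*255 + 0.114*255 = 178.755 -> 179
  expect_identical(pigmentValue(255, 0, 0), 179L)
  expect_error(weightedGray(256, 0, 0), "\\[0, 255\\]")
  expect_error(pigmentValue(-1, 0, 0), "\\[0, 255\\]")
})

test_that("pigment value is the inverted gray up to rounding, monotone", {
  withr::with_seed(9, {
    r <- sample(0:255, 500, TRUE)
    g <- sample(0:255, 500, TRUE)
    b <- sample(0:255, 500, TRUE)
  })
  expect_true(all(abs(pigmentValue(r, g, b) -
                        (255L - weightedGray(r, g, b))) <= 1L))
  # monotone non-increasing in each channel
  expect_true(all(pigmentValue(pmin(r + 10, 255), g, b) <=
                    pigmentValue(r, g, b)))
  expect_true(all(pigmentValue(r, pmin(g + 10, 255), b) <=
                    pigmentValue(r, g, b)))
  expect_true(all(pigmentValue(r, g, pmin(b + 10, 255)) <=
                    pigmentValue(r, g, b)))
})

test_that("extractPixels reproduces the macro's rows, order and counts", {
  img <- uniformImage(30, 40, c(255, 255, 255))
  rs <- RoiSet(c("F:a:1:u", "F:b:1:u"), c(2, 20), c(2, 5), c(8, 10),
               c(8, 12))
  tab <- extractPixels(img, rs)
  expect_true(all(tab$pixel == 0L))  # white image extracts to 0 everywhere
  # conservation: one row per contained pixel, ROI-major order
  n1 <- nrow(containedPixels(rs[1], 40, 30))
  n2 <- nrow(containedPixels(rs[2], 40, 30))
  expect_identical(nrow(tab), n1 + n2)
  expect_identical(tab$ROI, c(rep("F:a:1:u", n1), rep("F:b:1:u", n2)))

  # one-pixel ROI reads exactly pigmentValue of that pixel
  img[11, 6, ] <- c(10L, 20L, 30L)
  one <- RoiSet("F:c:1:u", 5, 10, 1, 1)
  expect_identical(extractPixels(img, one)$pixel, pigmentValue(10, 20, 30))

  # source image is untouched
  before <- img
  invisible(extractPixels(img, rs))
  expect_identical(img, before)

  expect_error(extractPixels(img, RoiSet()), "empty RoiSet")
  expect_error(extractPixels(img[, , 1], rs), "RGB")
  expect_warning(extractPixels(img, RoiSet("off:x:1:u", 200, 200, 5, 5)),
                 "no image pixels")
})

test_that("pixel CSV round-trips byte-stably with an index column", {
  withr::with_seed(4, {
    tab <- data.frame(
      ROI = sample(c("F:wt:1:A", "M:wm4:2:B"), 1e4, TRUE),
      pixel = sample(0:255, 1e4, TRUE), stringsAsFactors = FALSE)
  })
  f <- withr::local_tempfile(fileext = ".csv")
  writePixelCsv(tab, f)
  expect_identical(readLines(f, n = 1), ",ROI,pixel")
  back <- readPixelCsv(f, schema = NULL)
  expect_identical(back$ROI, tab$ROI)
  expect_identical(back$pixel, as.integer(tab$pixel))
  f2 <- withr::local_tempfile(fileext = ".csv")
  writePixelCsv(back, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))

  # small-table line counts: header + one line per row
  f3 <- withr::local_tempfile(fileext = ".csv")
  writePixelCsv(tab[1:3, ], f3)
  expect_identical(length(readLines(f3)), 4L)
  f4 <- withr::local_tempfile(fileext = ".csv")
  writePixelCsv(tab[0, ], f4)
  expect_identical(length(readLines(f4)), 1L)
})

test_that("readPixelCsv concatenates files and parses factors", {
  t1 <- data.frame(ROI = rep("F:wt:2:B", 5), pixel = 1:5)
  t2 <- data.frame(ROI = rep("M:wm4:1:A", 5), pixel = 6:10)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writePixelCsv(t1, f1); writePixelCsv(t2, f2)
  both <- readPixelCsv(c(f1, f2))
  expect_identical(nrow(both), 10L)
  expect_identical(both$pixel, 1:10)  # file order then row order
  expect_identical(as.character(both$genotype[1]), "wt")
  expect_identical(as.character(both$user[10]), "A")
  # group-by tallies equal per-file tallies
  expect_identical(as.vector(table(both$genotype)[c("wt", "wm4")]),
                   c(5L, 5L))
  # malformed pixel reported with file and line
  writeLines(c(",ROI,pixel", "1,F:wt:1:A,12", "2,F:wt:1:A,999"), f1)
  expect_error(readPixelCsv(f1), "line 3")
})

test_that("image io round-trips 8-bit RGB and rejects what it must", {
  withr::with_seed(2, {
    img <- array(sample(0:255, 20 * 30 * 3, TRUE), dim = c(20, 30, 3))
  })
  storage.mode(img) <- "integer"
  fp <- withr::local_tempfile(fileext = ".png")
  writeRgbImage(img, fp)
  expect_true(all(readRgbImage(fp) == img))
  ft <- withr::local_tempfile(fileext = ".tif")
  writeRgbImage(img, ft)
  back <- readRgbImage(ft)
  expect_true(all(back == img))

  # alpha dropped with a warning
  fa <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(10 * 10 * 4), dim = c(10, 10, 4)), fa)
  expect_warning(rgba <- readRgbImage(fa), "alpha")
  expect_identical(dim(rgba)[3], 3L)

  # 16-bit and single-channel rejected
  f16 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(100), 10), f16, bits.per.sample = 16L)
  expect_error(readRgbImage(f16), "not supported|single channel")
})
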