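test_that("intensityToRgb is an exact inverse of pigmentValue on 0..255", {
  v <- 0:255
  rgb <- intensityToRgb(v)
  expect_identical(as.integer(pigmentValue(rgb[, "r"], rgb[, "g"],
                                           rgb[, "b"])), v)
  expect_identical(as.vector(intensityToRgb(0L)), c(255L, 255L, 255L))
  expect_identical(as.vector(intensityToRgb(255L)), c(0L, 0L, 0L))
  expect_error(intensityToRgb(256), "\\[0, 255\\]")
})

test_that("rendered constant eyes extract back to their targets exactly", {
  pl <- smallPlate(c("yw", "wt1"), nPerGeno = 2, seed = 8)
  s <- summarizeEyes(extractPixels(pl$image, pl$rois))
  k <- parseRoiNames(s$ROI)
  expect_equal(s$mean[k$genotype == "yw"], rep(35, 2))
  expect_equal(s$mean[k$genotype == "wt1"], rep(140, 2))
  expect_equal(max(s$sd), 0)
})

test_that("normal eyes recover mu within 3*sigma/sqrt(n)", {
  pl <- smallPlate("wt2", nPerGeno = 3, seed = 21)
  s <- summarizeEyes(extractPixels(pl$image, pl$rois))
  tol <- 3 * 7 / sqrt(min(s$nPixels))
  expect_true(all(abs(s$mean - 140) < tol))
})

test_that("mixture eyes are bimodal at their component intensities", {
  pl <- smallPlate("strongPEV", nPerGeno = 1, seed = 5)
  tab <- extractPixels(pl$image, pl$rois)
  h <- eyeHistogram(tab, pl$rois@name[1])
  expect_identical(unname(sort(which(h > 0) - 1L)), c(35L, 110L))
  # spatial clustering: both components present in nontrivial proportion
  expect_gt(min(h[h > 0]) / sum(h), 0.1)
})

test_that("gradient eyes span top-to-bottom intensities", {
  pl <- smallPlate("dorsal-eye", nPerGeno = 1, seed = 5)
  tab <- extractPixels(pl$image, pl$rois)
  expect_gt(max(tab$pixel), 140)
  expect_lt(min(tab$pixel), 60)
})

test_that("plate rendering is deterministic and validates its layout", {
  p1 <- smallPlate(c("wm4", "yw"), seed = 33)
  p2 <- smallPlate(c("wm4", "yw"), seed = 33)
  expect_identical(p1$image, p2$image)   # bit-identical given the seed
  expect_identical(roiBounds(p1$rois), roiBounds(p2$rois))
  p3 <- smallPlate(c("wm4", "yw"), seed = 34)
  expect_false(identical(p1$image, p3$image))

  expect_error(renderPlate(plateSpec(1, 1, "nope")), "unknown genotype")
  big <- genotypePresets()
  big$yw@eyeAxes <- c(90, 70)
  expect_error(renderPlate(plateSpec(1, 1, "yw"), genotypes = big),
               "overlapping layout")
})

test_that("genotypes ordered by target mean extract in the same order", {
  genos <- c("yw", "mini-white", "wm4", "wt1")  # increasing target means
  pl <- smallPlate(genos, nPerGeno = 3, seed = 12)
  s <- summarizeEyes(extractPixels(pl$image, pl$rois))
  k <- parseRoiNames(s$ROI)
  groupMeans <- vapply(genos, function(g) mean(s$mean[k$genotype == g]),
                      numeric(1))
  expect_true(all(diff(groupMeans) > 0))
})

test_that("ground-truth ROI names follow the colon convention", {
  pl <- smallPlate("wm4", nPerGeno = 2, seed = 3)
  k <- parseRoiNames(roiNames(pl$rois))
  expect_true(all(k$genotype == "wm4"))
  expect_true(all(k$user == "truth"))
  expect_identical(sort(k$replicate), c("1", "2"))
  expect_identical(pl$metadata$targetMean,
                   rep(0.5 * 50 + 0.5 * 140, 2))
})

test_that("jitterRois degenerates to the truth at zero jitter", {
  truth <- smallPlate("wt1", nPerGeno = 2, seed = 2)$rois
  ops <- jitterRois(truth, jitterParams(centerSd = 0, axisRelSd = 0,
                                        nOperators = 3, seed = 1))
  expect_length(ops, 3)
  for (k in seq_along(ops)) {
    b <- roiBounds(ops[[k]])
    expect_identical(b[c("x0", "y0", "width", "height")],
                     roiBounds(truth)[c("x0", "y0", "width", "height")])
    expect_true(all(parseRoiNames(b$name)$user == sprintf("op%d", k)))
  }
})

test_that("jitter is seeded-deterministic and spread grows with axisRelSd", {
  truth <- smallPlate("dorsal-eye", nPerGeno = 2, seed = 6)
  spreadAt <- function(axisSd) {
    mean(vapply(1:4, function(s) {
      ops <- jitterRois(truth$rois,
                        jitterParams(centerSd = 0, axisRelSd = axisSd,
                                     nOperators = 5, seed = 40 + s))
      perOp <- vapply(ops, function(rs)
        mean(summarizeEyes(extractPixels(truth$image, rs))$mean),
        numeric(1))
      sd(perOp)
    }, numeric(1)))
  }
  expect_gt(spreadAt(0.2), spreadAt(0.02))
  o1 <- jitterRois(truth$rois, jitterParams(seed = 5))
  o2 <- jitterRois(truth$rois, jitterParams(seed = 5))
  expect_identical(lapply(o1, roiBounds), lapply(o2, roiBounds))
})

test_that("renderStack produces nSteps+1 slices and exact in-focus planes", {
  pl <- smallPlate("wm4", nPerGeno = 1, seed = 9)
  sharp <- pl$image
  d <- dim(sharp)
  # flat depth at the plane of slice 2 (focal = 2 * 50)
  depth <- matrix(100, nrow = d[1], ncol = d[2])
  st <- renderStack(sharp, stackSpec(3, 50, depth, blurScale = 0.02))
  expect_length(st$slices, 4)
  expect_identical(st$slices[[3]], sharp)       # focal plane hit exactly
  expect_false(identical(st$slices[[1]], sharp))
  # blurScale 0: every slice equals the sharp image
  st0 <- renderStack(sharp, stackSpec(3, 50, depth, blurScale = 0))
  for (s in st0$slices) expect_identical(s, sharp)
  expect_error(renderStack(sharp, stackSpec(3, 50, matrix(0, 2, 2))),
               "dimensions")
})

test_that("simulateEyeMeans is seeded and clipped to the pigment scale", {
  a <- simulateEyeMeans(30, 60, 10, seed = 3)
  expect_identical(a, simulateEyeMeans(30, 60, 10, seed = 3))
  expect_true(all(a >= 0 & a <= 255))
  expect_lt(abs(mean(a) - 60), 3 * 10 / sqrt(30) + 1)
})
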