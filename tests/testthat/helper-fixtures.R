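# Shared fixtures: all synthetic, generated in code at test time.

# Independent brute-force rasterization oracle: a literal double loop over
# the bounding box applying the pixel-center ellipse inequality. Kept
# deliberately naive and separate from containedPixels().
bruteForcePixels <- function(x0, y0, width, height, imgW, imgH) {
  cx <- x0 + width / 2; cy <- y0 + height / 2
  a <- width / 2; b <- height / 2
  xs <- integer(0); ys <- integer(0)
  for (y in y0:(y0 + height - 1)) {
    for (x in x0:(x0 + width - 1)) {
      if (x < 0 || y < 0 || x >= imgW || y >= imgH) next
      if (((x + 0.5 - cx) / a)^2 + ((y + 0.5 - cy) / b)^2 <= 1) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
  }
  data.frame(x = xs, y = ys)
}

randomRoiSet <- function(n, seed, imgW = 200, imgH = 150) {
  withr::with_seed(seed, {
    RoiSet(
      name = paste(sample(c("F", "M"), n, TRUE),
                   paste0("g", seq_len(n)),
                   sample(1:3, n, TRUE),
                   sample(LETTERS[1:4], n, TRUE), sep = ":"),
      x0 = sample(0:(imgW - 30), n, TRUE),
      y0 = sample(0:(imgH - 30), n, TRUE),
      width = sample(3:25, n, TRUE),
      height = sample(3:25, n, TRUE),
      source = "synthetic")
  })
}

randomName <- function() {
  nfields <- sample(2:6, 1)
  paste(replicate(nfields, paste(sample(c(letters, LETTERS, 0:9),
                                        sample(1:6, 1), TRUE),
                                 collapse = "")),
        collapse = ":")
}

# Small, fast genotype presets for rendering tests: same distributions as
# the defaults, smaller eyes and patch scales.
smallPresets <- function() {
  lapply(genotypePresets(), function(g) {
    g@eyeAxes <- c(14, 11)
    if (g@distribution$kind == "mixture") g@distribution$patchScale <- 3
    g
  })
}

smallPlate <- function(genos, nPerGeno = 2, seed = 1L, checker = FALSE) {
  renderPlate(
    plateSpec(nPerGeno, length(genos), genos, cellSize = c(40, 44),
              checker = checker, seed = seed),
    genotypes = smallPresets())
}

uniformImage <- function(h, w, rgb) {
  img <- array(0L, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- as.integer(rgb[ch])
  img
}
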