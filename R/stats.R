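#' Per-eye pigment summaries
#'
#' Collapses the long-format pixel table to one row per eye (ROI): pixel
#' count, mean, median and sample standard deviation of the pigment values.
#' Summaries appear in first-appearance order of the ROI names, and any
#' factor columns present on the table (from [readPixelCsv()]) are carried
#' through.
#'
#' @param table pixel table with columns \code{ROI} and \code{pixel}.
#' @return \code{data.frame} with columns \code{ROI, nPixels, mean, median,
#'   sd} plus carried factor columns.
#' @seealso [meanDifference()], [interoperatorCv()]
#' @export
summarizeEyes <- function(table) {
  stopifnot(all(c("ROI", "pixel") %in% names(table)))
  if (nrow(table) == 0L) stop("empty pixel table")
  rois <- unique(table$ROI)
  groups <- split(table$pixel, factor(table$ROI, levels = rois))
  out <- data.frame(
    ROI = rois,
    nPixels = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    median = vapply(groups, function(x) as.numeric(stats::median(x)),
                    numeric(1)),
    sd = vapply(groups, function(x) if (length(x) > 1) stats::sd(x) else 0,
                numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  extraCols <- setdiff(names(table), c("ROI", "pixel"))
  if (length(extraCols)) {
    first <- table[!duplicated(table$ROI), c("ROI", extraCols)]
    out <- merge(out, first, by = "ROI", sort = FALSE)
    out <- out[match(rois, out$ROI), ]
    rownames(out) <- NULL
  }
  out
}

#' Per-eye intensity histogram
#'
#' Counts pixels at each of the 256 pigment intensities for one eye.
#' Histograms of individual eyes reveal bimodal or otherwise non-normal
#' pigment distributions, the hallmark of variegating (PEV) genotypes.
#'
#' @param table pixel table with columns \code{ROI} and \code{pixel}.
#' @param roiName name of the eye to tabulate.
#' @return Integer vector of length 256, named \code{"0"..."255"}; bin i
#'   counts pixels of value i, and the bins sum to the eye's pixel count.
#' @export
eyeHistogram <- function(table, roiName) {
  stopifnot(all(c("ROI", "pixel") %in% names(table)))
  px <- table$pixel[table$ROI == roiName]
  if (!length(px)) stop("unknown ROI: ", roiName)
  counts <- tabulate(px + 1L, nbins = 256L)
  names(counts) <- 0:255
  counts
}

.eyeMeans <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("mean" %in% names(x))
    x$mean
  } else as.numeric(x)
}

#' Bootstrap mean pigment difference between two groups of eyes
#'
#' The estimation-statistics core of the workflow: the effect of a genotype
#' or treatment is reported as the difference of group means of per-eye
#' mean intensities (group B minus group A), with a 95\% bootstrap
#' confidence interval instead of a p-value. The resampling unit is the
#' eye: within each group, eyes are resampled with replacement and the
#' difference of resampled group means recomputed. The default interval is
#' bias-corrected accelerated (BCa), which accommodates the asymmetric
#' sampling distributions typical of bounded, variegating pigment data; a
#' plain percentile interval is available as a fallback. Results are fully
#' reproducible given \code{seed}.
#'
#' @param summariesA,summariesB per-eye summaries for the two groups
#'   (data frames from [summarizeEyes()], or plain numeric vectors of
#'   per-eye means); each group needs at least 2 eyes.
#' @param nBoot number of bootstrap resamples (default 5000).
#' @param seed integer RNG seed for the resampling.
#' @param method \code{"bca"} (default) or \code{"percentile"}.
#' @param groupA,groupB group labels for reporting.
#' @return An [EffectSize-class].
#' @examples
#' a <- c(10, 20, 30); b <- c(40, 50, 60)
#' meanDifference(a, b, nBoot = 999, seed = 1)
#' @export
meanDifference <- function(summariesA, summariesB, nBoot = 5000L,
                           seed = 17L, method = c("bca", "percentile"),
                           groupA = "A", groupB = "B") {
  method <- match.arg(method)
  a <- .eyeMeans(summariesA)
  b <- .eyeMeans(summariesB)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 eyes")
  nBoot <- as.integer(nBoot)
  t0 <- mean(b) - mean(a)
  stats <- withr::with_seed(as.integer(seed), {
    ia <- matrix(sample.int(length(a), length(a) * nBoot, replace = TRUE),
                 nrow = nBoot)
    ib <- matrix(sample.int(length(b), length(b) * nBoot, replace = TRUE),
                 nrow = nBoot)
    rowMeans(matrix(b[ib], nrow = nBoot)) -
      rowMeans(matrix(a[ia], nrow = nBoot))
  })
  alpha <- c(0.025, 0.975)
  if (method == "percentile") {
    ci <- unname(stats::quantile(stats, alpha, type = 7))
  } else {
    # BCa: bias correction from the bootstrap distribution, acceleration
    # from a leave-one-eye-out jackknife over both groups.
    z0 <- stats::qnorm((sum(stats < t0) + 0.5 * sum(stats == t0)) /
                         length(stats))
    jack <- c(
      vapply(seq_along(a), function(i) mean(b) - mean(a[-i]), numeric(1)),
      vapply(seq_along(b), function(i) mean(b[-i]) - mean(a), numeric(1)))
    d <- mean(jack) - jack
    accel <- sum(d^3) / (6 * sum(d^2)^1.5)
    if (!is.finite(z0) || !is.finite(accel)) {
      # degenerate bootstrap distribution (e.g. zero-variance groups)
      ci <- unname(stats::quantile(stats, alpha, type = 7))
    } else {
      zAlpha <- stats::qnorm(alpha)
      adj <- stats::pnorm(z0 + (z0 + zAlpha) / (1 - accel * (z0 + zAlpha)))
      ci <- unname(stats::quantile(stats, adj, type = 7))
    }
  }
  new("EffectSize", groupA = as.character(groupA),
      groupB = as.character(groupB), diff = t0,
      ciLow = min(ci[1], t0), ciHigh = max(ci[2], t0),
      nA = length(a), nB = length(b), nBoot = nBoot,
      seed = as.integer(seed), method = method)
}

#' Inter-operator coefficient of variation per genotype
#'
#' Quantifies segmentation reproducibility when several operators
#' independently segment the same image: for each genotype, the per-user
#' mean of per-eye mean intensities is computed, and the spread across
#' users is reported as a percent coefficient of variation,
#' \code{100 * sd(perUserMeans) / mean(perUserMeans)}. Low-intensity
#' (light-eyed) genotypes naturally show higher CVs because the same
#' absolute spread is a larger fraction of a small mean.
#'
#' @param summaries per-eye summary data frame carrying \code{genotype} and
#'   \code{user} columns (see [summarizeEyes()] on a table from
#'   [readPixelCsv()]).
#' @param genotypeCol,userCol column names of the grouping factors.
#' @return \code{data.frame} with one row per genotype: \code{genotype},
#'   \code{nUsers}, \code{cvPercent}, and a \code{perUserMeans} list
#'   column of the named per-user means.
#' @export
interoperatorCv <- function(summaries, genotypeCol = "genotype",
                            userCol = "user") {
  stopifnot(all(c(genotypeCol, userCol, "mean") %in% names(summaries)))
  genos <- unique(as.character(summaries[[genotypeCol]]))
  rows <- lapply(genos, function(g) {
    sub <- summaries[as.character(summaries[[genotypeCol]]) == g, ]
    users <- unique(as.character(sub[[userCol]]))
    if (length(users) < 2L)
      stop("genotype '", g, "' has fewer than 2 users; CV undefined")
    pum <- vapply(users, function(u)
      mean(sub$mean[as.character(sub[[userCol]]) == u]), numeric(1))
    m <- mean(pum)
    if (m == 0)
      stop("genotype '", g, "' has zero mean intensity; CV undefined ",
           "(white-eyed edge case)")
    data.frame(genotype = g, nUsers = length(users),
               cvPercent = 100 * stats::sd(pum) / m,
               perUserMeans = I(list(pum)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published reference intensities for plot annotation
#'
#' The two internal landmarks used on every pigment plot: the average mean
#' eye intensity of white-eyed flies (beige line) and of wild-type flies
#' (red line). Values are calibration constants of the workflow and can be
#' overridden.
#'
#' @param white,wildtype reference pigment intensities.
#' @return Named numeric vector \code{c(white = 35, wildtype = 140)} by
#'   default.
#' @export
referenceLines <- function(white = 35, wildtype = 140) {
  c(white = white, wildtype = wildtype)
}
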