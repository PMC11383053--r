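#' Ridgeline plot of per-eye intensity histograms
#'
#' Displays every eye's full pixel-intensity distribution as a vertical
#' histogram, eyes side by side (optionally arranged by group, e.g. in
#' order of pigment expression), with horizontal reference lines at the
#' white (beige) and wild-type (red) calibration intensities. Bimodal
#' variegating eyes show up as two-lobed silhouettes.
#'
#' @param table pixel table with columns \code{ROI}, \code{pixel} and
#'   optionally a grouping column.
#' @param file output figure path (extension selects the format).
#' @param order optional character vector of group labels giving the
#'   left-to-right arrangement; unknown labels are an error.
#' @param groupCol grouping column used with \code{order} (default
#'   \code{"genotype"}; parsed from ROI names if absent).
#' @param refLines named vector from [referenceLines()].
#' @return The figure path, invisibly. The input table is not modified.
#' @export
plotRidgeline <- function(table, file, order = NULL, groupCol = "genotype",
                          refLines = referenceLines()) {
  stopifnot(all(c("ROI", "pixel") %in% names(table)), nrow(table) > 0)
  df <- table
  if (!is.null(order) || !groupCol %in% names(df)) {
    if (!groupCol %in% names(df)) {
      keys <- parseRoiNames(unique(df$ROI))
      df[[groupCol]] <- keys[[groupCol]][match(df$ROI, unique(df$ROI))]
    }
  }
  eyes <- unique(df$ROI)
  if (!is.null(order)) {
    groups <- as.character(df[[groupCol]][match(eyes, df$ROI)])
    unknown <- setdiff(order, groups)
    if (length(unknown))
      stop("unknown group(s) in 'order': ", paste(unknown, collapse = ", "))
    eyes <- eyes[order(match(groups, order))]
  }
  polys <- do.call(rbind, lapply(seq_along(eyes), function(j) {
    counts <- eyeHistogram(df, eyes[j])
    data.frame(eye = eyes[j], pos = j, intensity = 0:255,
               w = 0.85 * counts / max(counts))
  }))
  p <- ggplot2::ggplot(polys) +
    ggplot2::geom_ribbon(ggplot2::aes(
      y = .data$intensity, xmin = .data$pos, xmax = .data$pos + .data$w,
      group = .data$eye), fill = "grey35", orientation = "y") +
    ggplot2::geom_hline(yintercept = refLines[["white"]],
                        colour = "#d8c49a", linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = refLines[["wildtype"]],
                        colour = "#c23b22", linewidth = 0.8) +
    ggplot2::scale_x_continuous(breaks = seq_along(eyes), labels = eyes) +
    ggplot2::labs(x = NULL, y = "pigment intensity (0-255)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
  ggplot2::ggsave(file, p, width = max(4, 1 + 0.6 * length(eyes)),
                  height = 4, dpi = 120)
  invisible(file)
}

#' Swarm-and-box plot of per-eye means
#'
#' One filled circle per eye (its mean pigment intensity), a box showing
#' the interquartile range with the median as a horizontal line, a filled
#' black square at each group mean, and the white/wild-type reference
#' lines. When an [EffectSize-class] is supplied, its estimate and CI are
#' annotated on the figure.
#'
#' @param summaries per-eye summary data frame from [summarizeEyes()] with
#'   a grouping column.
#' @param file output figure path.
#' @param effect optional [EffectSize-class] to annotate.
#' @param groupCol grouping column (default \code{"genotype"}).
#' @param refLines named vector from [referenceLines()].
#' @return The figure path, invisibly.
#' @export
plotSwarmBox <- function(summaries, file, effect = NULL,
                         groupCol = "genotype",
                         refLines = referenceLines()) {
  stopifnot("mean" %in% names(summaries), nrow(summaries) > 0)
  df <- summaries
  if (!groupCol %in% names(df)) {
    keys <- parseRoiNames(df$ROI)
    df[[groupCol]] <- keys[[groupCol]]
  }
  df$.group <- factor(as.character(df[[groupCol]]))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$.group, y = .data$mean)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.45,
                          colour = "grey40", fill = NA) +
    ggplot2::geom_jitter(width = 0.12, height = 0, size = 1.8,
                         colour = "#2b6aa0", alpha = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 15,
                          size = 3, colour = "black") +
    ggplot2::geom_hline(yintercept = refLines[["white"]],
                        colour = "#d8c49a", linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = refLines[["wildtype"]],
                        colour = "#c23b22", linewidth = 0.8) +
    ggplot2::labs(x = NULL, y = "mean pigment intensity per eye") +
    ggplot2::theme_minimal()
  if (!is.null(effect)) {
    stopifnot(is(effect, "EffectSize"))
    lab <- sprintf("diff = %.3f [95%%CI %.3f, %.3f]",
                   effect@diff, effect@ciLow, effect@ciHigh)
    p <- p + ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.05,
                               vjust = 1.5, label = lab, size = 3.2)
  }
  ggplot2::ggsave(file, p, width = max(4, 1.5 + nlevels(df$.group)),
                  height = 4, dpi = 120)
  invisible(file)
}
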