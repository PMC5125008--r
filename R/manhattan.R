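#' Manhattan plot of a report
#'
#' Plots `-log10(p)` against genomic position with chromosomes in
#' alternating colours, significant SNPs highlighted, and the calibrated
#' threshold drawn as a dashed horizontal line — per chromosome when the
#' threshold was calibrated chromosome-wise, genome-wide otherwise.
#' P-values below `10^-cap` are drawn at the cap.
#'
#' @param report a [GwasReport-class].
#' @param outPath optional file path; when given the plot is saved there
#'   (format from the extension, via [ggplot2::ggsave()]).
#' @param cap y-axis truncation for `-log10(p)` (default 15).
#' @return the ggplot object, invisibly.
#' @export
manhattanPlot <- function(report, outPath = NULL, cap = 15) {
  res <- as.data.frame(snpResults(report))
  if (!nrow(res)) stop("empty report", call. = FALSE)
  chrLevels <- unique(res$chromosome)
  res$chromosome <- factor(res$chromosome, levels = chrLevels)
  # cumulative x coordinate so chromosomes sit side by side
  offs <- 0
  res$xpos <- NA_real_
  ticks <- numeric(length(chrLevels))
  for (i in seq_along(chrLevels)) {
    sel <- res$chromosome == chrLevels[i]
    res$xpos[sel] <- res$position[sel] + offs
    ticks[i] <- offs + mean(range(res$position[sel]))
    offs <- offs + max(res$position[sel]) + 1
  }
  res$logp <- pmin(-log10(res$p_value), cap)
  res$band <- factor(seq_along(chrLevels)[match(res$chromosome,
                                                chrLevels)] %% 2L)

  t <- tStar(report)
  thr <- if (length(t) == 1L)
    data.frame(chromosome = NA, y = -log10(unname(t)),
               xmin = -Inf, xmax = Inf)
  else {
    do.call(rbind, lapply(seq_along(chrLevels), function(i) {
      sel <- res$chromosome == chrLevels[i]
      data.frame(chromosome = chrLevels[i],
                 y = -log10(unname(t[as.character(chrLevels[i])])),
                 xmin = min(res$xpos[sel]), xmax = max(res$xpos[sel]))
    }))
  }
  thr <- thr[is.finite(thr$y), , drop = FALSE]
  thr$y <- pmin(thr$y, cap)

  p <- ggplot2::ggplot(res, ggplot2::aes(x = .data$xpos, y = .data$logp)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$band), size = 0.8,
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
    ggplot2::geom_point(data = res[res$significant, , drop = FALSE],
                        colour = "forestgreen", size = 1.6) +
    ggplot2::scale_x_continuous(breaks = ticks, labels = chrLevels) +
    ggplot2::coord_cartesian(ylim = c(0, cap)) +
    ggplot2::labs(x = "chromosome", y = expression(-log[10](italic(p))),
                  title = sprintf("%s (%s threshold)", report@method,
                                  report@threshold@criterion)) +
    ggplot2::theme_minimal()
  if (nrow(thr))
    p <- p + ggplot2::geom_segment(
      data = thr,
      ggplot2::aes(x = .data$xmin, xend = .data$xmax,
                   y = .data$y, yend = .data$y),
      linetype = "dashed", colour = "red", inherit.aes = FALSE)
  if (!is.null(outPath)) ggplot2::ggsave(outPath, p, width = 8, height = 3)
  invisible(p)
}
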