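## cumulative x-axis coordinates for a Manhattan plot; unmapped markers
## are appended in a trailing panel
.manhattan_coords <- function(assoc, map) {
  i <- match(assoc$marker, map$marker)
  lg <- map$linkage_group[i]
  pos <- map$position_cM[i]
  unmapped <- is.na(lg) | is.na(pos)
  lgs <- sort(unique(lg[!unmapped]))
  offs <- 0
  x <- rep(NA_real_, nrow(assoc))
  centers <- numeric(0)
  for (g in lgs) {
    sel <- !unmapped & lg == g
    span <- max(pos[sel]) - min(pos[sel]) + 1
    x[sel] <- offs + pos[sel] - min(pos[sel])
    centers <- c(centers, offs + span / 2)
    offs <- offs + span + 5
  }
  if (any(unmapped)) {
    k <- sum(unmapped)
    x[unmapped] <- offs + seq(0, max(k - 1, 1), length.out = k)
    centers <- c(centers, offs + (max(k - 1, 1)) / 2)
    lgs <- c(lgs, "NA")
  }
  list(x = x, lg = ifelse(unmapped, "NA", lg), panels = lgs,
       centers = centers)
}

#' Manhattan plot of association results
#'
#' Markers are placed at their genetic map positions, linkage groups
#' side by side; unmapped markers are drawn as black points in a
#' trailing panel. An optional horizontal line marks the genome-wide
#' significance threshold.
#'
#' @param assoc an `assoc_result`.
#' @param map marker map data.frame.
#' @param threshold optional `-log10 p` genome-wide threshold.
#' @param file optional PNG/SVG path; NULL plots to the active device.
#' @param main plot title.
#' @return invisible NULL.
#' @export
plot_manhattan <- function(assoc, map, threshold = NULL, file = NULL,
                           main = "GWAS") {
  co <- .manhattan_coords(assoc, map)
  if (!is.null(file)) .open_device(file)
  cols <- ifelse(co$lg == "NA", "black",
                 c("steelblue", "grey55")[1 + (match(co$lg, co$panels) %% 2)])
  graphics::plot(co$x, assoc$neg_log10_p, pch = 20, cex = 0.6,
                 col = cols, xaxt = "n", xlab = "linkage group",
                 ylab = expression(-log[10](p)), main = main)
  graphics::axis(1, at = co$centers, labels = co$panels, las = 2,
                 cex.axis = 0.7)
  if (!is.null(threshold))
    graphics::abline(h = threshold, lty = 3)
  if (!is.null(file)) grDevices::dev.off()
  invisible(NULL)
}

#' QQ plot of observed vs expected p-values
#'
#' @param qq a [qq_data()] result (or a p-value vector).
#' @param file optional PNG/SVG path.
#' @param main plot title.
#' @return invisible NULL.
#' @export
plot_qq <- function(qq, file = NULL, main = "QQ plot") {
  if (!inherits(qq, "qq_data")) qq <- qq_data(qq)
  if (!is.null(file)) .open_device(file)
  graphics::plot(qq$points$expected, qq$points$observed, pch = 20,
                 cex = 0.6, xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)),
                 main = sprintf("%s (lambda[GC] = %.3f)", main,
                                qq$lambda_gc))
  graphics::abline(0, 1, lty = 2)
  if (!is.null(file)) grDevices::dev.off()
  invisible(NULL)
}

#' LD decay plot
#'
#' Per-bin upper-percentile of corrected r2 against map distance with
#' the smoothed decay curve.
#'
#' @param curve an [decay_curve()] result.
#' @param file optional PNG/SVG path.
#' @return invisible NULL.
#' @export
plot_ld_decay <- function(curve, file = NULL) {
  b <- curve$bins
  if (!is.null(file)) .open_device(file)
  graphics::plot(b$mid, b$percentile, pch = 1, col = "grey50",
                 xlab = "distance (cM)",
                 ylab = sprintf("%dth percentile of r2", curve$percentile))
  u <- b$used
  graphics::lines(b$mid[u], b$smoothed[u], lwd = 2, col = "firebrick")
  if (!is.null(file)) grDevices::dev.off()
  invisible(NULL)
}

.open_device <- function(file) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         png = grDevices::png(file, width = 1600, height = 900, res = 150),
         svg = grDevices::svg(file, width = 10, height = 6),
         stop("unsupported plot format: ", ext))
}
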