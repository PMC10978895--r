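# Diagnostic figures: the angle-colored outline with change-point markers,
# and the arc-length versus angle plot with segment means.

#' Plot an analyzed artifact to image files
#'
#' Writes two figures: (1) the plan-view outline colored by edge angle with
#' change points marked, and (2) arc length against edge angle with the
#' local mean of each segment. Output is PNG when a device is available,
#' falling back to PDF; if no device can be opened the plots are skipped
#' with a warning (plots are a convenience, not a pipeline stage).
#'
#' @param report an `artifact_report`.
#' @param outline the matching `outline3d`.
#' @param profile the matching `edge_angle_profile`.
#' @param seg the matching `segmentation`.
#' @param dir output directory.
#' @param basename file name stem (defaults to the artifact id).
#' @return invisibly, character vector of files written (possibly empty).
#' @export
plot_artifact <- function(report, outline, profile, seg, dir = ".",
                          basename = NULL) {
  if (is.null(basename)) basename <- gsub("[^A-Za-z0-9_.-]", "_", report$artifact_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  open_dev <- function(stem) {
    png_path <- file.path(dir, paste0(stem, ".png"))
    ok <- tryCatch({
      grDevices::png(png_path, width = 900, height = 700, type = "cairo")
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(png_path)
    pdf_path <- file.path(dir, paste0(stem, ".pdf"))
    ok <- tryCatch({
      grDevices::pdf(pdf_path, width = 9, height = 7)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(pdf_path)
    NULL
  }
  files <- character(0)

  pal <- grDevices::colorRampPalette(c("#2166ac", "#67a9cf", "#fddbc7",
                                       "#ef8a62", "#b2182b"))(100)
  col_of <- pal[pmin(100L, pmax(1L, ceiling(profile$angle / 180 * 100)))]
  bps <- seg$breakpoints

  f1 <- open_dev(paste0(basename, "_outline"))
  if (!is.null(f1)) {
    p <- outline$coords
    graphics::plot(p[, 1], p[, 2], asp = 1, pch = 16, cex = 0.6, col = col_of,
                   xlab = "x (length units)", ylab = "y",
                   main = sprintf("%s: edge angle around outline", report$artifact_id))
    if (length(bps)) {
      graphics::points(p[bps, 1], p[bps, 2], pch = 4, cex = 2, lwd = 2, col = "red")
    }
    grDevices::dev.off()
    files <- c(files, f1)
  }

  f2 <- open_dev(paste0(basename, "_profile"))
  if (!is.null(f2)) {
    graphics::plot(outline$arc_pos, profile$angle, type = "l",
                   xlab = "arc length from tip", ylab = "edge angle (deg)",
                   ylim = c(0, 180),
                   main = sprintf("%s: CEAM profile, %d change point(s)",
                                  report$artifact_id, seg$chosen_k))
    bounds <- c(0L, bps, seg$n)
    for (s in seq_along(seg$segment_means)) {
      idx <- c(bounds[s] + 1L, bounds[s + 1L])
      graphics::segments(outline$arc_pos[idx[1]], seg$segment_means[s],
                         outline$arc_pos[idx[2]], seg$segment_means[s],
                         col = "blue", lwd = 2)
    }
    if (length(bps)) {
      graphics::abline(v = outline$arc_pos[bps], col = "red", lty = 2)
    }
    grDevices::dev.off()
    files <- c(files, f2)
  }
  if (length(files) == 0L) warning("no graphics device available; plots skipped")
  invisible(files)
}
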