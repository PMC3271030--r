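#' @importFrom ggplot2 ggplot aes geom_point geom_segment geom_hline
#'   geom_vline labs theme_bw scale_colour_manual
NULL

.openDevice <- function(path, format, width, height, dpi) {
  switch(format,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = dpi),
         pdf = grDevices::pdf(path, width = width, height = height),
         svg = grDevices::svg(path, width = width, height = height),
         stop("unsupported format: ", format))
}

.armColors <- c(treated = "#0072B2", control = "#D55E00")  # colorblind-safe

#' Plot the health space
#'
#' Renders the scaled scores: one 3-D view (when at least three axes exist)
#' plus every pairwise 2-D projection.  Each subject can be drawn as a
#' vector from its control point to its treated point (the individual
#' treatment displacement); dashed reference lines mark the 0 (treated-group
#' mean, the healthy origin) and 1 (control-group mean) anchors on every
#' axis.  The display axes are drawn orthogonal even though the underlying
#' processes are statistically interdependent; no re-orthogonalization is
#' performed.
#'
#' @param scores a non-empty [ScoreSet-class] with >= 2 axes.
#' @param axes axis names to plot, in (x, y, z) display order; defaults to
#'   all axes of `scores`.  Unknown names raise an error.
#' @param dir output directory (created if needed).
#' @param basename file name stem.
#' @param format `"pdf"` (default), `"png"` or `"svg"`.
#' @param width,height device size in inches; `dpi` applies to png.
#' @param drawVectors draw the per-subject control-to-treated segments.
#' @return character vector of the files written, invisibly.
#' @export
plotHealthSpace <- function(scores, axes = axisNames(scores), dir = ".",
                            basename = "health_space",
                            format = c("pdf", "png", "svg"),
                            width = 7, height = 6, dpi = 150,
                            drawVectors = TRUE) {
  format <- match.arg(format)
  stopifnot(methods::is(scores, "ScoreSet"))
  if (nrow(scores@scores) == 0L)
    stop("empty ScoreSet: nothing to plot")
  unknown <- setdiff(axes, axisNames(scores))
  if (length(unknown))
    stop("unknown axis name(s): ", paste(unknown, collapse = ", "))
  if (length(axes) < 2L)
    stop("plotting needs at least 2 axes")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  df <- data.frame(subject = scores@subjectId, arm = scores@arm,
                   scores@scores[, axes, drop = FALSE], check.names = FALSE)
  files <- character()

  if (length(axes) >= 3L) {
    path <- file.path(dir, paste0(basename, "_3d.", format))
    .openDevice(path, format, width, height, dpi)
    fml <- stats::as.formula(
      sprintf("`%s` ~ `%s` * `%s`", axes[3], axes[1], axes[2]))
    print(lattice::cloud(fml, data = df, groups = df$arm, pch = 19,
                         par.settings = list(superpose.symbol = list(
                           col = unname(.armColors))),
                         auto.key = list(space = "right"),
                         main = "Health space (scaled scores)"))
    grDevices::dev.off()
    files <- c(files, path)
  }

  for (pair in utils::combn(axes, 2L, simplify = FALSE)) {
    ax <- pair[1]; ay <- pair[2]
    p <- ggplot(df, aes(x = .data[[ax]], y = .data[[ay]], colour = .data$arm)) +
      geom_vline(xintercept = c(0, 1), linetype = "dashed", colour = "grey60") +
      geom_hline(yintercept = c(0, 1), linetype = "dashed", colour = "grey60") +
      geom_point(size = 2) +
      scale_colour_manual(values = .armColors) +
      labs(x = paste(ax, "(scaled score)"), y = paste(ay, "(scaled score)"),
           colour = "arm") +
      theme_bw()
    if (drawVectors) {
      wide <- merge(df[df$arm == "control", c("subject", ax, ay)],
                    df[df$arm == "treated", c("subject", ax, ay)],
                    by = "subject", suffixes = c(".c", ".t"))
      p <- p + geom_segment(
        data = wide,
        aes(x = .data[[paste0(ax, ".c")]], y = .data[[paste0(ay, ".c")]],
            xend = .data[[paste0(ax, ".t")]], yend = .data[[paste0(ay, ".t")]]),
        inherit.aes = FALSE, colour = "grey40", linewidth = 0.3,
        arrow = grid::arrow(length = grid::unit(0.12, "cm")))
    }
    path <- file.path(dir, paste0(basename, "_", ax, "_vs_", ay, ".", format))
    .openDevice(path, format, width, height, dpi)
    print(p)
    grDevices::dev.off()
    files <- c(files, path)
  }
  invisible(files)
}

#' Plot the response clustering (dendrogram + heatmap)
#'
#' Left panel: the UPGMA dendrogram of the non-outlier subjects.  Right
#' panel: the per-subject per-axis response heatmap, rows in dendrogram leaf
#' order with the cluster label shown per row; outlier subjects are appended
#' below a separator, marked "(outlier)", and carry no cluster band.
#'
#' @param responses a clustered [ResponseSet-class] (see
#'   [clusterResponses()]).
#' @param path output file path.
#' @param format `"pdf"` (default), `"png"` or `"svg"`.
#' @param width,height,dpi device settings.
#' @return `path`, invisibly.  The leaf order used is attached as the
#'   attribute `"row_order"` of the return value.
#' @export
plotResponseClustering <- function(responses, path,
                                   format = c("pdf", "png", "svg"),
                                   width = 8, height = 6, dpi = 150) {
  format <- match.arg(format)
  stopifnot(methods::is(responses, "ResponseSet"))
  hc <- responseDendrogram(responses)
  if (!all(hc$labels %in% responses@subjectId))
    stop("dendrogram subjects do not match the ResponseSet")
  leaf_order <- hc$labels[hc$order]
  outliers <- responses@subjectId[responses@outlier]
  n_out <- length(outliers)
  # bottom-to-top display order: outliers below a separator, then the
  # dendrogram leaves in tree order
  display_ids <- c(rev(outliers), leaf_order)
  mat <- responses@responses[display_ids, , drop = FALSE]
  n <- nrow(mat)
  pal <- grDevices::hcl.colors(101, "Blue-Red 3")
  lim <- max(abs(mat), 1e-12)

  .openDevice(path, format, width, height, dpi)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::layout(matrix(1:2, 1L), widths = c(1, 1.6))
  old <- graphics::par(mar = c(4, 1, 3, 0))
  on.exit(graphics::par(old), add = TRUE)
  graphics::plot(stats::as.dendrogram(hc), horiz = TRUE, leaflab = "none",
                 yaxs = "i", ylim = c(0.5 - n_out, length(leaf_order) + 0.5),
                 main = "response clustering (UPGMA)")
  graphics::par(mar = c(4, 5, 3, 6))
  graphics::image(x = seq_len(ncol(mat)), y = seq_len(n), z = t(mat),
                  zlim = c(-lim, lim), col = pal, axes = FALSE,
                  ylim = c(0.5, n + 0.5), xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(ncol(mat)), labels = colnames(mat),
                 las = 2, cex.axis = 0.8)
  cl <- clusterLabels(responses)[display_ids]
  lab <- ifelse(display_ids %in% outliers, paste(display_ids, "(outlier)"),
                paste0(display_ids, " [", cl, "]"))
  graphics::axis(4, at = seq_len(n), labels = lab, las = 2, cex.axis = 0.7,
                 tick = FALSE)
  if (n_out)
    graphics::abline(h = n_out + 0.5, lwd = 2)
  graphics::title(main = "per-axis response (control - treated)")
  out <- invisible(path)
  attr(out, "row_order") <- rev(display_ids)  # top row first
  out
}
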