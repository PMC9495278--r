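#' Collate evaluation runs into a comparison grid
#'
#' Builds the method x view x attention comparison table (one row per
#' configuration) from a set of `metrics_report` objects, mirroring the
#' usual ablation layout: per row the method arm, the view configuration,
#' whether attention guidance was enabled, pooled ACC and F1, and the
#' cross-fold AUC mean and sd.
#'
#' @param entries list of entries, each a list with `method` (e.g.
#'   `"network"` or `"radiomics"`), `view` (view name or `"multi-view"`),
#'   `attention` (logical or NA), and `report` (a `metrics_report`).
#' @return Data frame with columns method, view, attention, acc,
#'   auc_mean, auc_sd, f1.
#' @export
comparison_report <- function(entries) {
  rows <- lapply(entries, function(e) {
    stopifnot(inherits(e$report, "metrics_report"))
    data.frame(method = e$method, view = e$view,
               attention = if (is.null(e$attention)) NA else e$attention,
               acc = e$report$acc, auc_mean = e$report$auc_mean,
               auc_sd = e$report$auc_sd, f1 = e$report$f1)
  })
  do.call(rbind, rows)
}

#' Write a comparison grid as CSV and markdown
#'
#' @param grid data frame from [comparison_report()].
#' @param directory output directory (created if needed).
#' @return Named character vector with the `csv` and `markdown` paths.
#' @export
write_report <- function(grid, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  csv_path <- file.path(directory, "comparison.csv")
  md_path <- file.path(directory, "comparison.md")
  utils::write.csv(grid, csv_path, row.names = FALSE)
  fmt <- function(x) sprintf("%.4f", x)
  lines <- c(
    "| Method | View | Attention | ACC | AUC | F1 |",
    "|---|---|---|---|---|---|",
    vapply(seq_len(nrow(grid)), function(i) {
      att <- if (is.na(grid$attention[i])) "-" else {
        if (grid$attention[i]) "yes" else "no"
      }
      sprintf("| %s | %s | %s | %s | %s ± %s | %s |",
              grid$method[i], grid$view[i], att, fmt(grid$acc[i]),
              fmt(grid$auc_mean[i]), fmt(grid$auc_sd[i]), fmt(grid$f1[i]))
    }, character(1))
  )
  writeLines(lines, md_path)
  c(csv = csv_path, markdown = md_path)
}

#' Export an attention heatmap
#'
#' Writes the raw attention array as CSV and, when the `png` package is
#' available, a gray-image/heat overlay PNG.
#'
#' @param attention matrix in `[0, 1]`.
#' @param image2d the underlying image (for the overlay).
#' @param path_prefix output path without extension.
#' @return Character vector of files written, invisibly.
#' @export
export_heatmap <- function(attention, image2d, path_prefix) {
  csv_path <- paste0(path_prefix, ".csv")
  utils::write.table(attention, csv_path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  written <- csv_path
  if (requireNamespace("png", quietly = TRUE)) {
    g <- (image2d - min(image2d)) / max(1e-12, diff(range(image2d)))
    rgb <- array(0, c(nrow(g), ncol(g), 3))
    rgb[, , 1] <- pmin(1, g + attention)      # attention tints red
    rgb[, , 2] <- g * (1 - 0.5 * attention)
    rgb[, , 3] <- g * (1 - 0.5 * attention)
    png_path <- paste0(path_prefix, ".png")
    png::writePNG(rgb, png_path)
    written <- c(written, png_path)
  }
  invisible(written)
}
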