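#' Export co-expression heatmaps and matrix CSVs
#'
#' One heatmap per (treatment, nucleus) matrix on a diverging blue-white-red
#' scale anchored at r = -1 and +1, with significance marks from the
#' BH-adjusted p-values: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `.` p < 0.1. Missing cells are rendered in neutral grey and annotated
#' `na`. Each matrix is also written as a per-cell CSV.
#'
#' @param matrices list of `coexpr_matrix` objects.
#' @param out_dir output directory (created if needed).
#' @param format `"png"` or `"svg"`.
#' @param write_images set `FALSE` to write only the CSVs.
#' @return invisibly, the files written.
#' @export
export_heatmaps <- function(matrices, out_dir, format = c("png", "svg"),
                            write_images = TRUE) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#FFFFFF", "#B2182B"))(101)
  breaks <- seq(-1, 1, length.out = 102)
  files <- character(0)
  for (m in matrices) {
    stem <- paste0("coexpr_", m$treatment, "_", m$nucleus)
    cells <- data.frame(
      gene1 = rep(m$genes, times = length(m$genes)),
      gene2 = rep(m$genes, each = length(m$genes)),
      r = as.vector(m$r), n = as.vector(m$n),
      p = as.vector(m$p), p_adj = as.vector(m$p_adj))
    csv <- file.path(out_dir, paste0(stem, ".csv"))
    write_table_csv(cells, csv)
    files <- c(files, csv)
    if (!write_images) next
    marks <- significance_marks(m$p_adj)
    diag(marks) <- ""
    r_plot <- m$r
    r_plot[is.na(r_plot)] <- 0
    marks[is.na(m$r)] <- "na"
    img <- file.path(out_dir, paste0(stem, ".", format))
    if (format == "png") grDevices::png(img, width = 640, height = 560)
    else grDevices::svg(img, width = 6.4, height = 5.6)
    tryCatch(
      pheatmap::pheatmap(
        r_plot, color = pal, breaks = breaks,
        cluster_rows = FALSE, cluster_cols = FALSE,
        display_numbers = marks, fontsize_number = 12,
        na_col = "#CCCCCC",
        main = paste0(m$treatment, " / ", m$nucleus)),
      finally = grDevices::dev.off())
    files <- c(files, img)
  }
  invisible(files)
}

#' Significance marks for adjusted p-values
#'
#' @param p matrix or vector of (adjusted) p-values.
#' @return same shape, with `***`, `**`, `*`, `.` or `""`.
#' @export
significance_marks <- function(p) {
  out <- ifelse(is.na(p), "",
                ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**",
                              ifelse(p < 0.05, "*",
                                     ifelse(p < 0.1, ".", "")))))
  if (is.matrix(p)) dim(out) <- dim(p)
  out
}
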