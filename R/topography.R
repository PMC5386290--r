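#' Reshape per-node values into the fixed grid layout
#'
#' Row-major, 1-based: grid cell (r, c) always holds node id
#' `(r-1)*cols + c`, so node positions are identical across every panel.
#' Missing node values are preserved as `NA`.
#'
#' @param node_values numeric vector indexed by node id 1..rows*cols (a named
#'   vector may cover a subset; unnamed vectors must have length rows*cols).
#' @param rows,cols grid dimensions.
#' @param kind value kind label (e.g. `"mean_level"`, `"protein_count"`).
#' @param condition,time panel metadata.
#' @return A `topography_matrix` (rows x cols) with attributes `kind`,
#'   `condition`, `time`.
#' @export
topography_matrix <- function(node_values, rows, cols, kind = "value",
                              condition = NA_character_, time = NA_character_) {
  n_nodes <- rows * cols
  if (is.null(names(node_values))) {
    if (length(node_values) != n_nodes) {
      stop("unnamed node_values must have length rows * cols")
    }
    v <- as.numeric(node_values)
  } else {
    idx <- as.integer(names(node_values))
    if (anyNA(idx) || any(idx < 1) || any(idx > n_nodes)) {
      stop("node id out of range 1..", n_nodes)
    }
    v <- rep(NA_real_, n_nodes)
    v[idx] <- as.numeric(node_values)
  }
  m <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  structure(m, class = c("topography_matrix", "matrix"),
            kind = kind, condition = condition, time = time)
}

#' Flatten a topography matrix back to the node-value vector
#' @param tm a `topography_matrix`.
#' @return numeric vector indexed by node id (row-major).
#' @export
flatten_topography <- function(tm) {
  as.vector(t(unclass(tm)))
}

#' Render topography heatmaps with a shared color scale per value kind
#'
#' Writes one PNG heatmap and one TSV twin per matrix. All matrices must share
#' the same grid dimensions; panels of the same `kind` share one color scale
#' so cells are comparable across conditions and time points. Missing nodes
#' are drawn in grey.
#'
#' @param matrices named list of `topography_matrix` objects.
#' @param out_dir output directory (created if needed).
#' @param palette color ramp function (levels -> colors).
#' @param px pixel size per grid cell.
#' @return data frame of written files with the scale bounds used, invisibly.
#' @export
render_topographies <- function(matrices, out_dir,
                                palette = grDevices::hcl.colors, px = 24) {
  stopifnot(length(matrices) > 0, !is.null(names(matrices)))
  dims <- vapply(matrices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all topography matrices must share the same grid dimensions")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kinds <- vapply(matrices, attr, character(1), "kind")
  zlim_by_kind <- lapply(split(matrices, kinds), function(ms) {
    v <- unlist(lapply(ms, as.vector))
    v <- v[is.finite(v)]
    if (length(v) == 0) c(0, 1) else range(v)
  })
  rows <- dims[1, 1]; cols <- dims[2, 1]
  files <- lapply(names(matrices), function(nm) {
    tm <- matrices[[nm]]
    kind <- attr(tm, "kind")
    zlim <- zlim_by_kind[[kind]]
    if (zlim[1] == zlim[2]) zlim <- zlim + c(-0.5, 0.5)
    tsv <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(unclass(tm), tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    png_file <- file.path(out_dir, paste0(nm, ".png"))
    grDevices::png(png_file, width = cols * px + 80, height = rows * px + 80)
    op <- graphics::par(mar = c(2, 2, 3, 1))
    # image() draws row 1 at the bottom; flip so grid row 1 is on top
    z <- t(unclass(tm))[, rev(seq_len(rows)), drop = FALSE]
    graphics::image(x = seq_len(cols), y = seq_len(rows), z = z, zlim = zlim,
                    col = palette(64), axes = FALSE, xlab = "", ylab = "",
                    main = nm, useRaster = FALSE)
    if (anyNA(z)) {
      na_idx <- which(is.na(z), arr.ind = TRUE)
      graphics::rect(na_idx[, 1] - 0.5, na_idx[, 2] - 0.5,
                     na_idx[, 1] + 0.5, na_idx[, 2] + 0.5,
                     col = "grey85", border = NA)
    }
    graphics::box()
    graphics::par(op)
    grDevices::dev.off()
    data.frame(name = nm, kind = kind, png = png_file, tsv = tsv,
               zmin = zlim[1], zmax = zlim[2], stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, files))
}
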