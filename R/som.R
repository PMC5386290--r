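#' Plan a SOM grid from a genes-per-node resolution
#'
#' Chooses grid dimensions so that the map holds roughly `n_genes /
#' resolution` nodes with a portrait aspect ratio: the target node count is
#' `round(n_genes / resolution)`, the column count is
#' `floor(sqrt(target / aspect))` (clamped to at least 2) and the row count is
#' `round(target / cols)`. With 11,430 genes at 25 genes per node this yields
#' a 24 x 19 grid of 456 nodes.
#'
#' @param n_genes number of genes to be clustered.
#' @param resolution target genes per node.
#' @param aspect aspect constant controlling the rows:cols ratio.
#' @return integer vector `c(rows, cols)` with `rows >= cols`.
#' @export
plan_grid <- function(n_genes, resolution = 25, aspect = 1.26) {
  if (n_genes < 4 * resolution) {
    stop("too few genes to plan a grid at this resolution; supply rows/cols explicitly")
  }
  target <- round(n_genes / resolution)
  cols <- max(2L, as.integer(floor(sqrt(target / aspect))))
  rows <- as.integer(round(target / cols))
  if (rows < cols) { tmp <- rows; rows <- cols; cols <- tmp }
  c(rows = rows, cols = cols)
}

#' Grid coordinates of the nodes
#'
#' Node ids are 1..rows*cols in row-major order: id = (row-1)*cols + col.
#'
#' @param rows,cols grid dimensions.
#' @return matrix with columns `row`, `col`, one line per node id.
#' @export
node_coordinates <- function(rows, cols) {
  id <- seq_len(rows * cols)
  cbind(row = ((id - 1) %/% cols) + 1L, col = ((id - 1) %% cols) + 1L)
}

# Euclidean distances between node grid coordinates (nodes x nodes).
grid_distances <- function(rows, cols) {
  xy <- node_coordinates(rows, cols)
  as.matrix(stats::dist(xy))
}

#' Initial neighbourhood radius of a grid
#'
#' The 2/3 quantile (empirical cdf with linear interpolation, `type = 4`) of
#' all pairwise Euclidean distances between node grid coordinates.
#'
#' @param rows,cols grid dimensions.
#' @return positive scalar radius.
#' @export
initial_radius <- function(rows, cols) {
  if (rows * cols < 2) stop("grid must have at least 2 nodes")
  d <- stats::dist(node_coordinates(rows, cols))
  unname(stats::quantile(d, 2 / 3, type = 4))
}

#' Default training length in vector presentations
#'
#' 1000 presentations per node: `per_node * rows * cols` (e.g. 456,000 for a
#' 24 x 19 map). Convert to batch epochs with [batch_epochs()].
#'
#' @param rows,cols grid dimensions.
#' @param per_node presentations per node.
#' @return total number of vector presentations.
#' @export
default_epochs <- function(rows, cols, per_node = 1000) {
  as.numeric(per_node) * rows * cols
}

#' Convert vector presentations to batch epochs
#'
#' One batch epoch presents every gene once, so epochs =
#' `ceiling(presentations / n_genes)`, floored at `min_epochs`.
#'
#' @param presentations total vector presentations (see [default_epochs()]).
#' @param n_genes number of training vectors.
#' @param min_epochs lower bound on the epoch count.
#' @return integer epoch count.
#' @export
batch_epochs <- function(presentations, n_genes, min_epochs = 10) {
  max(as.integer(min_epochs), as.integer(ceiling(presentations / n_genes)))
}

# Squared Euclidean cross-distances between rows of x (n x d) and rows of
# w (m x d); returns n x m.
cross_dist2 <- function(x, w) {
  d2 <- -2 * x %*% t(w)
  d2 <- d2 + rowSums(x^2)
  d2 <- sweep(d2, 2, rowSums(w^2), "+")
  d2[d2 < 0] <- 0
  d2
}

# Best-matching unit per row of x; ties broken toward the lowest node id.
bmu_of <- function(x, codebook) {
  d2 <- cross_dist2(x, codebook)
  bmu <- max.col(-d2, ties.method = "first")
  list(bmu = bmu, dist = sqrt(d2[cbind(seq_len(nrow(x)), bmu)]))
}

#' Train a batch self-organizing map
#'
#' Batch training: each epoch assigns every gene to its best-matching unit
#' (minimum Euclidean distance; ties toward the lowest node id) and replaces
#' each codebook by the neighbourhood-weighted mean of the assigned vectors.
#' The neighbourhood kernel is a cut Gaussian over grid distance,
#' `exp(-d^2 / (2 r^2))` for `d < r` and zero beyond the radius, with the
#' radius decaying linearly from `r0` to 1 across epochs; in the final epochs
#' only the BMU itself is updated, so training degenerates to k-means steps.
#' Codebooks are initialized by seeded uniform draws within each feature's
#' data range (or along the first two principal components with
#' `init = "pca"`). Deterministic given `seed`.
#'
#' @param features numeric matrix, genes x features (typically log2 values of
#'   all replicate samples over all conditions and time points).
#' @param rows,cols grid dimensions (see [plan_grid()]).
#' @param epochs batch epochs; default derives from [default_epochs()] via
#'   [batch_epochs()].
#' @param r0 initial neighbourhood radius; default [initial_radius()].
#' @param seed RNG seed for the initialization.
#' @param init `"uniform"` (default) or `"pca"`.
#' @return A `som_model`: list with `rows`, `cols`, `codebook`
#'   (nodes x features), `coords`, `seed`, `epochs`, `r0`, `init`,
#'   `qe_initial`, `qe_final`, `qe_history`.
#' @export
train_som <- function(features, rows, cols,
                      epochs = batch_epochs(default_epochs(rows, cols), nrow(features)),
                      r0 = initial_radius(rows, cols),
                      seed = 1L, init = c("uniform", "pca")) {
  init <- match.arg(init)
  x <- as.matrix(features)
  if (anyNA(x) || any(!is.finite(x))) stop("features contain NaN/NA/Inf values")
  if (epochs < 1) stop("epochs must be >= 1")
  n_nodes <- rows * cols
  if (n_nodes < 2) stop("grid must have at least 2 nodes")
  d <- ncol(x)

  if (!is.null(seed)) set.seed(seed)
  if (init == "uniform") {
    lo <- apply(x, 2, min); hi <- apply(x, 2, max)
    codebook <- matrix(stats::runif(n_nodes * d, rep(lo, each = n_nodes),
                                    rep(hi, each = n_nodes)),
                       nrow = n_nodes, ncol = d)
  } else {
    pc <- stats::prcomp(x, rank. = 2)
    xy <- node_coordinates(rows, cols)
    u <- if (rows > 1) (xy[, "row"] - (rows + 1) / 2) / (rows / 2) else rep(0, n_nodes)
    v <- if (cols > 1) (xy[, "col"] - (cols + 1) / 2) / (cols / 2) else rep(0, n_nodes)
    sc <- cbind(u * 2 * stats::sd(pc$x[, 1]),
                v * 2 * if (ncol(pc$x) > 1) stats::sd(pc$x[, 2]) else 0)
    codebook <- sc %*% t(pc$rotation[, seq_len(ncol(sc)), drop = FALSE])
    codebook <- sweep(codebook, 2, colMeans(x), "+")
  }
  colnames(codebook) <- colnames(x)

  gd <- grid_distances(rows, cols)
  radii <- if (epochs == 1) r0 else seq(r0, 1, length.out = epochs)
  qe_history <- numeric(epochs)
  qe_initial <- mean(bmu_of(x, codebook)$dist)

  for (e in seq_len(epochs)) {
    fit <- bmu_of(x, codebook)
    qe_history[e] <- mean(fit$dist)
    r <- radii[e]
    h <- ifelse(gd < r, exp(-gd^2 / (2 * r^2)), 0)
    diag(h) <- 1
    sums <- matrix(0, n_nodes, d)
    hit <- rowsum(x, fit$bmu)
    sums[as.integer(rownames(hit)), ] <- hit
    n_assigned <- tabulate(fit$bmu, nbins = n_nodes)
    num <- h %*% sums
    den <- as.vector(h %*% n_assigned)
    upd <- den > 0
    codebook[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  }
  qe_final <- mean(bmu_of(x, codebook)$dist)
  rownames(codebook) <- seq_len(n_nodes)

  structure(list(rows = rows, cols = cols, codebook = codebook,
                 coords = node_coordinates(rows, cols),
                 seed = seed, epochs = epochs, r0 = r0, init = init,
                 qe_initial = qe_initial, qe_final = qe_final,
                 qe_history = qe_history),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("som model: %d x %d grid (%d nodes), %d features, %d epochs, r0 = %.3f\n",
              x$rows, x$cols, x$rows * x$cols, ncol(x$codebook), x$epochs, x$r0))
  cat(sprintf("  quantization error: %.4f -> %.4f\n", x$qe_initial, x$qe_final))
  invisible(x)
}

#' Assign genes to their best-matching nodes
#'
#' @param model a `som_model`.
#' @param features genes x features matrix; feature dimension must match the
#'   codebook.
#' @return A `node_assignment`: list with `node` (named integer vector,
#'   gene -> node id), `members` (list of gene id vectors per node),
#'   `n_nodes`.
#' @export
assign_genes_to_nodes <- function(model, features) {
  x <- as.matrix(features)
  if (ncol(x) != ncol(model$codebook)) {
    stop(sprintf("feature dimension %d does not match codebook dimension %d",
                 ncol(x), ncol(model$codebook)))
  }
  fit <- bmu_of(x, model$codebook)
  node <- fit$bmu
  names(node) <- rownames(x)
  members <- split(rownames(x), factor(node, levels = seq_len(model$rows * model$cols)))
  structure(list(node = node, members = members,
                 n_nodes = model$rows * model$cols,
                 rows = model$rows, cols = model$cols),
            class = "node_assignment")
}

#' @export
print.node_assignment <- function(x, ...) {
  occ <- sum(lengths(x$members) > 0)
  cat(sprintf("node assignment: %d genes over %d nodes (%d occupied)\n",
              length(x$node), x$n_nodes, occ))
  invisible(x)
}

#' Per-node mean expression topography
#'
#' Mean over member genes and replicate samples of the log2 values for every
#' (condition, time) cell. Empty nodes yield `NA` and are excluded from any
#' percentile computed downstream.
#'
#' @param assignment a `node_assignment` covering all genes of `nm`.
#' @param nm a `normalized_matrix`.
#' @return numeric matrix nodes x cells (colnames `condition.time`), with
#'   attributes `cells`, `rows`, `cols`.
#' @export
node_mean_topography <- function(assignment, nm) {
  stopifnot(inherits(assignment, "node_assignment"),
            inherits(nm, "normalized_matrix"))
  if (!setequal(names(assignment$node), rownames(nm$log2))) {
    stop("assignment does not cover the genes of the normalized matrix")
  }
  cells <- design_cells(nm$design)
  node <- assignment$node[rownames(nm$log2)]
  n_nodes <- assignment$n_nodes
  out <- matrix(NA_real_, n_nodes, nrow(cells),
                dimnames = list(seq_len(n_nodes), cells$label))
  sizes <- tabulate(node, nbins = n_nodes)
  for (i in seq_len(nrow(cells))) {
    s <- cell_samples(nm$design, cells$condition[i], cells$time[i])
    gene_mean <- rowMeans(nm$log2[, s, drop = FALSE])
    sums <- rowsum(gene_mean, node)
    out[as.integer(rownames(sums)), i] <- sums / sizes[as.integer(rownames(sums))]
  }
  attr(out, "cells") <- cells
  attr(out, "rows") <- assignment$rows
  attr(out, "cols") <- assignment$cols
  out
}

#' Per-node mean fold changes
#'
#' Node-level log2 fold change = mean of the member genes' fold changes, per
#' non-control (condition, time) cell.
#'
#' @param assignment a `node_assignment`.
#' @param fc a `fold_change_table`.
#' @return numeric matrix nodes x non-control cells; `NA` for empty nodes.
#' @export
node_mean_fold_change <- function(assignment, fc) {
  stopifnot(inherits(assignment, "node_assignment"),
            inherits(fc, "fold_change_table"))
  node <- assignment$node[rownames(fc$fc)]
  n_nodes <- assignment$n_nodes
  out <- matrix(NA_real_, n_nodes, ncol(fc$fc),
                dimnames = list(seq_len(n_nodes), colnames(fc$fc)))
  sizes <- tabulate(node, nbins = n_nodes)
  sums <- rowsum(fc$fc, node)
  idx <- as.integer(rownames(sums))
  out[idx, ] <- sums / sizes[idx]
  attr(out, "cells") <- fc$cells
  out
}

#' Quantization error of a model on data
#' @param model a `som_model`.
#' @param features genes x features matrix.
#' @return mean Euclidean distance from each gene to its BMU codebook.
#' @export
quantization_error <- function(model, features) {
  mean(bmu_of(as.matrix(features), model$codebook)$dist)
}

#' Persist a SOM model as a TSV codebook plus JSON metadata sidecar
#' @param model a `som_model`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_som_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cb <- data.frame(node = seq_len(nrow(model$codebook)), model$codebook,
                   check.names = FALSE)
  utils::write.table(cb, file.path(dir, "codebook.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- model[c("rows", "cols", "seed", "epochs", "r0", "init",
                  "qe_initial", "qe_final", "qe_history")]
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a SOM model persisted by [write_som_model()]
#' @param dir directory holding `codebook.tsv` and `model.json`.
#' @return a `som_model`.
#' @export
read_som_model <- function(dir) {
  cb <- utils::read.delim(file.path(dir, "codebook.tsv"), check.names = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  codebook <- as.matrix(cb[, -1, drop = FALSE])
  rownames(codebook) <- cb$node
  structure(c(list(codebook = codebook,
                   coords = node_coordinates(meta$rows, meta$cols)),
              meta),
            class = "som_model")
}
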