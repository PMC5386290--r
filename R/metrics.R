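#' Transcription induction factor (TIF)
#'
#' TIF = (log2 fold change)^2, used to rank induction strength. Squaring
#' discards the sign, so by default only up-regulated entries (log2 FC > 0)
#' are reported; set `up_only = FALSE` to keep all entries with an `up` mask.
#'
#' @param fc a `fold_change_table`.
#' @param up_only restrict output to log2 FC > 0.
#' @return data frame: gene, condition, time, log2fc, tif, up.
#' @export
transcription_induction_factor <- function(fc, up_only = TRUE) {
  stopifnot(inherits(fc, "fold_change_table"))
  long <- data.frame(gene = rep(rownames(fc$fc), ncol(fc$fc)),
                     condition = rep(fc$cells$condition, each = nrow(fc$fc)),
                     time = rep(fc$cells$time, each = nrow(fc$fc)),
                     log2fc = as.vector(fc$fc),
                     stringsAsFactors = FALSE)
  long$tif <- long$log2fc^2
  long$up <- long$log2fc > 0
  if (up_only) long <- long[long$up, , drop = FALSE]
  rownames(long) <- NULL
  long
}

# Spearman rho with average-rank ties and a two-sided p-value from the
# t-approximation; exact permutation p available for small n without ties.
spearman_one <- function(x, y, exact = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (exact && n <= 10 && !anyDuplicated(x) && !anyDuplicated(y)) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else if (abs(rho) == 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Node-level transcriptome-secretome rank correlation
#'
#' Per (condition, time) cell, Spearman's rank correlation between the
#' per-node mean log2 transcription level and the per-node count of secreted
#' proteins detected in that cell. With `nodes = "secreting"` only nodes
#' containing at least one retained secreted protein (overall) enter the
#' correlation; `"all"` uses every non-empty node.
#'
#' @param node_means output of [node_mean_topography()].
#' @param overlay a `secretome_overlay`.
#' @param nodes `"all"` or `"secreting"`.
#' @param exact use the exact permutation p-value when n <= 10 and there are
#'   no ties (otherwise the t-approximation is used).
#' @return data frame: condition, time, rho, p, n_nodes.
#' @export
node_spearman <- function(node_means, overlay, nodes = c("all", "secreting"),
                          exact = FALSE) {
  nodes <- match.arg(nodes)
  stopifnot(inherits(overlay, "secretome_overlay"))
  cells <- attr(overlay$per_cell, "cells")
  keep <- if (nodes == "secreting") overlay$total > 0 else rep(TRUE, nrow(node_means))
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    lb <- cells$label[i]
    x <- node_means[keep, lb]
    y <- overlay$per_cell[keep, lb]
    r <- spearman_one(x, y, exact = exact)
    out[[i]] <- data.frame(condition = cells$condition[i], time = cells$time[i],
                           rho = r$rho, p = r$p, n_nodes = r$n,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Spatial coherence of gene blocks on the map
#'
#' Tests whether genes sharing a block label occupy nearby nodes: the
#' statistic is the mean (over blocks) of the mean pairwise Euclidean grid
#' distance between the nodes of the block members; the null distribution is
#' obtained by permuting block labels over genes. A small empirical p-value
#' indicates spatial co-clustering.
#'
#' @param assignment a `node_assignment`.
#' @param blocks named integer/character vector gene -> block label; genes
#'   with label 0/NA are background and ignored.
#' @param n_perm number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return list: `observed`, `null` (vector), `p` (one-sided empirical
#'   p-value, add-one corrected).
#' @export
block_coherence_test <- function(assignment, blocks, n_perm = 100, seed = 1L) {
  blocks <- blocks[names(assignment$node)]
  keep <- !is.na(blocks) & blocks != 0
  labs <- blocks[keep]
  coords <- node_coordinates(assignment$rows, assignment$cols)
  xy <- coords[assignment$node[names(labs)], , drop = FALSE]

  stat <- function(lab) {
    mean(vapply(split(seq_along(lab), lab), function(idx) {
      if (length(idx) < 2) return(NA_real_)
      mean(stats::dist(xy[idx, , drop = FALSE]))
    }, numeric(1)), na.rm = TRUE)
  }
  observed <- stat(labs)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) stat(sample(labs)), numeric(1))
  p <- (1 + sum(null <= observed)) / (n_perm + 1)
  list(observed = observed, null = null, p = p)
}

#' Write TIF and correlation tables as TSV
#' @param tif output of [transcription_induction_factor()].
#' @param path output TSV.
#' @export
write_tif <- function(tif, path) {
  utils::write.table(tif, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
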