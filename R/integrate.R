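#' Background-subtract the secretome against the control condition
#'
#' Proteins detected in any control-condition sample (at either time point)
#' are treated as background and removed globally. The result is the set of
#' proteins detected in at least one non-control sample and never in a
#' control sample.
#'
#' @param st a `secretome_table`.
#' @return character vector of retained protein ids.
#' @export
background_subtract_secretome <- function(st) {
  stopifnot(inherits(st, "secretome_table"))
  design <- st$design
  ctrl_samples <- design$sample[design$is_control]
  other_samples <- design$sample[!design$is_control]
  det <- st$detected
  in_ctrl <- rowSums(det[, intersect(ctrl_samples, colnames(det)), drop = FALSE]) > 0
  in_other <- rowSums(det[, intersect(other_samples, colnames(det)), drop = FALSE]) > 0
  rownames(det)[in_other & !in_ctrl]
}

#' Overlay secreted-protein detections onto SOM nodes
#'
#' Counts, per node, the distinct retained proteins whose gene maps to that
#' node. Per-(condition, time) counts use detection (spectral count >=
#' `detection_min`) in at least one replicate sample of the cell. Protein ids
#' absent from the clustered gene universe are dropped with a warning.
#'
#' @param st a `secretome_table`.
#' @param proteins retained protein ids (see
#'   [background_subtract_secretome()]).
#' @param assignment a `node_assignment`.
#' @return A `secretome_overlay`: list with `total` (per-node protein count),
#'   `per_cell` (nodes x cells matrix of per-cell detection counts),
#'   `proteins` (mapped protein ids), `node_of` (protein -> node).
#' @export
overlay_secretome_counts <- function(st, proteins, assignment) {
  stopifnot(inherits(st, "secretome_table"), inherits(assignment, "node_assignment"))
  unmatched <- setdiff(proteins, names(assignment$node))
  if (length(unmatched) > 0) {
    warning(length(unmatched), " protein id(s) not in the gene universe, dropped: ",
            paste(utils::head(unmatched, 5), collapse = ", "),
            if (length(unmatched) > 5) ", ...")
  }
  proteins <- intersect(proteins, names(assignment$node))
  n_nodes <- assignment$n_nodes
  node_of <- assignment$node[proteins]
  total <- tabulate(node_of, nbins = n_nodes)
  names(total) <- seq_len(n_nodes)

  cells <- design_cells(st$design)
  per_cell <- matrix(0L, n_nodes, nrow(cells),
                     dimnames = list(seq_len(n_nodes), cells$label))
  det <- st$detected[proteins, , drop = FALSE]
  for (i in seq_len(nrow(cells))) {
    s <- cell_samples(st$design, cells$condition[i], cells$time[i])
    s <- intersect(s, colnames(det))
    in_cell <- rowSums(det[, s, drop = FALSE]) > 0
    per_cell[, i] <- tabulate(node_of[in_cell], nbins = n_nodes)
  }
  attr(per_cell, "cells") <- cells
  structure(list(total = total, per_cell = per_cell,
                 proteins = proteins, node_of = node_of),
            class = "secretome_overlay")
}

#' @export
print.secretome_overlay <- function(x, ...) {
  cat(sprintf("secretome overlay: %d proteins over %d nodes (%d with >= 1 protein)\n",
              length(x$proteins), length(x$total), sum(x$total > 0)))
  invisible(x)
}

#' Select secretion-hotspot nodes
#'
#' Among nodes containing at least one secreted protein, selects those whose
#' protein count strictly exceeds the `percentile` quantile (linear
#' interpolation, R default type 7) of the nonzero-count distribution. If a
#' single node carries all nonzero counts it is returned directly.
#'
#' @param node_counts per-node protein counts (e.g. `overlay$total`).
#' @param percentile percentile of the nonzero counts, in (0, 100).
#' @return integer vector of hotspot node ids (possibly empty).
#' @export
select_secretion_hotspots <- function(node_counts, percentile = 90) {
  counts <- as.numeric(node_counts)
  ids <- seq_along(counts)
  nz <- counts > 0
  if (!any(nz)) {
    warning("no node contains a secreted protein; empty hotspot set")
    return(integer(0))
  }
  if (sum(nz) == 1) return(ids[nz])
  thr <- stats::quantile(counts[nz], percentile / 100, type = 7, names = FALSE)
  ids[nz & counts > thr]
}

#' Build the per-node summary table
#'
#' One row per node: grid coordinates, member-gene count, per-cell mean log2
#' level, per-cell mean log2 fold change, and secreted-protein counts.
#'
#' @param assignment a `node_assignment`.
#' @param node_means output of [node_mean_topography()].
#' @param node_fc output of [node_mean_fold_change()].
#' @param overlay optional `secretome_overlay`.
#' @return A `node_table` data frame with attribute `cells`.
#' @export
build_node_table <- function(assignment, node_means, node_fc, overlay = NULL) {
  n_nodes <- assignment$n_nodes
  coords <- node_coordinates(assignment$rows, assignment$cols)
  tab <- data.frame(node = seq_len(n_nodes),
                    row = coords[, "row"], col = coords[, "col"],
                    n_genes = as.integer(lengths(assignment$members)))
  mlev <- as.data.frame(node_means)
  names(mlev) <- paste0("mean_", colnames(node_means))
  mfc <- as.data.frame(node_fc)
  names(mfc) <- paste0("fc_", colnames(node_fc))
  tab <- cbind(tab, mlev, mfc)
  if (!is.null(overlay)) {
    tab$protein_total <- as.integer(overlay$total)
    pc <- as.data.frame(overlay$per_cell)
    names(pc) <- paste0("prot_", colnames(overlay$per_cell))
    tab <- cbind(tab, pc)
  }
  attr(tab, "cells") <- attr(node_means, "cells")
  class(tab) <- c("node_table", "data.frame")
  tab
}

#' Select transcription-responsive nodes per substrate and time point
#'
#' A node is responsive for a non-control (condition, time) cell when its
#' mean log2 level strictly exceeds the level threshold (the
#' `level_percentile` quantile of all finite node-mean levels, pooled over
#' every cell), OR its log2 fold change versus control strictly exceeds
#' `fc_threshold`. In `"node_mean"` mode the node-level fold change is the
#' mean of its member genes' fold changes; in `"any_gene"` mode a node
#' qualifies when any member gene exceeds `fc_threshold`.
#'
#' @param node_means output of [node_mean_topography()].
#' @param node_fc output of [node_mean_fold_change()].
#' @param level_percentile percentile defining the high-level threshold.
#' @param fc_threshold log2 fold-change threshold.
#' @param mode `"node_mean"` (default) or `"any_gene"`.
#' @param fc gene-level `fold_change_table` (required for `"any_gene"`).
#' @param assignment `node_assignment` (required for `"any_gene"`).
#' @return named list of integer node-id vectors, one per non-control cell
#'   (names `condition.time`); attribute `level_threshold` holds the realized
#'   cutoff.
#' @export
select_responsive_nodes <- function(node_means, node_fc,
                                    level_percentile = 90, fc_threshold = 2,
                                    mode = c("node_mean", "any_gene"),
                                    fc = NULL, assignment = NULL) {
  mode <- match.arg(mode)
  pooled <- node_means[is.finite(node_means)]
  level_thr <- stats::quantile(pooled, level_percentile / 100, type = 7,
                               names = FALSE)
  cells <- attr(node_fc, "cells")
  labels <- colnames(node_fc)
  if (mode == "any_gene") {
    if (is.null(fc) || is.null(assignment)) {
      stop("mode 'any_gene' requires the gene-level fold changes and the assignment")
    }
    node <- assignment$node[rownames(fc$fc)]
    gene_pass <- fc$fc > fc_threshold
    fc_pass <- rowsum(gene_pass + 0, node) > 0
    pass_fc <- matrix(FALSE, nrow(node_fc), ncol(node_fc),
                      dimnames = dimnames(node_fc))
    pass_fc[as.integer(rownames(fc_pass)), colnames(fc_pass)] <- fc_pass
  } else {
    pass_fc <- !is.na(node_fc) & node_fc > fc_threshold
  }
  out <- lapply(labels, function(lb) {
    lev <- node_means[, lb]
    sel <- (!is.na(lev) & lev > level_thr) | pass_fc[, lb]
    which(sel)
  })
  names(out) <- labels
  attr(out, "level_threshold") <- level_thr
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "cells") <- cells
  out
}

#' Classify substrate specificity of responsive nodes
#'
#' Given one responsive node set per non-control condition (at a fixed time
#' point), labels every node of the union: `shared_all` when present in all
#' sets, `shared_two:<a>+<b>` when in exactly two, `specific:<condition>`
#' when in exactly one.
#'
#' @param sets named list, condition -> integer node ids.
#' @return data frame with columns `node`, `label`.
#' @export
classify_node_specificity <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  conds <- names(sets)
  union_nodes <- sort(unique(unlist(sets)))
  if (length(union_nodes) == 0) {
    return(data.frame(node = integer(0), label = character(0)))
  }
  member <- vapply(sets, function(s) union_nodes %in% s,
                   logical(length(union_nodes)))
  member <- matrix(member, nrow = length(union_nodes),
                   dimnames = list(NULL, conds))
  k <- rowSums(member)
  label <- character(length(union_nodes))
  for (i in seq_along(union_nodes)) {
    inc <- conds[member[i, ]]
    label[i] <- if (k[i] == length(conds)) "shared_all"
      else if (k[i] == 2) paste0("shared_two:", paste(sort(inc), collapse = "+"))
      else if (k[i] == 1) paste0("specific:", inc)
      else "none"
  }
  data.frame(node = union_nodes, label = label, stringsAsFactors = FALSE)
}

#' Write the node table as TSV
#' @param tab a `node_table`.
#' @param path output TSV.
#' @export
write_node_table <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# node table: mean_<cell> = mean log2 level; fc_<cell> = ",
                    "mean member log2 fold change vs control; prot_<cell> = ",
                    "distinct secreted proteins detected in the cell"), con)
  utils::write.table(as.data.frame(tab), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
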