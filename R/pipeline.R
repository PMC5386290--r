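#' Run the full integration pipeline
#'
#' Convenience wrapper chaining the whole analysis: low-count filtering,
#' median-of-ratios normalization, per-time-point log2 fold changes, grid
#' planning, batch SOM training, gene-to-node assignment, node topographies,
#' secretome background subtraction and overlay, hotspot and responsive-node
#' selection, substrate-specificity labels, node-wise term enrichment, TIF,
#' and the node-level transcriptome-secretome rank correlation.
#'
#' @param em an `expression_matrix`.
#' @param catalog an `annotation_catalog` (or `NULL` to skip enrichment).
#' @param secretome a `secretome_table` (or `NULL` to skip the overlay).
#' @param min_total low-count filter threshold (genes kept when total
#'   count > `min_total`).
#' @param resolution genes per node for grid planning.
#' @param grid optional explicit `c(rows, cols)`, bypassing [plan_grid()].
#' @param epochs optional batch epoch count; default derives from
#'   [default_epochs()] via [batch_epochs()].
#' @param seed RNG seed for SOM initialization.
#' @param level_percentile,fc_threshold responsive-node criteria.
#' @param hotspot_percentile secretion-hotspot percentile.
#' @param min_count enrichment test-admission count.
#' @param alpha enrichment FDR threshold.
#' @param responsive_mode `"node_mean"` or `"any_gene"`.
#' @return A `secretomap_result` list with every intermediate product.
#' @export
run_pipeline <- function(em, catalog = NULL, secretome = NULL,
                         min_total = 5, resolution = 25, grid = NULL,
                         epochs = NULL, seed = 1L,
                         level_percentile = 90, fc_threshold = 2,
                         hotspot_percentile = 90, min_count = 3, alpha = 0.01,
                         responsive_mode = c("node_mean", "any_gene")) {
  responsive_mode <- match.arg(responsive_mode)
  em <- filter_low_count_genes(em, min_total = min_total)
  factors <- compute_size_factors(em)
  nm <- normalize_log2(em, factors)
  fc <- fold_change_vs_control(nm)

  if (is.null(grid)) grid <- plan_grid(nrow(em$counts), resolution = resolution)
  rows <- grid[1]; cols <- grid[2]
  if (is.null(epochs)) {
    epochs <- batch_epochs(default_epochs(rows, cols), nrow(em$counts))
  }
  model <- train_som(nm$log2, rows, cols, epochs = epochs, seed = seed)
  assignment <- assign_genes_to_nodes(model, nm$log2)
  node_means <- node_mean_topography(assignment, nm)
  node_fc <- node_mean_fold_change(assignment, fc)

  overlay <- NULL; hotspots <- NULL; retained <- NULL; correlation <- NULL
  if (!is.null(secretome)) {
    retained <- background_subtract_secretome(secretome)
    overlay <- overlay_secretome_counts(secretome, retained, assignment)
    hotspots <- select_secretion_hotspots(overlay$total,
                                          percentile = hotspot_percentile)
    correlation <- node_spearman(node_means, overlay)
  }

  responsive <- select_responsive_nodes(node_means, node_fc,
                                        level_percentile = level_percentile,
                                        fc_threshold = fc_threshold,
                                        mode = responsive_mode,
                                        fc = fc, assignment = assignment)
  cells <- fc$cells
  specificity <- lapply(unique(cells$time), function(t) {
    sets <- responsive[cells$label[cells$time == t]]
    names(sets) <- cells$condition[cells$time == t]
    classify_node_specificity(sets)
  })
  names(specificity) <- unique(cells$time)

  enrichment <- NULL; term_counts <- NULL
  if (!is.null(catalog)) {
    term_counts <- count_node_terms(catalog, assignment, min_count = min_count)
    enrichment <- enrich_nodes(term_counts, alpha = alpha)
  }

  node_table <- build_node_table(assignment, node_means, node_fc, overlay)
  tif <- transcription_induction_factor(fc)

  structure(list(expression = em, size_factors = factors, normalized = nm,
                 fold_changes = fc, model = model, assignment = assignment,
                 node_means = node_means, node_fc = node_fc,
                 retained_proteins = retained, overlay = overlay,
                 hotspots = hotspots, responsive = responsive,
                 specificity = specificity, term_counts = term_counts,
                 enrichment = enrichment, node_table = node_table,
                 correlation = correlation, tif = tif,
                 grid = c(rows = unname(rows), cols = unname(cols)),
                 epochs = epochs, seed = seed),
            class = "secretomap_result")
}

#' @export
print.secretomap_result <- function(x, ...) {
  cat(sprintf("secretomap result: %d genes on a %d x %d map (%d epochs, seed %s)\n",
              nrow(x$expression$counts), x$grid["rows"], x$grid["cols"],
              x$epochs, x$seed))
  if (!is.null(x$overlay)) {
    cat(sprintf("  secretome: %d retained proteins, %d hotspot node(s)\n",
                length(x$overlay$proteins), length(x$hotspots)))
  }
  if (!is.null(x$enrichment)) {
    cat(sprintf("  enrichment: %d tests, %d significant (node, term) pair(s)\n",
                nrow(x$enrichment), sum(x$enrichment$significant)))
  }
  invisible(x)
}

#' Export pipeline result tables and topography panels
#'
#' Writes the node table, enrichment table, fold changes, TIF, correlation
#' report, and per-(condition, time) topography heatmaps (mean level and
#' protein count) with fixed node layout.
#'
#' @param result a `secretomap_result`.
#' @param out_dir output directory.
#' @return invisible vector of written files.
#' @export
export_results <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_node_table(result$node_table, file.path(out_dir, "node_table.tsv"))
  write_fold_changes(result$fold_changes, file.path(out_dir, "fold_changes.tsv"))
  write_tif(result$tif, file.path(out_dir, "tif.tsv"))
  if (!is.null(result$enrichment)) {
    write_enrichment(result$enrichment, file.path(out_dir, "enrichment.tsv"))
  }
  if (!is.null(result$correlation)) {
    utils::write.table(result$correlation, file.path(out_dir, "correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rows <- result$grid["rows"]; cols <- result$grid["cols"]
  mats <- list()
  for (lb in colnames(result$node_means)) {
    v <- result$node_means[, lb]
    names(v) <- seq_along(v)
    mats[[paste0("mean_level_", lb)]] <-
      topography_matrix(v, rows, cols, kind = "mean_level")
  }
  if (!is.null(result$overlay)) {
    for (lb in colnames(result$overlay$per_cell)) {
      v <- result$overlay$per_cell[, lb]
      names(v) <- seq_along(v)
      mats[[paste0("protein_count_", lb)]] <-
        topography_matrix(v, rows, cols, kind = "protein_count")
    }
  }
  render_topographies(mats, file.path(out_dir, "topographies"))
  invisible(list.files(out_dir, recursive = TRUE, full.names = TRUE))
}
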