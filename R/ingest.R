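#' Read and validate a sample design sheet
#'
#' The design sheet describes the cultivation layout: one row per sequencing
#' library / MS sample with its substrate (condition), biological replicate
#' index, time point, and a flag marking the control substrate (e.g. maltose).
#'
#' @param path CSV file with columns `sample`, `condition`, `replicate`,
#'   `time`, `is_control` (logical or 0/1).
#' @return A `sample_design` data frame.
#' @export
read_sample_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_sample_design(df)
}

#' Construct a sample design from a data frame
#'
#' @param df data frame with columns `sample`, `condition`, `replicate`,
#'   `time`, `is_control`.
#' @return A validated `sample_design` object.
#' @export
as_sample_design <- function(df) {
  req <- c("sample", "condition", "replicate", "time", "is_control")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("design sheet is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, req]
  df$sample <- as.character(df$sample)
  df$condition <- as.character(df$condition)
  df$time <- as.character(df$time)
  df$is_control <- as.logical(df$is_control)
  if (anyDuplicated(df$sample)) {
    stop("duplicated sample id(s) in design: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  }
  ctrl <- unique(df$condition[df$is_control])
  if (length(ctrl) != 1) {
    stop("exactly one condition must be flagged as control; found: ",
         if (length(ctrl) == 0) "none" else paste(ctrl, collapse = ", "))
  }
  # replicate indices unique within each (condition, time) cell
  cell <- interaction(df$condition, df$time, drop = TRUE)
  for (cl in levels(cell)) {
    reps <- df$replicate[cell == cl]
    if (anyDuplicated(reps)) {
      stop("duplicated replicate index within cell ", cl)
    }
  }
  class(df) <- c("sample_design", "data.frame")
  df
}

#' @export
print.sample_design <- function(x, ...) {
  cat(sprintf("sample design: %d samples, %d conditions (control: %s), %d time points\n",
              nrow(x), length(unique(x$condition)), control_condition(x),
              length(unique(x$time))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Control condition of a design
#' @param design a `sample_design`.
#' @return The condition label flagged as control.
#' @export
control_condition <- function(design) {
  unique(design$condition[design$is_control])
}

#' Design cells (condition x time combinations)
#'
#' @param design a `sample_design`.
#' @param drop_control drop cells of the control condition.
#' @return data frame with columns `condition`, `time`, `label`, `is_control`.
#' @export
design_cells <- function(design, drop_control = FALSE) {
  cells <- unique(design[, c("condition", "time")])
  cells <- cells[order(cells$condition != control_condition(design),
                       cells$condition, cells$time), ]
  cells$label <- paste(cells$condition, cells$time, sep = ".")
  cells$is_control <- cells$condition == control_condition(design)
  if (drop_control) cells <- cells[!cells$is_control, ]
  rownames(cells) <- NULL
  cells
}

#' Samples belonging to one design cell
#' @param design a `sample_design`.
#' @param condition,time cell coordinates.
#' @return character vector of sample ids.
#' @export
cell_samples <- function(design, condition, time) {
  design$sample[design$condition == condition & design$time == time]
}

#' Number of gene-level observations in a study design
#'
#' Total observation count = genes x samples, i.e. genes x conditions x
#' replicates x time points for a balanced design.
#'
#' @param n_genes number of genes in the analysis universe.
#' @param design a `sample_design`.
#' @return integer observation count.
#' @export
count_observations <- function(n_genes, design) {
  as.integer(n_genes) * nrow(design)
}

#' Construct an expression matrix object
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param design a `sample_design` covering every column.
#' @return An `expression_matrix` object (list with `counts` and `design`).
#' @export
expression_matrix <- function(counts, design) {
  design <- as_sample_design(design)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicated gene id(s): ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicated sample id(s) in counts header")
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-integer or negative count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  miss <- setdiff(colnames(counts), design$sample)
  if (length(miss) > 0) {
    stop("sample(s) in counts missing from design: ", paste(miss, collapse = ", "))
  }
  miss2 <- setdiff(design$sample, colnames(counts))
  if (length(miss2) > 0) {
    stop("sample(s) in design missing from counts: ", paste(miss2, collapse = ", "))
  }
  # normalize column order to design order
  counts <- counts[, design$sample, drop = FALSE]
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, design = design), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples (control: %s)\n",
              nrow(x$counts), ncol(x$counts), control_condition(x$design)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$counts)

#' Read a raw count matrix with its design sheet
#'
#' Counts are read from a TSV with gene ids in the first column and one column
#' per sample (HTSeq-count style integers); the design CSV must list every
#' sample in the header and vice versa. Columns are reordered to design order.
#'
#' @param path counts TSV.
#' @param design_path design CSV (see [read_sample_design()]).
#' @return An `expression_matrix`.
#' @export
read_count_matrix <- function(path, design_path) {
  design <- read_sample_design(design_path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("counts TSV must have a gene id column plus sample columns")
  gene_ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    stop("counts TSV contains non-numeric entries")
  }
  rownames(m) <- gene_ids
  expression_matrix(m, design)
}

#' Write an expression matrix (and optionally its design) to disk
#' @param em an `expression_matrix`.
#' @param path counts TSV to write.
#' @param design_path optional design CSV to write.
#' @export
write_count_matrix <- function(em, path, design_path = NULL) {
  df <- data.frame(gene = rownames(em$counts), em$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(design_path)) {
    utils::write.csv(as.data.frame(em$design), design_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Drop genes with low total counts
#'
#' Retains exactly the genes whose total count summed over all samples is
#' strictly greater than `min_total` (default 5, i.e. "more than five reads").
#' Gene order is preserved. Idempotent.
#'
#' @param em an `expression_matrix`.
#' @param min_total keep genes with total count > `min_total`.
#' @return The filtered `expression_matrix`.
#' @export
filter_low_count_genes <- function(em, min_total = 5) {
  stopifnot(inherits(em, "expression_matrix"))
  keep <- rowSums(em$counts) > min_total
  if (!any(keep)) stop("no gene passes the low-count filter; nothing to cluster")
  em$counts <- em$counts[keep, , drop = FALSE]
  em
}

#' Read a gene -> term annotation catalog
#'
#' Three-column TSV (gene, namespace, term). Duplicate (gene, namespace, term)
#' triples are collapsed. Records whose namespace is outside `namespaces` are
#' kept under namespace `"other"` with a warning.
#'
#' @param path annotation TSV.
#' @param namespaces declared namespace set.
#' @return An `annotation_catalog` data frame (gene, namespace, term).
#' @export
read_annotation_catalog <- function(path,
                                    namespaces = c("CAZy", "GO", "KEGG", "KOG", "SignalP")) {
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                      col.names = c("gene", "namespace", "term"),
                      colClasses = "character"),
    error = function(e) data.frame(gene = character(), namespace = character(),
                                   term = character(), stringsAsFactors = FALSE))
  as_annotation_catalog(df, namespaces = namespaces)
}

#' Construct an annotation catalog from a data frame
#' @param df data frame with columns gene, namespace, term.
#' @param namespaces declared namespace set.
#' @return An `annotation_catalog`.
#' @export
as_annotation_catalog <- function(df,
                                  namespaces = c("CAZy", "GO", "KEGG", "KOG", "SignalP")) {
  if (nrow(df) == 0) {
    warning("annotation catalog is empty")
    df <- data.frame(gene = character(), namespace = character(),
                     term = character(), stringsAsFactors = FALSE)
  } else {
    names(df)[1:3] <- c("gene", "namespace", "term")
    unknown <- setdiff(unique(df$namespace), namespaces)
    if (length(unknown) > 0) {
      warning("unknown namespace(s) kept under 'other': ",
              paste(unknown, collapse = ", "))
      df$namespace[df$namespace %in% unknown] <- "other"
    }
    df <- unique(df[, c("gene", "namespace", "term")])
    rownames(df) <- NULL
  }
  structure(df, class = c("annotation_catalog", "data.frame"),
            namespaces = namespaces)
}

#' Per-namespace record totals of a catalog
#' @param catalog an `annotation_catalog`.
#' @return named integer vector of record counts by namespace.
#' @export
namespace_totals <- function(catalog) {
  if (nrow(catalog) == 0) return(integer(0))
  table_to_named_int(table(catalog$namespace))
}

table_to_named_int <- function(tb) {
  out <- as.integer(tb)
  names(out) <- names(tb)
  out
}

#' Write an annotation catalog as TSV
#' @param catalog an `annotation_catalog`.
#' @param path output TSV.
#' @export
write_annotation_catalog <- function(catalog, path) {
  utils::write.table(as.data.frame(catalog), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a secretome spectral-count table
#'
#' Wide table: a protein id column (first) plus one spectral-count column per
#' MS sample. Protein ids share the gene id namespace. A protein counts as
#' "detected" in a sample iff its spectral count is at least `detection_min`.
#'
#' @param path CSV or TSV (separator chosen from the file extension).
#' @param design a `sample_design`; every count column must be a design sample.
#' @param detection_min minimal spectral count for a detection call.
#' @return A `secretome_table` (list: `counts` matrix, `detected` logical
#'   matrix, `design`, `detection_min`).
#' @export
read_secretome_table <- function(path, design, detection_min = 1) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  secretome_table(m, design, detection_min = detection_min)
}

#' Construct a secretome table from a count matrix
#' @param counts spectral-count matrix, proteins x samples.
#' @param design a `sample_design`.
#' @param detection_min minimal spectral count for a detection call.
#' @return A `secretome_table`.
#' @export
secretome_table <- function(counts, design, detection_min = 1) {
  design <- as_sample_design(design)
  if (anyDuplicated(rownames(counts))) {
    stop("duplicated protein id(s): ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (any(!is.finite(counts) | counts < 0)) {
    stop("secretome spectral counts must be non-negative")
  }
  miss <- setdiff(colnames(counts), design$sample)
  if (length(miss) > 0) {
    stop("secretome sample(s) missing from design: ", paste(miss, collapse = ", "))
  }
  counts <- counts[, intersect(design$sample, colnames(counts)), drop = FALSE]
  structure(list(counts = counts,
                 detected = counts >= detection_min,
                 design = design,
                 detection_min = detection_min),
            class = "secretome_table")
}

#' @export
print.secretome_table <- function(x, ...) {
  cat(sprintf("secretome table: %d proteins x %d samples (detection_min = %d)\n",
              nrow(x$counts), ncol(x$counts), x$detection_min))
  invisible(x)
}

#' Write a secretome table as CSV
#' @param st a `secretome_table`.
#' @param path output CSV.
#' @export
write_secretome_table <- function(st, path) {
  df <- data.frame(protein = rownames(st$counts), st$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
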