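#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of the
#' ratio count / per-gene geometric mean, where reference genes are those with
#' no zero count in any sample. By default the factors are rescaled to
#' geometric mean 1 so they are comparable across runs.
#'
#' @param em an `expression_matrix` or a numeric count matrix.
#' @param rescale rescale factors to geometric mean 1.
#' @return named numeric vector of positive per-sample factors.
#' @export
compute_size_factors <- function(em, rescale = TRUE) {
  counts <- if (inherits(em, "expression_matrix")) em$counts else em
  counts <- as.matrix(counts)
  ref <- rowSums(counts == 0) == 0
  if (!any(ref)) {
    stop("no reference gene with all-positive counts; consider a pseudocount mode")
  }
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  factors <- apply(exp(logc - loggeo), 2, stats::median)
  if (rescale) factors <- factors / exp(mean(log(factors)))
  factors
}

#' Log2-normalized expression values
#'
#' value_ij = log2(count_ij / factor_j + 1). The +1 pseudocount keeps zeros at
#' zero and all values non-negative.
#'
#' @param em an `expression_matrix`.
#' @param factors per-sample size factors (default [compute_size_factors()]).
#' @return A `normalized_matrix` (list: `log2` matrix, `size_factors`,
#'   `design`).
#' @export
normalize_log2 <- function(em, factors = compute_size_factors(em)) {
  stopifnot(inherits(em, "expression_matrix"))
  if (any(!is.finite(factors) | factors <= 0)) stop("size factors must be positive")
  if (length(factors) != ncol(em$counts)) stop("one size factor per sample required")
  log2m <- log2(sweep(em$counts, 2, factors, "/") + 1)
  structure(list(log2 = log2m, size_factors = factors, design = em$design),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized matrix: %d genes x %d samples (log2, pseudocount 1)\n",
              nrow(x$log2), ncol(x$log2)))
  invisible(x)
}

# Mean of log2 values over the replicate samples of each design cell.
# Returns genes x cells matrix with cell labels as colnames.
cell_means <- function(nm, drop_control = FALSE) {
  cells <- design_cells(nm$design, drop_control = drop_control)
  out <- vapply(seq_len(nrow(cells)), function(i) {
    s <- cell_samples(nm$design, cells$condition[i], cells$time[i])
    rowMeans(nm$log2[, s, drop = FALSE])
  }, numeric(nrow(nm$log2)))
  out <- matrix(out, nrow = nrow(nm$log2),
                dimnames = list(rownames(nm$log2), cells$label))
  out
}

#' Per-time-point log2 fold changes against the control condition
#'
#' FC(g, c, t) = mean over replicates of the log2 value in (c, t) minus the
#' mean over replicates in (control, t).
#'
#' @param nm a `normalized_matrix`.
#' @return A `fold_change_table`: list with `fc` (genes x non-control cells
#'   matrix, columns labelled `condition.time`), `cells` (data frame), and
#'   `control` (control condition label).
#' @export
fold_change_vs_control <- function(nm) {
  stopifnot(inherits(nm, "normalized_matrix"))
  design <- nm$design
  ctrl <- control_condition(design)
  cells <- design_cells(design, drop_control = TRUE)
  times <- unique(cells$time)
  for (t in times) {
    if (length(cell_samples(design, ctrl, t)) == 0) {
      stop("no control samples at time point ", t)
    }
  }
  cm <- cell_means(nm)
  fc <- vapply(seq_len(nrow(cells)), function(i) {
    cm[, cells$label[i]] - cm[, paste(ctrl, cells$time[i], sep = ".")]
  }, numeric(nrow(nm$log2)))
  fc <- matrix(fc, nrow = nrow(nm$log2),
               dimnames = list(rownames(nm$log2), cells$label))
  structure(list(fc = fc, cells = cells, control = ctrl),
            class = "fold_change_table")
}

#' @export
print.fold_change_table <- function(x, ...) {
  cat(sprintf("fold changes: %d genes x %d contrasts vs control '%s'\n",
              nrow(x$fc), ncol(x$fc), x$control))
  invisible(x)
}

# Vectorized Welch two-sample test on the rows of two matrices.
# Returns two-sided p-values; rows where both groups are identical with zero
# variance get p = 1 (no evidence of difference).
welch_rows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # zero variance in both groups: identical means -> p 1, else p -> 0
  degen <- se2 == 0
  p[degen & m1 == m2] <- 1
  p[degen & m1 != m2] <- 0
  p
}

#' Replicate-level significance flags per contrast
#'
#' For every non-control (condition, time) cell, a Welch-type unequal-variance
#' test compares replicate log2 values against the control cell at the same
#' time point. P-values are adjusted across genes within each contrast by both
#' Benjamini-Hochberg and Bonferroni; a gene is flagged when both adjusted
#' values fall below `alpha`. This replicate-level test is a simple screen, not
#' a count-model fit; the flag metadata records the method.
#'
#' @param nm a `normalized_matrix`.
#' @param alpha significance level for both adjusted p-values.
#' @return data frame: gene, condition, time, p, p_bh, p_bonf, significant;
#'   attribute `method` = `"welch_log2"`.
#' @export
flag_significant_genes <- function(nm, alpha = 0.05) {
  stopifnot(inherits(nm, "normalized_matrix"))
  design <- nm$design
  ctrl <- control_condition(design)
  cells <- design_cells(design, drop_control = TRUE)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    s1 <- cell_samples(design, cells$condition[i], cells$time[i])
    s0 <- cell_samples(design, ctrl, cells$time[i])
    if (length(s1) < 2 || length(s0) < 2) {
      warning(sprintf("fewer than 2 replicates in contrast %s; flags undefined",
                      cells$label[i]))
      p <- rep(NA_real_, nrow(nm$log2))
    } else {
      p <- welch_rows(nm$log2[, s1, drop = FALSE], nm$log2[, s0, drop = FALSE])
    }
    p_bh <- stats::p.adjust(p, method = "BH")
    p_bonf <- stats::p.adjust(p, method = "bonferroni")
    out[[i]] <- data.frame(gene = rownames(nm$log2),
                           condition = cells$condition[i],
                           time = cells$time[i],
                           p = p, p_bh = p_bh, p_bonf = p_bonf,
                           significant = p_bh < alpha & p_bonf < alpha,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "method") <- "welch_log2"
  attr(res, "alpha") <- alpha
  res
}

#' Write normalization outputs as TSV
#' @param nm a `normalized_matrix`.
#' @param path output TSV for the log2 matrix.
#' @param factors_path optional TSV for the size factors.
#' @export
write_normalized_matrix <- function(nm, path, factors_path = NULL) {
  df <- data.frame(gene = rownames(nm$log2), nm$log2,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(factors_path)) {
    utils::write.table(data.frame(sample = names(nm$size_factors),
                                  size_factor = nm$size_factors),
                       factors_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a fold-change table (long format) as TSV
#' @param fc a `fold_change_table`.
#' @param path output TSV.
#' @param flags optional output of [flag_significant_genes()] to merge in.
#' @export
write_fold_changes <- function(fc, path, flags = NULL) {
  long <- data.frame(gene = rep(rownames(fc$fc), ncol(fc$fc)),
                     condition = rep(fc$cells$condition, each = nrow(fc$fc)),
                     time = rep(fc$cells$time, each = nrow(fc$fc)),
                     log2fc = as.vector(fc$fc),
                     stringsAsFactors = FALSE)
  if (!is.null(flags)) {
    long <- merge(long, flags[, c("gene", "condition", "time", "p_bh", "p_bonf",
                                  "significant")],
                  by = c("gene", "condition", "time"), all.x = TRUE, sort = FALSE)
  }
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
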