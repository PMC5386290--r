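# Shared fixture builders; everything is generated in code.

# Balanced design: first condition is the control.
toy_design <- function(conditions = c("ctrl", "a", "b"), n_rep = 2,
                       times = c("t1", "t2")) {
  g <- expand.grid(replicate = seq_len(n_rep), time = times,
                   condition = conditions, stringsAsFactors = FALSE)
  g$sample <- sprintf("%s_%s_r%d", g$condition, g$time, g$replicate)
  g$is_control <- g$condition == conditions[1]
  as_sample_design(g[, c("sample", "condition", "replicate", "time", "is_control")])
}

# Expression matrix whose log2-normalized values (size factors 1) equal `v`:
# counts = 2^v - 1.
em_from_log2 <- function(v, design) {
  counts <- round(2^v - 1)
  storage.mode(counts) <- "integer"
  rownames(counts) <- rownames(v)
  colnames(counts) <- design$sample
  expression_matrix(counts, design)
}

# normalized_matrix with prescribed log2 values (bypasses counts).
nm_from_log2 <- function(v, design) {
  structure(list(log2 = v,
                 size_factors = stats::setNames(rep(1, nrow(design)), design$sample),
                 design = design),
            class = "normalized_matrix")
}

# Hand-built node assignment.
make_assignment <- function(node, rows, cols) {
  members <- split(names(node), factor(node, levels = seq_len(rows * cols)))
  structure(list(node = node, members = members, n_nodes = rows * cols,
                 rows = rows, cols = cols),
            class = "node_assignment")
}

# Hand-built secretome overlay with a single synthetic cell per column.
make_overlay <- function(per_cell, total = rowSums(per_cell),
                         conditions = colnames(per_cell),
                         times = rep("t1", ncol(per_cell))) {
  cells <- data.frame(condition = conditions, time = times,
                      label = colnames(per_cell),
                      is_control = FALSE, stringsAsFactors = FALSE)
  attr(per_cell, "cells") <- cells
  structure(list(total = total, per_cell = per_cell,
                 proteins = character(0), node_of = integer(0)),
            class = "secretome_overlay")
}

# Independent oracle: hypergeometric upper tail by direct choose() summation.
hyper_tail_oracle <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Independent oracle: classical BH step-up adjusted p-values.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Default small dataset for pipeline-level tests.
small_dataset <- function(seed = 1, ...) {
  generate_dataset(n_genes = 600, n_blocks = 4, block_size = 30, seed = seed, ...)
}
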