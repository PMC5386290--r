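#' Count annotation-term occurrences per node
#'
#' One occurrence per annotated gene per term. For every (node, namespace,
#' term): `k` = occurrences in the node, `n` = all term occurrences in the
#' node within the namespace, `K` = genome-wide occurrences of the term,
#' `N` = all genome-wide occurrences in the namespace. Totals are computed on
#' the full counts; only terms with `k >= min_count` are admitted to testing
#' (`tested` flag). With `universe = "gene"` the counts are gene-based
#' instead: `n` = genes in the node, `N` = genes in the universe, `K` = genes
#' carrying the term.
#'
#' @param catalog an `annotation_catalog`.
#' @param assignment a `node_assignment` (defines the gene universe; catalog
#'   records for other genes are ignored).
#' @param min_count minimal in-node term count for test admission.
#' @param universe `"occurrence"` (default) or `"gene"`.
#' @return data frame: node, namespace, term, k, n, K, N, tested.
#' @export
count_node_terms <- function(catalog, assignment, min_count = 3,
                             universe = c("occurrence", "gene")) {
  universe <- match.arg(universe)
  stopifnot(inherits(assignment, "node_assignment"))
  cat_df <- as.data.frame(catalog)
  cat_df <- cat_df[cat_df$gene %in% names(assignment$node), , drop = FALSE]
  if (nrow(cat_df) == 0) {
    return(data.frame(node = integer(0), namespace = character(0),
                      term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), tested = logical(0)))
  }
  cat_df$node <- assignment$node[cat_df$gene]

  # per (node, namespace, term) occurrence counts
  key <- paste(cat_df$node, cat_df$namespace, cat_df$term, sep = "\r")
  tb <- table(key)
  parts <- do.call(rbind, strsplit(names(tb), "\r", fixed = TRUE))
  res <- data.frame(node = as.integer(parts[, 1]), namespace = parts[, 2],
                    term = parts[, 3], k = as.integer(tb),
                    stringsAsFactors = FALSE)

  if (universe == "occurrence") {
    n_tab <- table(paste(cat_df$node, cat_df$namespace, sep = "\r"))
    res$n <- as.integer(n_tab[paste(res$node, res$namespace, sep = "\r")])
    K_tab <- table(paste(cat_df$namespace, cat_df$term, sep = "\r"))
    res$K <- as.integer(K_tab[paste(res$namespace, res$term, sep = "\r")])
    N_tab <- table(cat_df$namespace)
    res$N <- as.integer(N_tab[res$namespace])
  } else {
    node_sizes <- lengths(assignment$members)
    res$n <- as.integer(node_sizes[res$node])
    K_tab <- table(paste(cat_df$namespace, cat_df$term, sep = "\r"))
    res$K <- as.integer(K_tab[paste(res$namespace, res$term, sep = "\r")])
    res$N <- length(assignment$node)
  }
  res$tested <- res$k >= min_count
  res <- res[order(res$node, res$namespace, res$term), ]
  rownames(res) <- NULL
  attr(res, "universe") <- universe
  attr(res, "min_count") <- min_count
  res
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X hypergeometric with population size `N`, `K` successes and
#' `n` draws (upper tail inclusive of `k`). Vectorized over its arguments.
#'
#' @param k observed successes in the draw.
#' @param n draw size.
#' @param K successes in the population.
#' @param N population size.
#' @return upper-tail probability in \[0, 1\].
#' @export
hypergeometric_upper_tail <- function(k, n, K, N) {
  m <- cbind(k, n, K, N)
  k <- m[, 1]; n <- m[, 2]; K <- m[, 3]; N <- m[, 4]
  feasible <- k >= 0 & n >= 0 & K >= 0 & N >= 0 &
    n <= N & K <= N & k <= pmin(n, K) & k >= pmax(0, n + K - N)
  if (any(!feasible)) {
    bad <- which(!feasible)[1]
    stop(sprintf("infeasible hypergeometric parameters: k=%g, n=%g, K=%g, N=%g",
                 k[bad], n[bad], K[bad], N[bad]))
  }
  unname(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Node-wise term over-representation with BH control
#'
#' Runs the hypergeometric upper-tail test for every admitted (node, term)
#' pair, adjusts the p-values by Benjamini-Hochberg jointly across all tests
#' (all nodes and namespaces pooled), and flags pairs with adjusted p below
#' `alpha`. Results are sorted by adjusted p.
#'
#' @param term_counts output of [count_node_terms()].
#' @param alpha FDR threshold for the significance flag.
#' @return An `enrichment_result` data frame: node, namespace, term, k, n, K,
#'   N, p_raw, p_bh, significant.
#' @export
enrich_nodes <- function(term_counts, alpha = 0.01) {
  tc <- term_counts[term_counts$tested, , drop = FALSE]
  if (nrow(tc) == 0) {
    warning("no (node, term) pair admitted to testing")
    out <- data.frame(node = integer(0), namespace = character(0),
                      term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p_raw = numeric(0),
                      p_bh = numeric(0), significant = logical(0))
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  tc$p_raw <- hypergeometric_upper_tail(tc$k, tc$n, tc$K, tc$N)
  tc$p_bh <- stats::p.adjust(tc$p_raw, method = "BH")
  tc$significant <- tc$p_bh < alpha
  tc <- tc[order(tc$p_bh, tc$p_raw, tc$node), ]
  tc$tested <- NULL
  rownames(tc) <- NULL
  attr(tc, "alpha") <- alpha
  class(tc) <- c("enrichment_result", "data.frame")
  tc
}

#' Write an enrichment result as TSV
#' @param res an `enrichment_result`.
#' @param path output TSV.
#' @export
write_enrichment <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
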