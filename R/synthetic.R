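#' Generate a synthetic multi-omics dataset with planted structure
#'
#' Emulates the statistical structure the pipeline assumes: a 4-condition x
#' 3-replicate x 2-time-point bulk RNA-seq design with negative-binomial
#' counts, planted blocks of co-regulated genes carrying a shared annotation
#' term, and secreted-protein detections whose probability increases with the
#' transcript level, plus control-condition background proteins.
#'
#' Per gene, baseline log2 mean ~ Normal(`baseline_mean`, `baseline_sd`);
#' per-sample scaling factor ~ LogNormal(0, 0.15); counts ~ NB with mean
#' `2^(baseline + shift) * factor` and variance `mu + dispersion * mu^2`.
#' Block genes share a log2 `effect_size` shift in a block-specific subset of
#' the non-control conditions (both time points). Each block's planted term
#' (namespace CAZy) covers `term_coverage` of its genes; background GO/KEGG
#' terms are scattered uniformly. Protein detection per gene and sample is
#' Bernoulli(plogis(`coupling` * (log2 level - threshold))) with the
#' threshold at the 80th percentile of baseline log2 means. Only secretable
#' genes can be detected: all block genes (induced secreted enzymes) plus a
#' `secretable_fraction` of the background genes, mimicking a signal-peptide
#' subset of the proteome; a disjoint set of background proteins is
#' additionally detected in control samples.
#'
#' @param n_genes number of genes.
#' @param n_blocks number of planted co-regulated blocks.
#' @param block_size genes per block.
#' @param conditions condition labels; the first is the control.
#' @param n_replicates replicates per (condition, time) cell.
#' @param times time point labels.
#' @param nb_dispersion NB dispersion alpha (variance mu + alpha mu^2); 0
#'   gives Poisson counts.
#' @param effect_size planted log2 shift of block genes.
#' @param coupling logistic slope linking log2 level to detection
#'   probability.
#' @param secretable_fraction fraction of non-block genes that are secretable
#'   (block genes always are).
#' @param baseline_mean,baseline_sd baseline log2 mean distribution
#'   (marginal over genes).
#' @param block_level_sd within-block standard deviation of the baseline; the
#'   between-block variance is reduced so the marginal stays
#'   Normal(`baseline_mean`, `baseline_sd`).
#' @param term_coverage fraction of block genes carrying the planted term.
#' @param n_background_terms number of background annotation terms.
#' @param background_rate probability that a gene carries a background term.
#' @param n_background_proteins control-condition background proteins.
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @return list with `expression` (an `expression_matrix`), `design`,
#'   `catalog` (an `annotation_catalog`), `secretome` (a `secretome_table`),
#'   and `truth` (a `synthetic_truth`).
#' @export
generate_dataset <- function(n_genes = 2000, n_blocks = 8, block_size = 40,
                             conditions = c("maltose", "aspen", "pine", "wheat_straw"),
                             n_replicates = 3, times = c("day3", "day7"),
                             nb_dispersion = 0.05, effect_size = 4, coupling = 2,
                             secretable_fraction = 0.15,
                             baseline_mean = 7, baseline_sd = 2,
                             block_level_sd = 0.8,
                             term_coverage = 0.6, n_background_terms = 30,
                             background_rate = 0.5, n_background_proteins = 25,
                             seed = 1L) {
  if (n_replicates < 2) stop("degenerate design: at least 2 replicates required")
  if (n_blocks * block_size > n_genes) stop("blocks exceed the gene universe")
  stopifnot(length(conditions) >= 2, length(times) >= 1)
  set.seed(seed)

  ctrl <- conditions[1]
  design <- expand.grid(replicate = seq_len(n_replicates), time = times,
                        condition = conditions, stringsAsFactors = FALSE)
  design <- design[, c("condition", "replicate", "time")]
  design$sample <- sprintf("%s_%s_r%d", design$condition, design$time, design$replicate)
  design$is_control <- design$condition == ctrl
  design <- as_sample_design(design[, c("sample", "condition", "replicate",
                                        "time", "is_control")])

  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  block <- integer(n_genes)
  names(block) <- gene_ids
  block[seq_len(n_blocks * block_size)] <- rep(seq_len(n_blocks), each = block_size)

  # baselines: marginally Normal(baseline_mean, baseline_sd); genes of a
  # co-regulated block share a level component (within-block sd
  # `block_level_sd`), since a coherent transcriptomic module is similar in
  # level as well as in profile shape
  baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  if (n_blocks > 0) {
    between_sd <- sqrt(max(baseline_sd^2 - block_level_sd^2, 0))
    block_mu <- stats::rnorm(n_blocks, baseline_mean, between_sd)
    in_b <- block > 0
    baseline[in_b] <- stats::rnorm(sum(in_b), block_mu[block[in_b]],
                                   block_level_sd)
  }
  names(baseline) <- gene_ids

  # block effect profiles: each block is induced on a random non-empty subset
  # of the non-control conditions, with block-specific time dynamics (early-
  # vs late-responding modules), so distinct blocks carry distinct profiles
  non_ctrl <- setdiff(conditions, ctrl)
  cells <- design_cells(design)
  effects <- matrix(0, n_blocks, nrow(cells),
                    dimnames = list(seq_len(n_blocks), cells$label))
  for (b in seq_len(n_blocks)) {
    k <- sample(seq_along(non_ctrl), 1)
    on <- sample(non_ctrl, k)
    amp <- stats::runif(length(times), 0.7, 1.3)
    for (ti in seq_along(times)) {
      effects[b, cells$condition %in% on & cells$time == times[ti]] <-
        effect_size * amp[ti]
    }
  }

  size_factors <- stats::rlnorm(nrow(design), 0, 0.15)
  names(size_factors) <- design$sample

  # true log2 mean per gene per sample
  cell_of_sample <- paste(design$condition, design$time, sep = ".")
  shift <- matrix(0, n_genes, nrow(design), dimnames = list(gene_ids, design$sample))
  in_block <- block > 0
  shift[in_block, ] <- effects[block[in_block], cell_of_sample]
  log2_level <- baseline + shift
  mu <- 2^log2_level * rep(size_factors, each = n_genes)

  counts <- if (nb_dispersion > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion)
  } else {
    stats::rpois(length(mu), mu)
  }
  counts <- matrix(counts, n_genes, nrow(design),
                   dimnames = list(gene_ids, design$sample))
  em <- expression_matrix(counts, design)

  # annotation catalog: planted CAZy-style terms + uniform background
  planted_terms <- sprintf("FAM%02d", seq_len(n_blocks))
  ann <- list()
  for (b in seq_len(n_blocks)) {
    members <- gene_ids[block == b]
    carriers <- sample(members, round(term_coverage * length(members)))
    ann[[b]] <- data.frame(gene = carriers, namespace = "CAZy",
                           term = planted_terms[b], stringsAsFactors = FALSE)
  }
  bg_ns <- sample(c("GO", "KEGG"), n_background_terms, replace = TRUE)
  bg_terms <- sprintf("%s:%04d", bg_ns, seq_len(n_background_terms))
  bg_genes <- gene_ids[stats::runif(n_genes) < background_rate]
  if (length(bg_genes) > 0) {
    pick <- sample.int(n_background_terms, length(bg_genes), replace = TRUE)
    ann[[n_blocks + 1]] <- data.frame(gene = bg_genes, namespace = bg_ns[pick],
                                      term = bg_terms[pick], stringsAsFactors = FALSE)
  }
  catalog <- suppressWarnings(as_annotation_catalog(do.call(rbind, ann)))

  # secretome: detection coupled to the realized log2 level, restricted to
  # the secretable subset of the proteome
  secretable <- in_block
  secretable[!in_block] <- stats::runif(sum(!in_block)) < secretable_fraction
  detect_threshold <- unname(stats::quantile(baseline, 0.8, type = 7))
  p_detect <- stats::plogis(coupling * (log2_level - detect_threshold))
  p_detect[!secretable, ] <- 0
  detected <- matrix(stats::runif(length(p_detect)) < p_detect,
                     n_genes, nrow(design), dimnames = dimnames(shift))
  bg_proteins <- sample(gene_ids[secretable & !in_block],
                        min(n_background_proteins, sum(secretable & !in_block)))
  ctrl_samples <- design$sample[design$is_control]
  detected[bg_proteins, ctrl_samples] <-
    detected[bg_proteins, ctrl_samples] |
    matrix(stats::runif(length(bg_proteins) * length(ctrl_samples)) < 0.9,
           length(bg_proteins), length(ctrl_samples))
  spectra <- matrix(0L, n_genes, nrow(design), dimnames = dimnames(shift))
  n_det <- sum(detected)
  spectra[detected] <- stats::rpois(n_det, 4) + 1L
  keep_prot <- rowSums(spectra) > 0
  st <- secretome_table(spectra[keep_prot, , drop = FALSE], design)

  truth <- structure(list(block = block, effects = effects,
                          planted_terms = planted_terms,
                          baseline = baseline,
                          size_factors = size_factors,
                          secretable = secretable,
                          coupling = coupling,
                          detect_threshold = detect_threshold,
                          background_proteins = bg_proteins,
                          params = list(n_genes = n_genes, n_blocks = n_blocks,
                                        block_size = block_size,
                                        nb_dispersion = nb_dispersion,
                                        effect_size = effect_size,
                                        term_coverage = term_coverage,
                                        baseline_mean = baseline_mean,
                                        baseline_sd = baseline_sd),
                          seed = seed),
                     class = "synthetic_truth")

  list(expression = em, design = design, catalog = catalog, secretome = st,
       truth = truth)
}

#' Expected flags implied by the planted truth
#'
#' Deterministically computes, from the truth object alone, which planted
#' blocks exceed the fold-change criterion in expectation (strict >; a block
#' whose shift equals the threshold is expected non-responsive), the expected
#' responsive gene set, and the expected enriched (block, term) pairs (blocks
#' with any nonzero effect, whose genes co-cluster).
#'
#' @param truth a `synthetic_truth`.
#' @param fc_threshold log2 fold-change threshold.
#' @return list: `responsive_blocks`, `responsive_genes`, `enriched` (data
#'   frame block, term).
#' @export
expected_flags <- function(truth, fc_threshold = 2) {
  stopifnot(inherits(truth, "synthetic_truth"))
  max_shift <- apply(truth$effects, 1, max)
  responsive_blocks <- which(max_shift > fc_threshold)
  responsive_genes <- names(truth$block)[truth$block %in% responsive_blocks]
  coherent <- which(apply(truth$effects, 1, function(e) any(e != 0)))
  list(responsive_blocks = unname(responsive_blocks),
       responsive_genes = responsive_genes,
       enriched = data.frame(block = unname(coherent),
                             term = truth$planted_terms[coherent],
                             stringsAsFactors = FALSE))
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' Writes counts TSV, design CSV, annotation TSV, secretome CSV, and the
#' truth object as JSON.
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             design = file.path(dir, "design.csv"),
             annotations = file.path(dir, "annotations.tsv"),
             secretome = file.path(dir, "secretome.csv"),
             truth = file.path(dir, "truth.json"))
  write_count_matrix(dataset$expression, paths["counts"], paths["design"])
  write_annotation_catalog(dataset$catalog, paths["annotations"])
  write_secretome_table(dataset$secretome, paths["secretome"])
  tr <- dataset$truth
  tr_json <- list(block = as.list(tr$block), effects = tr$effects,
                  planted_terms = tr$planted_terms,
                  coupling = tr$coupling, detect_threshold = tr$detect_threshold,
                  background_proteins = tr$background_proteins,
                  params = tr$params, seed = tr$seed)
  jsonlite::write_json(tr_json, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
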