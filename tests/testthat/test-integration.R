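test_that("control-detected proteins are removed globally as background", {
  design <- toy_design(conditions = c("maltose", "pine"), n_rep = 1,
                       times = c("day3", "day7"))
  # columns: maltose.day3, maltose.day7, pine.day3, pine.day7
  counts <- matrix(as.integer(c(2, 0, 5, 0,    # maltose day3 + pine day3
                                0, 0, 0, 3,    # pine day7 only
                                3, 0, 0, 0,    # maltose day3 only
                                0, 0, 0, 0)),  # never detected
                   nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("p", 1:4), design$sample))
  st <- secretome_table(counts, design)
  kept <- background_subtract_secretome(st)
  expect_identical(kept, "p2")
  expect_false("p1" %in% kept)  # detected on the control at day 3 -> excluded
  expect_false("p4" %in% kept)

  # commutes with sample reordering
  st2 <- secretome_table(counts[, c(3, 1, 4, 2)], design)
  expect_identical(sort(background_subtract_secretome(st2)), sort(kept))
})

test_that("secretome overlay counts distinct proteins per node and conserves totals", {
  design <- toy_design(conditions = c("maltose", "pine"), n_rep = 2, times = "day3")
  genes <- sprintf("g%02d", 1:12)
  node <- stats::setNames(rep(c(7L, 2L, 5L), each = 4), genes)
  asg <- make_assignment(node, 3, 3)

  counts <- matrix(0L, 12, nrow(design), dimnames = list(genes, design$sample))
  counts[, "pine_day3_r1"] <- 2L  # all detected on pine only
  st <- secretome_table(counts, design)

  ov <- overlay_secretome_counts(st, c("g01", "g02"), asg)
  expect_equal(unname(ov$total[7]), 2)
  expect_equal(sum(ov$total), 2)

  expect_warning(
    ov2 <- overlay_secretome_counts(st, c("g01", "notagene"), asg),
    "notagene")
  expect_equal(sum(ov2$total), 1)

  # ten proteins over three nodes: per-node counts sum to ten
  ten <- genes[c(1:4, 5:8, 9, 10)]
  ov3 <- overlay_secretome_counts(st, ten, asg)
  expect_equal(sum(ov3$total), 10)
  expect_equal(unname(ov3$total[c(2, 5, 7)]), c(4, 2, 4))
  # per-cell counts: all detections are in pine.day3
  expect_equal(sum(ov3$per_cell[, "pine.day3"]), 10)
  expect_equal(sum(ov3$per_cell[, "maltose.day3"]), 0)
})

test_that("secretion hotspots exceed the percentile of nonzero counts", {
  counts <- c(rep(1, 9), 10, rep(0, 5))
  expect_identical(select_secretion_hotspots(counts), 10L)  # threshold 1.9

  expect_length(select_secretion_hotspots(rep(3, 8)), 0)    # all equal

  single <- c(0, 0, 4, 0)
  expect_identical(select_secretion_hotspots(single), 3L)   # single nonzero

  expect_warning(out <- select_secretion_hotspots(rep(0, 6)), "no node")
  expect_length(out, 0)
})

test_that("responsive nodes pass the level-percentile OR fold-change criterion", {
  cells <- data.frame(condition = "pine", time = "day3", label = "pine.day3",
                      is_control = FALSE, stringsAsFactors = FALSE)
  means <- matrix(c(1:9, 10), ncol = 1, dimnames = list(1:10, "pine.day3"))
  attr(means, "cells") <- cells
  fc <- matrix(0, 10, 1, dimnames = list(1:10, "pine.day3"))
  fc[3, 1] <- 2.5   # qualifies on fold change despite low level
  fc[5, 1] <- 1.0
  attr(fc, "cells") <- cells

  sel <- select_responsive_nodes(means, fc)  # level threshold = q90 = 9.1
  expect_equal(attr(sel, "level_threshold"), 9.1)
  expect_true(10 %in% sel$pine.day3)    # mean 10 > 9.1
  expect_true(3 %in% sel$pine.day3)     # FC 2.5 > 2
  expect_false(5 %in% sel$pine.day3)    # mean 5, FC 1.0
  expect_false(9 %in% sel$pine.day3)    # mean 9.0 < 9.1

  # boundary is strict: FC exactly at the threshold does not qualify
  fc[3, 1] <- 2
  sel2 <- select_responsive_nodes(means, fc)
  expect_false(3 %in% sel2$pine.day3)
})

test_that("raising thresholds never grows a responsive set", {
  set.seed(17)
  cells <- data.frame(condition = c("a", "b"), time = "t1",
                      label = c("a.t1", "b.t1"), is_control = FALSE,
                      stringsAsFactors = FALSE)
  means <- matrix(stats::rnorm(60, 8, 2), 30, 2,
                  dimnames = list(1:30, cells$label))
  fc <- matrix(stats::rnorm(60, 0, 2), 30, 2,
               dimnames = list(1:30, cells$label))
  attr(means, "cells") <- cells
  attr(fc, "cells") <- cells
  for (case in 1:3) {
    lp <- sample(c(50, 70, 90), 2)
    ft <- sort(stats::runif(2, 0, 4))
    loose <- select_responsive_nodes(means, fc, level_percentile = min(lp),
                                     fc_threshold = ft[1])
    tight <- select_responsive_nodes(means, fc, level_percentile = max(lp),
                                     fc_threshold = ft[2])
    for (lb in cells$label) {
      expect_true(all(tight[[lb]] %in% loose[[lb]]))
    }
  }
})

test_that("any-gene responsive mode lifts gene-level passes to nodes", {
  design <- toy_design(conditions = c("ctrl", "a"), n_rep = 2, times = "t1")
  v <- rbind(g1 = c(5, 5, 5.5, 5.5),   # FC 0.5
             g2 = c(5, 5, 8.0, 8.0),   # FC 3 -> its node passes in any_gene mode
             g3 = c(5, 5, 5.0, 5.0))
  colnames(v) <- design$sample
  nm <- nm_from_log2(v, design)
  fc <- fold_change_vs_control(nm)
  asg <- make_assignment(c(g1 = 1L, g2 = 1L, g3 = 4L), 2, 2)
  means <- node_mean_topography(asg, nm)
  nfc <- node_mean_fold_change(asg, fc)
  expect_equal(unname(nfc[1, "a.t1"]), 1.75)  # mean of 0.5 and 3

  node_mode <- select_responsive_nodes(means, nfc, level_percentile = 100)
  any_mode <- select_responsive_nodes(means, nfc, level_percentile = 100,
                                      mode = "any_gene", fc = fc, assignment = asg)
  expect_false(1 %in% node_mode$a.t1)  # node mean 1.75 < 2
  expect_true(1 %in% any_mode$a.t1)    # g2 alone exceeds 2
})

test_that("specificity labels follow set membership and partition the union", {
  sets <- list(A = c(1, 2), P = c(2, 3), W = 2)
  lab <- classify_node_specificity(sets)
  expect_equal(lab$label[lab$node == 2], "shared_all")
  expect_equal(lab$label[lab$node == 1], "specific:A")
  expect_equal(lab$label[lab$node == 3], "specific:P")

  disjoint <- classify_node_specificity(list(A = 1, P = 2, W = 3))
  expect_true(all(grepl("^specific:", disjoint$label)))

  two <- classify_node_specificity(list(A = c(1, 5), P = c(5, 9), W = 7))
  expect_equal(two$label[two$node == 5], "shared_two:A+P")

  # random fixture against a brute-force membership-count oracle
  set.seed(23)
  rsets <- list(A = sample(20, 8), P = sample(20, 8), W = sample(20, 8))
  lab2 <- classify_node_specificity(rsets)
  for (i in seq_len(nrow(lab2))) {
    n <- lab2$node[i]
    inc <- names(rsets)[vapply(rsets, function(s) n %in% s, logical(1))]
    want <- if (length(inc) == 3) "shared_all"
      else if (length(inc) == 2) paste0("shared_two:", paste(sort(inc), collapse = "+"))
      else paste0("specific:", inc)
    expect_equal(lab2$label[i], want)
  }
  # labels cover exactly the union, once each
  expect_identical(lab2$node, sort(unique(unlist(rsets))))
  expect_false(anyDuplicated(lab2$node) > 0)
})
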