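states4 <- c("active", "repressive", "bivalent", "none")

long_states <- function(from, to, ids = sprintf("g%03d", seq_along(from))) {
  tibble::tibble(
    gene_id = rep(ids, 2),
    condition = rep(c("LLC-NR", "LLC-R"), each = length(from)),
    state = factor(c(from, to), levels = states4)
  )
}

test_that("identical state vectors give a diagonal table with unit proportions", {
  st <- long_states(rep(states4, 5), rep(states4, 5))
  tt <- transition_table(st)
  expect_equal(sum(tt$counts), 20)
  expect_equal(diag(tt$counts), stats::setNames(rep(5L, 4), states4))
  expect_equal(diag(tt$proportions), stats::setNames(rep(1, 4), states4))
})

test_that("row proportions condition on the starting state; empty rows are NA", {
  st <- long_states(rep("bivalent", 10), rep(c("active", "bivalent"), c(8, 2)))
  tt <- transition_table(st)
  expect_equal(unname(tt$proportions["bivalent", c("active", "bivalent")]),
               c(0.8, 0.2))
  expect_true(all(is.na(tt$proportions["active", ])))
  # counts conserve the universe; non-empty rows sum to 1
  expect_equal(sum(tt$counts), 10)
  expect_equal(unname(rowSums(tt$proportions)["bivalent"]), 1)
})

test_that("mismatched gene universes are rejected with the missing ids", {
  st <- long_states(rep("active", 3), rep("active", 3))
  st <- st[-5, ]  # drop one gene from the R condition
  expect_error(transition_table(st), "g002")
})

test_that("stratification by CpG class tabulates each class separately", {
  st <- long_states(rep(c("bivalent", "none"), 10), rep("active", 20))
  cls <- tibble::tibble(gene_id = sprintf("g%03d", 1:20),
                        cpg_class = rep(c("HCP", "LCP"), each = 10))
  tt <- transition_table(st, cpg_class = cls)
  expect_named(tt$by_class, c("HCP", "LCP"))
  expect_equal(sum(tt$by_class$HCP$counts), 10)
  td <- tidy(tt)
  expect_setequal(unique(td$cpg_class), c("all", "HCP", "LCP"))
})

test_that("Spearman correlation handles monotone, reversed and degenerate input", {
  expect_equal(spearman_occupancy_expression(1:10, (1:10)^3), 1)
  expect_equal(spearman_occupancy_expression(1:10, rev(1:10)), -1)
  expect_equal(spearman_occupancy_expression(c(1, 2, 3), c(3, 1, 2)), -0.5)
  expect_warning(r <- spearman_occupancy_expression(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
  expect_error(spearman_occupancy_expression(1:2, 1:2), "at least 3")
})

test_that("pooled-variance t test matches t.test and guards degenerate input", {
  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(0.3, 0.9, 1.4)
  got <- compare_expression_groups(a, b)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)

  same <- compare_expression_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  flat <- compare_expression_groups(c(1, 1), c(1, 1))
  expect_equal(flat$t, 0)
  expect_equal(flat$p_value, 1)
  expect_equal(flat$significance, "n.s.")

  sep <- compare_expression_groups(c(0, 0), c(1, 1))
  expect_true(is.infinite(sep$t))
  expect_equal(sep$significance, "**")
})

test_that("fold changes use the pseudocount on both sides", {
  occ <- tidyr::crossing(gene_id = c("g1", "g2"),
                         mark = c("H3K4me3", "H3K9ac", "H3K27me3"),
                         condition = c("LLC-NR", "LLC-R"))
  occ$occupancy <- 0
  occ$occupancy[occ$gene_id == "g1" & occ$mark == "H3K4me3"] <-
    c(3, 12)[match(occ$condition[occ$gene_id == "g1" & occ$mark == "H3K4me3"],
                   c("LLC-NR", "LLC-R"))]
  expr <- tibble::tibble(gene_id = c("g1", "g2"), fpkm_NR = c(2, 0),
                         fpkm_R = c(2, 0))
  fc <- fold_change_table(occ, expr, c("g1", "g2"), pseudocount = 1)
  expect_equal(fc$log2fc_H3K4me3[fc$gene_id == "g1"], log2(13 / 4))
  expect_equal(fc$log2fc_H3K9ac, c(0, 0))       # 0 -> 0 with pseudocount
  expect_equal(fc$log2fc_expression, c(0, 0))   # unchanged expression
  expect_warning(fold_change_table(occ, expr, c("g1", "gX")), "gX")
})

test_that("transition gene categories apply the literal state rules", {
  st <- long_states(
    c("repressive", "active", "repressive", "none", "bivalent", "repressive"),
    c("active",     "active", "none",       "active", "active",  "repressive"))
  tt <- transition_table(st)
  lists <- select_transition_genes(tt)
  expect_setequal(lists$gain_active, c("g001", "g004", "g005"))
  expect_setequal(lists$lose_repressive, c("g001", "g003"))
  # active -> active is in neither list
  expect_false("g002" %in% unlist(lists))
  expect_error(select_transition_genes(tt, list(bad = list(from = "zippy",
                                                           to = "active"))),
               "unknown state")
})

test_that("gene-body profiles are strand-oriented, normalized and group-averaged", {
  genes <- tibble::tibble(gene_id = c("gp", "gm"), chrom = "chr1",
                          start = c(0L, 0L), end = c(1000L, 1000L),
                          strand = c("+", "-"))
  # tags only in the 3' half of the plus-strand gene (coordinates 500-999)
  tags <- tibble::tibble(chrom = "chr1", midpoint = seq(500L, 999L, by = 5L))
  prof <- genebody_coverage_profile(tags, genes, n_bins = 10,
                                    library_size = 1e6)
  pp <- prof$mean_coverage[prof$group == "all"]
  # both genes see the same tags; orientation mirrors them for the minus gene
  p_plus <- genebody_coverage_profile(tags, genes[1, ], n_bins = 10,
                                      library_size = 1e6)
  p_minus <- genebody_coverage_profile(tags, genes[2, ], n_bins = 10,
                                       library_size = 1e6)
  expect_equal(p_minus$mean_coverage, rev(p_plus$mean_coverage))
  expect_equal(sum(p_plus$mean_coverage), 100 * 1e6 / 1e6)

  none <- genebody_coverage_profile(tags[0, ], genes, n_bins = 10,
                                    library_size = 1e6)
  expect_equal(none$mean_coverage, rep(0, 10))
  expect_warning(
    genebody_coverage_profile(tags, dplyr::mutate(genes, end = start + 5L),
                              n_bins = 10),
    "skipped")
})
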