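test_that("simulation_config validates probabilities and expression ordering", {
  expect_s3_class(tiny_config(), "simulation_config")
  expect_error(simulation_config(cpg_class_probs = c(0.5, 0.2, 0.2)))
  expect_error(simulation_config(
    expression_means = c(active = 1, bivalent = 2, repressive = 1, none = 1)),
    "ordered")
  tm <- diag(4); tm[1, 1] <- 0.5
  expect_error(simulation_config(transition_matrix = tm))
})

test_that("gene packing is rejected when chromosomes are too short", {
  expect_error(
    simulate_genome(simulation_config(n_genes = 100, n_chroms = 1,
                                      chrom_length = 3e5),
                    simulate_truth(simulation_config(n_genes = 100, n_chroms = 1,
                                                     chrom_length = 3e5))),
    "at least")
})

test_that("planted CpG classes are recovered by the promoter classifier", {
  cfg <- tiny_config(seed = 101, n_genes = 120)
  truth <- simulate_truth(cfg)
  layout <- simulate_genome(cfg, truth)
  pw <- promoter_windows(layout$genes, layout$chrom_sizes)
  called <- classify_promoters(pw, layout$genome)
  agree <- mean(as.character(called$cpg_class) == as.character(truth$cpg_class))
  expect_gte(agree, 0.95)
  # planted HCPs must never be missed: the embedded segment clears both rules
  hcp <- truth$cpg_class == "HCP"
  expect_true(all(called$cpg_class[hcp] == "HCP"))
})

test_that("same seed reproduces every emitted file byte for byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  tiny_bundle(d1, seed = 9)
  tiny_bundle(d2, seed = 9)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = paste("md5 of", f))
  }
  d3 <- withr::local_tempdir()
  tiny_bundle(d3, seed = 10)
  expect_false(unname(tools::md5sum(file.path(d1, "genome.fa"))) ==
                 unname(tools::md5sum(file.path(d3, "genome.fa"))))
})

test_that("promoter tag counts scale linearly with the planted enrichment", {
  cfg1 <- simulation_config(seed = 301, n_genes = 600, n_chroms = 2,
                            chrom_length = 1.5e6)
  e2 <- cfg1$enrichment; e2["H3K4me3", ] <- 2 * e2["H3K4me3", ]
  cfg2 <- simulation_config(seed = 301, n_genes = 600, n_chroms = 2,
                            chrom_length = 1.5e6, enrichment = e2)
  truth <- simulate_truth(cfg1)
  truth <- simulate_expression(cfg1, truth)
  layout <- simulate_genome(cfg1, truth)
  pw <- promoter_windows(layout$genes, layout$chrom_sizes)
  mean_k4_active <- function(cfg) {
    tags <- simulate_tags(cfg, truth, layout)[["H3K4me3:LLC-NR"]]
    cnt <- promoter_raw_count(tags, pw)$count
    c(active = mean(cnt[truth$state_NR == "active"]),
      none = mean(cnt[truth$state_NR == "none"]))
  }
  m1 <- mean_k4_active(cfg1)
  m2 <- mean_k4_active(cfg2)
  # planted part (above background, estimated from 'none' promoters) doubles
  expect_equal(unname((m2["active"] - m2["none"]) /
                        (m1["active"] - m1["none"])), 2, tolerance = 0.1)
  # 'none' promoters carry background only
  expect_equal(unname(m1["none"]), cfg1$background_rate * 1500, tolerance = 0.2)
})

test_that("expression medians honour the planted state ordering", {
  cfg <- simulation_config(seed = 17, n_genes = 2000, expression_sd = 0.5)
  truth <- simulate_expression(cfg, simulate_truth(cfg))
  med <- tapply(truth$fpkm_NR, truth$state_NR, median)
  expect_true(med["active"] > med["bivalent"] &&
                med["bivalent"] > med["repressive"])
  # noise-free medians sit exactly at exp(mean)
  cfg0 <- simulation_config(seed = 17, n_genes = 400, n_chroms = 2,
                            chrom_length = 1e6, expression_sd = 0)
  truth0 <- simulate_expression(cfg0, simulate_truth(cfg0))
  for (s in levels(truth0$state_NR)) {
    sel <- truth0$state_NR == s
    if (any(sel)) {
      expect_equal(unique(truth0$fpkm_NR[sel]),
                   exp(unname(cfg0$expression_means[s])), tolerance = 1e-12)
    }
  }
})

test_that("H3K36me3 tags track expression over gene bodies", {
  cfg <- simulation_config(seed = 23, n_genes = 400, n_chroms = 2,
                           chrom_length = 1e6)
  truth <- simulate_expression(cfg, simulate_truth(cfg))
  layout <- simulate_genome(cfg, truth)
  tags <- simulate_tags(cfg, truth, layout)[["H3K36me3:LLC-NR"]]
  body <- promoter_raw_count(
    tags, tibble::tibble(gene_id = layout$genes$gene_id,
                         chrom = layout$genes$chrom,
                         start = layout$genes$start,
                         end = layout$genes$end))$count
  # body counts correlate with planted FPKM beyond background
  expect_gt(cor(body, truth$fpkm_NR, method = "spearman"), 0.5)
})
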