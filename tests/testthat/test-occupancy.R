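prom <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                       start = 9000L, end = 10500L)

test_that("raw promoter counts use half-open interval semantics", {
  mk <- function(mids) tibble::tibble(chrom = "chr1", midpoint = mids)
  expect_equal(promoter_raw_count(mk(integer(0)), prom)$count, 0)
  # midpoint exactly at the end coordinate is excluded
  expect_equal(promoter_raw_count(mk(10500L), prom)$count, 0)
  expect_equal(promoter_raw_count(mk(c(9000L, 9500L, 10499L)), prom)$count, 3)
  expect_equal(promoter_raw_count(mk(8999L), prom)$count, 0)
})

test_that("peak sums add occupancies of peaks whose centers fall inside", {
  mk <- function(centers, occ) tibble::tibble(chrom = "chr1",
                                              center = centers, occupancy = occ)
  expect_equal(promoter_peak_sum(mk(integer(0), numeric(0)), prom)$peak_sum, 0)
  expect_equal(promoter_peak_sum(mk(c(9100L, 10400L), c(5, 3)), prom)$peak_sum, 8)
  expect_equal(promoter_peak_sum(mk(10500L, 7), prom)$peak_sum, 0)
})

test_that("per-million normalization scales by library size and rejects zero libraries", {
  occ <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        mark = "H3K4me3", condition = "LLC-NR",
                        occupancy = c(50, 0, 30))
  ls1 <- tibble::tibble(mark = "H3K4me3", condition = "LLC-NR",
                        library_size = 1e6)
  expect_equal(normalize_occupancy(occ, ls1)$occupancy, c(50, 0, 30))
  ls2 <- dplyr::mutate(ls1, library_size = 2e6)
  expect_equal(normalize_occupancy(occ, ls2)$occupancy, c(25, 0, 15))
  ls0 <- dplyr::mutate(ls1, library_size = 0)
  expect_error(normalize_occupancy(occ, ls0), "positive")
})

test_that("thresholds are arithmetic means over the full promoter universe", {
  occ <- tibble::tibble(
    gene_id = rep(c("g1", "g2", "g3"), 2),
    mark = rep(c("H3K4me3", "H3K27me3"), each = 3),
    condition = "LLC-NR",
    occupancy = c(0, 0, 6, 3, 3, 3)
  )
  thr <- compute_thresholds(occ)
  expect_equal(thr$M[thr$mark == "H3K4me3"], 2)
  expect_equal(thr$M[thr$mark == "H3K27me3"], 3)
  expect_error(compute_thresholds(occ[0, ]), "empty")

  pooled <- compute_thresholds(
    dplyr::mutate(occ, condition = rep(c("LLC-NR", "LLC-R"), 3)), mode = "pooled")
  expect_equal(unique(pooled$M[pooled$mark == "H3K4me3"]),
               mean(c(0, 0, 6)[rep(c(TRUE), 3)]))
})

test_that("state rules follow the quoted boundary semantics", {
  M <- 1
  # active needs a high active mark AND K27 strictly below its mean
  expect_equal(as.character(classify_state(2 * M, 0, 0.5 * M, M, M, M)), "active")
  # K27 exactly at its mean flips active to bivalent
  expect_equal(as.character(classify_state(2 * M, 0, M, M, M, M)), "bivalent")
  expect_equal(as.character(classify_state(0.5 * M, 0.5 * M, 1.5 * M, M, M, M)),
               "repressive")
  expect_equal(as.character(classify_state(0.5 * M, 0.5 * M, 0.5 * M, M, M, M)),
               "none")
  # H3K9ac alone can carry the active call
  expect_equal(as.character(classify_state(0, 2 * M, 0, M, M, M)), "active")
  expect_error(classify_state(-1, 0, 0, M, M, M), "negative")
})

test_that("the four states partition all occupancy triples", {
  set.seed(31)
  k4 <- rexp(500); k9 <- rexp(500); k27 <- rexp(500)
  st <- classify_state(k4, k9, k27, 1, 1, 1)
  expect_false(anyNA(st))
  expect_true(all(st %in% c("active", "repressive", "bivalent", "none")))
})

test_that("state calls are invariant to rescaling a mark column with its threshold", {
  set.seed(37)
  k4 <- rexp(300); k9 <- rexp(300); k27 <- rexp(300)
  base <- classify_state(k4, k9, k27, 1, 1, 1)
  scaled <- classify_state(7 * k4, k9, 0.1 * k27, 7, 1, 0.1)
  expect_equal(base, scaled)
})

test_that("classify_states pivots a long occupancy table and applies thresholds per condition", {
  occ <- tidyr::crossing(
    gene_id = c("g1", "g2", "g3", "g4"),
    mark = c("H3K4me3", "H3K9ac", "H3K27me3"),
    condition = "LLC-NR"
  )
  occ$occupancy <- 1
  occ$occupancy[occ$gene_id == "g1" & occ$mark == "H3K4me3"] <- 10
  occ$occupancy[occ$gene_id == "g2" & occ$mark == "H3K27me3"] <- 10
  st <- classify_states(occ)
  expect_equal(as.character(st$state[st$gene_id == "g1"]), "active")
  expect_equal(as.character(st$state[st$gene_id == "g2"]), "repressive")
  expect_equal(as.character(st$state[st$gene_id == "g3"]), "none")
})
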