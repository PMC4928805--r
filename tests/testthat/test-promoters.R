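test_that("promoter windows follow strand orientation and clip to the chromosome", {
  expect_equal(extract_promoter(10000, "+", 1e6),
               tibble::tibble(start = 9000, end = 10500))
  expect_equal(extract_promoter(10000, "-", 1e6),
               tibble::tibble(start = 9500, end = 11000))
  # clipped degenerate case near the chromosome start
  expect_equal(extract_promoter(400, "+", 1e6),
               tibble::tibble(start = 0, end = 900))
  expect_error(extract_promoter(-1, "+", 1e6), "outside")
  expect_error(extract_promoter(1e6, "+", 1e6), "outside")
})

test_that("reversing strand mirrors the window around the TSS exactly", {
  set.seed(1)
  tss <- sample(2000:99000, 50)
  plus <- extract_promoter(tss, "+", 1e5)
  minus <- extract_promoter(tss, "-", 1e5)
  # distances of the two edges from the TSS swap under strand flip
  expect_equal(tss - minus$start, plus$end - tss)
  expect_equal(minus$end - tss, tss - plus$start)
})

test_that("promoter_windows uses start/end as TSS by strand", {
  genes <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                          start = c(5000, 8000), end = c(7000, 9500),
                          strand = c("+", "-"))
  pw <- promoter_windows(genes, c(chr1 = 2e4))
  expect_equal(pw$tss, c(5000, 9500))
  expect_equal(pw$start, c(4000, 9000))
  expect_equal(pw$end, c(5500, 10500))
  expect_error(promoter_windows(genes, c(chr2 = 2e4)), "absent")
})

test_that("gc_content counts G+C over non-N bases", {
  expect_equal(gc_content(c("GCGC", "ATAT", "ACGT")), c(1, 0, 0.5))
  expect_equal(gc_content("ACGTNN"), 0.5)
  expect_equal(gc_content("NNNN"), 0)
  expect_error(gc_content(""), "empty")
})

test_that("cpg_oe implements (N_CpG * L) / (N_C * N_G)", {
  expect_equal(cpg_oe("CGCG"), 2)          # 2 * 4 / (2 * 2)
  expect_equal(cpg_oe("ATAT"), 0)          # no C or G
  expect_equal(cpg_oe(strrep("CG", 250)), 2)
  expect_equal(cpg_oe("ACGT"), 1 * 4 / (1 * 1))
  expect_error(cpg_oe(""), "empty")
})

test_that("windowed GC and O/E are invariant under shifts of a homogeneous repeat", {
  seq <- strrep("ACGG", 400)  # 1600 bp
  st <- promstates:::.cpg_window_stats(seq, window = 500, step = 1)
  # windows at offsets that are multiples of the repeat period are identical
  periodic <- st[st$offset %% 4 == 0, ]
  expect_true(diff(range(periodic$gc)) == 0)
  expect_true(diff(range(periodic$oe)) == 0)
})

test_that("constructed sequences classify as HCP / LCP / ICP", {
  expect_equal(classify_cpg_promoter(strrep("CG", 250)), "HCP")
  expect_equal(classify_cpg_promoter(strrep("AT", 750)), "LCP")
  # GC = 0.5 < 0.55 blocks HCP; O/E = 4 >= 0.4 blocks LCP
  expect_equal(classify_cpg_promoter(strrep("CGAT", 125)), "ICP")
})

test_that("every sequence gets exactly one class and sub-window sequences fall back to the whole sequence", {
  set.seed(7)
  seqs <- replicate(40, random_dna(sample(50:1500, 1)))
  cls <- classify_cpg_promoter(seqs)
  expect_true(all(cls %in% c("HCP", "ICP", "LCP")))
  # a 100-bp CpG-rich fragment is judged as one whole-sequence window
  expect_equal(classify_cpg_promoter(strrep("CG", 50)), "HCP")
})

test_that("sliding-window classifier agrees with the exhaustive regex oracle", {
  set.seed(11)
  seqs <- c(
    replicate(25, random_dna(1500)),
    replicate(10, random_dna(1500, c(A = .2, C = .3, G = .3, T = .2))),
    replicate(5, random_dna(700))
  )
  expect_equal(classify_cpg_promoter(seqs),
               vapply(seqs, oracle_cpg_class, "", USE.NAMES = FALSE))
})

test_that("classify_promoters extracts sequence context and reports window maxima", {
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste0(random_dna(1000), strrep("CG", 300), random_dna(1000))
  ))
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                          start = 1500, end = 2200, strand = "+")
  pw <- promoter_windows(genes, c(chr1 = 2600))
  out <- classify_promoters(pw, genome, keep_sequence = TRUE)
  expect_equal(as.character(out$cpg_class), "HCP")
  expect_equal(nchar(out$sequence), out$end - out$start)
  expect_gte(out$oe_max_window, 0.6)
  expect_gte(out$gc_max_window, 0.55)
})
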