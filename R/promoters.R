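#' Promoter interval around a transcription start site
#'
#' Computes the promoter window for one or more TSSs: by default 1 kb upstream
#' to 0.5 kb downstream of the TSS, oriented by strand and clipped to the
#' chromosome. Coordinates are 0-based half-open (BED convention); for a
#' minus-strand gene the window is the mirror image of the plus-strand one.
#'
#' @param tss Integer vector of TSS positions (0-based).
#' @param strand Character vector of `"+"` or `"-"`, recycled to `length(tss)`.
#' @param chrom_len Chromosome length(s) in bp, recycled.
#' @param upstream,downstream Window extent in bp on the 5' and 3' side of the
#'   TSS (defaults 1000 and 500).
#' @return A tibble with columns `start`, `end` (0-based half-open).
#' @examples
#' extract_promoter(10000, "+", 1e6)          # [9000, 10500)
#' extract_promoter(10000, "-", 1e6)          # [9500, 11000)
#' @export
extract_promoter <- function(tss, strand, chrom_len,
                             upstream = 1000L, downstream = 500L) {
  stopifnot(upstream >= 0, downstream >= 0)
  n <- length(tss)
  strand <- rep_len(as.character(strand), n)
  chrom_len <- rep_len(chrom_len, n)
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  bad <- tss < 0 | tss >= chrom_len
  if (any(bad)) {
    stop("TSS outside chromosome at index ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }
  up <- ifelse(strand == "+", upstream, downstream)
  dn <- ifelse(strand == "+", downstream, upstream)
  tibble::tibble(
    start = pmax(0, tss - up),
    end   = pmin(chrom_len, tss + dn)
  )
}

#' Promoter windows for a gene table
#'
#' Builds one promoter per gene from a gene-model table. The TSS of a
#' plus-strand gene is its `start`, that of a minus-strand gene its `end`
#' (0-based half-open annotation).
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (one row per gene; see [read_genes()]).
#' @param chrom_sizes Named integer vector or tibble (`chrom`, `length`) of
#'   chromosome lengths.
#' @inheritParams extract_promoter
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
promoter_windows <- function(genes, chrom_sizes,
                             upstream = 1000L, downstream = 500L) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  if (is.data.frame(chrom_sizes)) {
    sizes <- stats::setNames(chrom_sizes$length, chrom_sizes$chrom)
  } else {
    sizes <- chrom_sizes
  }
  missing_chrom <- setdiff(unique(genes$chrom), names(sizes))
  if (length(missing_chrom)) {
    stop("chromosomes absent from chrom_sizes: ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)
  }
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  win <- extract_promoter(tss, genes$strand, sizes[genes$chrom],
                          upstream = upstream, downstream = downstream)
  tibble::tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = win$start,
    end = win$end,
    strand = genes$strand,
    tss = tss
  )
}

#' GC content of nucleotide sequences
#'
#' Fraction (G + C) among non-N bases; 0 when every base is N.
#'
#' @param sequence Character vector of sequences over A/C/G/T/N.
#' @return Numeric vector in \[0, 1\].
#' @export
gc_content <- function(sequence) {
  .check_seq(sequence)
  x <- Biostrings::DNAStringSet(toupper(sequence))
  f <- Biostrings::letterFrequency(x, c("C", "G", "N"))
  non_n <- Biostrings::width(x) - f[, "N"]
  unname(ifelse(non_n == 0, 0, (f[, "C"] + f[, "G"]) / non_n))
}

#' CpG observed/expected ratio
#'
#' Gardiner-Garden & Frommer convention: `(N_CpG * L) / (N_C * N_G)` where
#' `N_CpG` counts (overlapping) CG dinucleotides, `L` is the sequence length
#' and `N_C`, `N_G` the base counts. Returns 0 when there is no C or no G.
#'
#' @inheritParams gc_content
#' @return Numeric vector, `>= 0`.
#' @export
cpg_oe <- function(sequence) {
  .check_seq(sequence)
  x <- Biostrings::DNAStringSet(toupper(sequence))
  f <- Biostrings::letterFrequency(x, c("C", "G"))
  ncg <- Biostrings::vcountPattern("CG", x)
  L <- Biostrings::width(x)
  unname(ifelse(f[, "C"] == 0 | f[, "G"] == 0, 0,
                ncg * L / (f[, "C"] * f[, "G"])))
}

.check_seq <- function(sequence) {
  if (length(sequence) == 0 || any(!nzchar(sequence)) || any(is.na(sequence))) {
    stop("empty sequence", call. = FALSE)
  }
  invisible(TRUE)
}

# Sliding-window GC and CpG O/E statistics via cumulative sums (exact, O(L)).
# Windows with > 50% N are flagged `skipped`. Sequences shorter than `window`
# are evaluated as a single whole-sequence window.
.cpg_window_stats <- function(sequence, window = 500L, step = 1L) {
  .check_seq(sequence)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(chars)
  w <- min(window, L)
  is_c <- chars == "C"
  is_g <- chars == "G"
  is_n <- chars == "N"
  cg <- if (L > 1) is_c[-L] & is_g[-1] else logical(0)
  cum_c <- c(0, cumsum(is_c))
  cum_g <- c(0, cumsum(is_g))
  cum_n <- c(0, cumsum(is_n))
  cum_cg <- c(0, cumsum(cg))
  starts <- seq.int(1L, L - w + 1L, by = step)
  if (starts[length(starts)] != L - w + 1L) starts <- c(starts, L - w + 1L)
  ends <- starts + w - 1L
  n_c <- cum_c[ends + 1L] - cum_c[starts]
  n_g <- cum_g[ends + 1L] - cum_g[starts]
  n_n <- cum_n[ends + 1L] - cum_n[starts]
  # CG dinucleotide starts fully inside [start, end]
  n_cg <- cum_cg[ends] - cum_cg[starts]
  non_n <- w - n_n
  tibble::tibble(
    offset = starts - 1L,
    gc = ifelse(non_n == 0, 0, (n_c + n_g) / non_n),
    oe = ifelse(n_c == 0 | n_g == 0, 0, n_cg * w / (n_c * n_g)),
    skipped = n_n / w > 0.5
  )
}

#' Classify a promoter sequence by CpG content
#'
#' Scans all `window`-bp subintervals (default 500 bp, step 1 bp). A promoter
#' is **HCP** if any window has GC content >= `gc_min` and CpG O/E >=
#' `oe_hcp`; **LCP** if no window reaches CpG O/E >= `oe_lcp`; **ICP**
#' otherwise. Sequences shorter than `window` are judged on the whole
#' sequence; windows that are more than half N are ignored.
#'
#' @inheritParams gc_content
#' @param window Window width in bp (default 500).
#' @param step Scan step in bp; 1 is exact, larger values are an approximation.
#' @param gc_min GC threshold for the HCP rule (default 0.55).
#' @param oe_hcp CpG O/E threshold for the HCP rule (default 0.6).
#' @param oe_lcp CpG O/E threshold excluding LCP (default 0.4).
#' @return Character vector of `"HCP"`, `"ICP"` or `"LCP"`.
#' @examples
#' classify_cpg_promoter(strrep("CG", 250))  # HCP
#' classify_cpg_promoter(strrep("AT", 750))  # LCP
#' @export
classify_cpg_promoter <- function(sequence, window = 500L, step = 1L,
                                  gc_min = 0.55, oe_hcp = 0.6, oe_lcp = 0.4) {
  stopifnot(window >= 1, window <= 1500, step >= 1)
  vapply(sequence, function(s) {
    st <- .cpg_window_stats(s, window = window, step = step)
    ok <- st[!st$skipped, , drop = FALSE]
    if (nrow(ok) == 0) ok <- st  # all-N-heavy promoter: fall back to all windows
    if (any(ok$gc >= gc_min & ok$oe >= oe_hcp)) return("HCP")
    if (!any(ok$oe >= oe_lcp)) return("LCP")
    "ICP"
  }, character(1), USE.NAMES = FALSE)
}

#' Extract promoter sequences and assign CpG classes
#'
#' Adds the extracted sequence, per-promoter maxima of the windowed GC and
#' CpG O/E statistics, and the CpG class to a promoter table.
#'
#' @param promoters Tibble from [promoter_windows()].
#' @param genome A named `DNAStringSet` (or path to a FASTA file).
#' @inheritParams classify_cpg_promoter
#' @param keep_sequence Keep the extracted sequence column (default FALSE).
#' @return The promoter tibble with columns `gc_max_window`, `oe_max_window`,
#'   `cpg_class` (and `sequence` if requested) appended.
#' @export
classify_promoters <- function(promoters, genome, window = 500L, step = 1L,
                               gc_min = 0.55, oe_hcp = 0.6, oe_lcp = 0.4,
                               keep_sequence = FALSE) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  seqs <- as.character(Biostrings::subseq(
    genome[promoters$chrom],
    start = promoters$start + 1L, end = promoters$end
  ))
  stats_list <- lapply(seqs, .cpg_window_stats, window = window, step = step)
  cls <- vapply(stats_list, function(st) {
    ok <- st[!st$skipped, , drop = FALSE]
    if (nrow(ok) == 0) ok <- st
    if (any(ok$gc >= gc_min & ok$oe >= oe_hcp)) "HCP"
    else if (!any(ok$oe >= oe_lcp)) "LCP"
    else "ICP"
  }, character(1))
  out <- dplyr::mutate(
    promoters,
    gc_max_window = vapply(stats_list, function(st) max(st$gc[!st$skipped], 0), numeric(1)),
    oe_max_window = vapply(stats_list, function(st) max(st$oe[!st$skipped], 0), numeric(1)),
    cpg_class = factor(cls, levels = .PS_CLASSES)
  )
  if (keep_sequence) out$sequence <- unname(seqs)
  out
}
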