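# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests. The oracles deliberately use different machinery
# (regex counting, O(n^2) greedy loop) from the package implementation.

random_dna <- function(n, probs = c(A = 0.26, C = 0.24, G = 0.24, T = 0.26)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# exhaustive all-window CpG-class scan using regex-based counting
oracle_cpg_class <- function(seq, window = 500L,
                             gc_min = 0.55, oe_hcp = 0.6, oe_lcp = 0.4) {
  L <- nchar(seq)
  w <- min(window, L)
  starts <- seq_len(L - w + 1L)
  ws <- substring(seq, starts, starts + w - 1L)
  cnt <- function(p) nchar(ws) - nchar(gsub(p, "", ws, fixed = TRUE))
  n_c <- cnt("C"); n_g <- cnt("G"); n_n <- cnt("N")
  n_cg <- cnt("CG") / 2
  non_n <- w - n_n
  gc <- ifelse(non_n == 0, 0, (n_c + n_g) / non_n)
  oe <- ifelse(n_c == 0 | n_g == 0, 0, n_cg * w / (n_c * n_g))
  keep <- n_n / w <= 0.5
  if (!any(keep)) keep <- rep(TRUE, length(ws))
  gc <- gc[keep]; oe <- oe[keep]
  if (any(gc >= gc_min & oe >= oe_hcp)) return("HCP")
  if (!any(oe >= oe_lcp)) return("LCP")
  "ICP"
}

# literal iterative greedy: global max, suppress < exclusion, repeat (O(n^2))
oracle_call_peaks <- function(signal, exclusion = 147L, min_occupancy = 2) {
  sig <- signal
  centers <- integer(0)
  repeat {
    i <- which.max(sig)
    if (length(i) == 0 || sig[i] < min_occupancy) break
    centers <- c(centers, i)
    lo <- max(1L, i - exclusion + 1L)
    hi <- min(length(sig), i + exclusion - 1L)
    sig[lo:hi] <- -Inf
  }
  centers <- sort(centers)
  tibble::tibble(center = centers - 1L, occupancy = signal[centers])
}

# spiky random signal with ties (rounding) to stress tie-breaking
random_signal <- function(n, n_spikes = 25) {
  sig <- numeric(n)
  at <- sample.int(n, n_spikes, replace = TRUE)
  for (p in at) {
    w <- sample(10:60, 1)
    lo <- max(1, p - w); hi <- min(n, p + w)
    sig[lo:hi] <- sig[lo:hi] + runif(1, 0.5, 6) *
      exp(-((lo:hi) - p)^2 / (2 * (w / 3)^2))
  }
  round(sig, 1)
}

# small but complete synthetic experiment for integration tests
tiny_config <- function(seed = 5, n_genes = 80, chrom_length = NULL, ...) {
  chrom_length <- chrom_length %||% (ceiling(n_genes / 2) * 5000)
  simulation_config(seed = seed, n_genes = n_genes, n_chroms = 2,
                    chrom_length = chrom_length, ...)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

tiny_bundle <- function(dir, seed = 5, ...) {
  simulate_chipseq_experiment(tiny_config(seed = seed, ...), dir)
}
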