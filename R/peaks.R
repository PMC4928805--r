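#' Gaussian-smoothed tag signal over a region
#'
#' Each tag contributes a unit-height Gaussian kernel
#' `exp(-(x - t)^2 / (2 sigma^2))`, truncated at 5 sigma, so the smoothed
#' signal reads as an effective count of overlapping tags. Tags up to 5 sigma
#' outside the region still contribute at its edges.
#'
#' @param positions Integer vector of tag midpoints (bp).
#' @param sigma Kernel standard deviation in bp (default 20).
#' @param region_start,region_end Region bounds, 0-based half-open.
#' @return Numeric vector of length `region_end - region_start`; element `i`
#'   is the signal at base `region_start + i - 1`.
#' @export
smooth_signal <- function(positions, sigma = 20, region_start, region_end) {
  stopifnot(sigma > 0)
  if (region_end <= region_start) stop("empty region", call. = FALSE)
  n <- region_end - region_start
  pad <- as.integer(ceiling(5 * sigma))
  keep <- positions >= region_start - pad & positions < region_end + pad
  pos <- positions[keep]
  if (length(pos) == 0) return(numeric(n))
  counts <- tabulate(pos - (region_start - pad) + 1L, nbins = n + 2L * pad)
  kernel <- exp(-(seq(-pad, pad))^2 / (2 * sigma^2))
  full <- .fft_convolve(counts, kernel)
  # index of region_start in the full convolution: counts index 1 is
  # region_start - pad; kernel centre is at offset pad + 1
  out <- full[(2L * pad + 1L):(2L * pad + n)]
  pmax(out, 0)
}

# linear convolution via FFT, padded with nextn() for a smooth transform size
.fft_convolve <- function(x, k) {
  n_out <- length(x) + length(k) - 1L
  m <- stats::nextn(n_out)
  fx <- stats::fft(c(x, numeric(m - length(x))))
  fk <- stats::fft(c(k, numeric(m - length(k))))
  Re(stats::fft(fx * fk, inverse = TRUE))[seq_len(n_out)] / m
}

#' Greedy fixed-width peak calling on a smoothed signal
#'
#' Iteratively selects the global maximum of the signal as a peak (leftmost
#' wins ties), suppresses all positions closer than `exclusion` bp to an
#' accepted peak, and repeats until no position reaches `min_occupancy`.
#' Accepted peaks are therefore pairwise at least `exclusion` bp apart
#' (center to center), the fixed nucleosomal footprint of the model.
#'
#' @param signal Numeric vector (per-base smoothed signal).
#' @param exclusion Minimum center-to-center distance between peaks in bp
#'   (default 147, nucleosomal DNA width).
#' @param min_occupancy Minimum smoothed height for a peak (default 2).
#' @param offset Genomic coordinate of `signal[1]` (default 0).
#' @return Tibble `center`, `occupancy`, sorted by center. `occupancy` is the
#'   smoothed height at the center before any suppression.
#' @export
call_peaks <- function(signal, exclusion = 147L, min_occupancy = 2,
                       offset = 0L) {
  stopifnot(exclusion > 0)
  n <- length(signal)
  if (n == 0) {
    return(tibble::tibble(center = integer(0), occupancy = numeric(0)))
  }
  cand <- which(signal >= min_occupancy)
  if (length(cand) == 0) {
    return(tibble::tibble(center = integer(0), occupancy = numeric(0)))
  }
  # visiting candidates by decreasing height (position breaks ties) and
  # skipping suppressed ones reproduces the iterative greedy selection
  ord <- cand[order(-signal[cand], cand)]
  suppressed <- logical(n)
  centers <- integer(0)
  for (i in ord) {
    if (suppressed[i]) next
    centers <- c(centers, i)
    lo <- max(1L, i - exclusion + 1L)
    hi <- min(n, i + exclusion - 1L)
    suppressed[lo:hi] <- TRUE
  }
  centers <- sort(centers)
  tibble::tibble(center = offset + centers - 1L,
                 occupancy = signal[centers])
}

#' Genome-wide peak calling from a tag table
#'
#' Smooths and calls peaks per chromosome. When the tag table carries strand
#' information, single-end tags are first shifted to estimated fragment
#' midpoints (see [estimate_fragment_shift()]).
#'
#' @param tags Tibble with columns `chrom`, `midpoint` and optionally
#'   `strand` (see [read_tags()]).
#' @param chrom_sizes Named vector or tibble (`chrom`, `length`).
#' @inheritParams smooth_signal
#' @inheritParams call_peaks
#' @param shift Fragment-shift handling: `"auto"` estimates the shift from
#'   strand cross-correlation when strands are present, a number applies that
#'   shift, `0` disables shifting.
#' @return Tibble `chrom`, `center`, `occupancy`.
#' @export
call_peaks_genome <- function(tags, chrom_sizes, sigma = 20, exclusion = 147L,
                              min_occupancy = 2, shift = "auto") {
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- stats::setNames(chrom_sizes$length, chrom_sizes$chrom)
  }
  mids <- tags$midpoint
  if (identical(shift, "auto")) {
    shift <- 0
    if ("strand" %in% names(tags) && any(tags$strand %in% c("+", "-"))) {
      shift <- estimate_fragment_shift(mids[tags$strand == "+"],
                                       mids[tags$strand == "-"])
    }
  }
  if (shift != 0 && "strand" %in% names(tags)) {
    mids <- mids + ifelse(tags$strand == "+", shift,
                          ifelse(tags$strand == "-", -shift, 0))
  }
  by_chrom <- split(mids, tags$chrom)
  res <- purrr::imap(by_chrom, function(pos, chrom) {
    len <- chrom_sizes[[chrom]]
    sig <- smooth_signal(pos, sigma = sigma, region_start = 0L,
                         region_end = as.integer(len))
    pk <- call_peaks(sig, exclusion = exclusion,
                     min_occupancy = min_occupancy, offset = 0L)
    pk$chrom <- chrom
    pk
  })
  dplyr::bind_rows(res)[, c("chrom", "center", "occupancy")]
}

#' Estimate the single-end fragment shift from strand cross-correlation
#'
#' Returns half the lag in \[0, 500\] bp at which the plus- and minus-strand
#' tag position histograms correlate most strongly: shifting both strands by
#' this amount moves tags to approximate fragment midpoints. Returns 0 (with
#' a warning) when either strand is empty.
#'
#' @param plus_positions,minus_positions Tag positions per strand.
#' @param max_lag Largest fragment length considered (default 500 bp).
#' @param max_tags Subsample cap per strand for the correlation (default 5e4).
#' @return Shift in bp (half the best lag).
#' @export
estimate_fragment_shift <- function(plus_positions, minus_positions,
                                    max_lag = 500L, max_tags = 50000L) {
  if (length(plus_positions) == 0 || length(minus_positions) == 0) {
    warning("one strand has no tags; fragment shift set to 0")
    return(0L)
  }
  if (length(plus_positions) > max_tags) {
    plus_positions <- plus_positions[as.integer(
      seq(1L, length(plus_positions), length.out = max_tags))]
  }
  p <- sort(as.numeric(plus_positions))
  m <- sort(as.numeric(minus_positions))
  # exact 1-bp histogram cross-correlation restricted to lags [0, max_lag]:
  # tabulate all pairwise minus-plus differences in range
  lo <- findInterval(p - 0.5, m) + 1L
  hi <- findInterval(p + max_lag + 0.5, m)
  cnt <- pmax(hi - lo + 1L, 0L)
  if (sum(cnt) == 0) return(0L)
  idx <- sequence(cnt, from = lo)
  d <- m[idx] - rep(p, cnt)
  score <- tabulate(as.integer(d) + 1L, nbins = max_lag + 1L)
  best <- which.max(score) - 1L  # smallest lag wins ties
  as.integer(best %/% 2L)
}
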