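# helper: counts of sorted numeric values falling in [start, end) per interval
.count_in <- function(sorted_values, start, end) {
  findInterval(end - 0.5, sorted_values) -
    findInterval(start - 0.5, sorted_values)
}

# helper: weighted sums of sorted positions falling in [start, end)
.sum_in <- function(sorted_pos, weights, start, end) {
  cw <- c(0, cumsum(weights))
  cw[findInterval(end - 0.5, sorted_pos) + 1L] -
    cw[findInterval(start - 0.5, sorted_pos) + 1L]
}

#' Raw tag count in a promoter
#'
#' Number of tag midpoints falling inside the half-open promoter interval
#' `[start, end)`; the first of the two occupancy quantifications.
#'
#' @param tags Tibble with `chrom` and `midpoint` columns (one mark, one
#'   condition; see [read_tags()]).
#' @param promoters Tibble with `gene_id`, `chrom`, `start`, `end`.
#' @return `promoters` with a `count` column appended.
#' @export
promoter_raw_count <- function(tags, promoters) {
  by_chrom <- split(tags$midpoint, tags$chrom)
  counts <- numeric(nrow(promoters))
  for (ch in unique(promoters$chrom)) {
    rows <- which(promoters$chrom == ch)
    mids <- sort(by_chrom[[ch]] %||% numeric(0))
    counts[rows] <- .count_in(mids, promoters$start[rows], promoters$end[rows])
  }
  dplyr::mutate(promoters, count = counts)
}

#' Fitted-peak occupancy sum in a promoter
#'
#' Sum of the occupancies of called peaks whose center lies inside the
#' half-open promoter interval; the second occupancy quantification.
#'
#' @param peaks Tibble with `chrom`, `center`, `occupancy`
#'   (see [call_peaks_genome()]).
#' @inheritParams promoter_raw_count
#' @return `promoters` with a `peak_sum` column appended.
#' @export
promoter_peak_sum <- function(peaks, promoters) {
  by_chrom <- split(peaks[, c("center", "occupancy")], peaks$chrom)
  sums <- numeric(nrow(promoters))
  for (ch in unique(promoters$chrom)) {
    rows <- which(promoters$chrom == ch)
    pk <- by_chrom[[ch]]
    if (is.null(pk) || nrow(pk) == 0) next
    ord <- order(pk$center)
    sums[rows] <- .sum_in(pk$center[ord], pk$occupancy[ord],
                          promoters$start[rows], promoters$end[rows])
  }
  dplyr::mutate(promoters, peak_sum = sums)
}

#' Assemble a promoter occupancy table
#'
#' Quantifies every (mark, condition) tag set over all promoters with one of
#' the two approaches and returns a long tibble covering the full promoter
#' universe (absent signal is an explicit 0).
#'
#' @param promoters Promoter tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param tag_sets Named list of tag tibbles; names are `"mark:condition"`
#'   keys (e.g. `"H3K4me3:LLC-NR"`).
#' @param peak_sets Optional named list of peak tibbles with the same keys;
#'   required for `method = "peak_sum"`.
#' @param method `"raw_count"` (default) or `"peak_sum"`.
#' @return Long tibble `gene_id`, `mark`, `condition`, `occupancy`, with the
#'   quantification method in attribute `"method"`.
#' @export
promoter_occupancy <- function(promoters, tag_sets, peak_sets = NULL,
                               method = c("raw_count", "peak_sum")) {
  method <- match.arg(method)
  src <- if (method == "raw_count") tag_sets else peak_sets
  if (is.null(src)) stop("peak_sets is required for method 'peak_sum'",
                         call. = FALSE)
  out <- purrr::imap(src, function(x, key) {
    mc <- strsplit(key, ":", fixed = TRUE)[[1]]
    if (length(mc) != 2) stop("tag set key not of form 'mark:condition': ", key,
                              call. = FALSE)
    q <- if (method == "raw_count") {
      promoter_raw_count(x, promoters)$count
    } else {
      promoter_peak_sum(x, promoters)$peak_sum
    }
    tibble::tibble(gene_id = promoters$gene_id, mark = mc[1],
                   condition = mc[2], occupancy = as.numeric(q))
  })
  res <- dplyr::bind_rows(out)
  attr(res, "method") <- method
  res
}

#' Library-size normalization of an occupancy table
#'
#' Scales each (mark, condition) column to tags per million:
#' `occupancy * 1e6 / library_size`.
#'
#' @param occupancy Long occupancy tibble from [promoter_occupancy()].
#' @param library_sizes Tibble `mark`, `condition`, `library_size` (total
#'   mapped tags per tag set), or a named vector keyed `"mark:condition"`.
#' @return The occupancy tibble with normalized values.
#' @export
normalize_occupancy <- function(occupancy, library_sizes) {
  if (!is.data.frame(library_sizes)) {
    keys <- strsplit(names(library_sizes), ":", fixed = TRUE)
    library_sizes <- tibble::tibble(
      mark = vapply(keys, `[`, "", 1),
      condition = vapply(keys, `[`, "", 2),
      library_size = as.numeric(library_sizes)
    )
  }
  if (any(library_sizes$library_size <= 0)) {
    stop("library sizes must be positive", call. = FALSE)
  }
  library_sizes$library_size <- as.numeric(library_sizes$library_size)
  method <- attr(occupancy, "method")
  out <- occupancy |>
    dplyr::left_join(library_sizes, by = c("mark", "condition")) |>
    dplyr::mutate(occupancy = .data$occupancy * 1e6 / .data$library_size) |>
    dplyr::select(-"library_size")
  if (anyNA(out$occupancy)) {
    stop("missing library size for some (mark, condition)", call. = FALSE)
  }
  attr(out, "method") <- method
  out
}

#' Mean-occupancy thresholds per mark and condition
#'
#' The classification thresholds are multiples of the mean occupancy M of
#' each mark over *all* promoters (zero rows included), computed within each
#' condition by default or pooled across conditions.
#'
#' @inheritParams normalize_occupancy
#' @param mode `"per-condition"` (default) or `"pooled"` (one M per mark,
#'   shared by both conditions).
#' @return Tibble `mark`, `condition`, `M`.
#' @export
compute_thresholds <- function(occupancy,
                               mode = c("per-condition", "pooled")) {
  mode <- match.arg(mode)
  if (nrow(occupancy) == 0) stop("empty occupancy table", call. = FALSE)
  if (mode == "per-condition") {
    occupancy |>
      dplyr::group_by(.data$mark, .data$condition) |>
      dplyr::summarise(M = mean(.data$occupancy), .groups = "drop")
  } else {
    pooled <- occupancy |>
      dplyr::group_by(.data$mark) |>
      dplyr::summarise(M = mean(.data$occupancy), .groups = "drop")
    tidyr::crossing(pooled,
                    condition = unique(occupancy$condition))[
      , c("mark", "condition", "M")]
  }
}

#' Four-state chromatin classification of occupancy triples
#'
#' Applies the promoter-state rules: with `A = (K4 >= 2 M_K4) or
#' (K9ac >= 2 M_K9ac)` and `R = (K27 >= M_K27)`, a promoter is **active** if
#' `A` and not `R`, **bivalent** if `A` and `R`, **repressive** if `R` and
#' not `A`, and **none** otherwise. Cutoffs are inclusive (`>=`); the active
#' state requires K27 strictly below its mean.
#'
#' @param occ_k4,occ_k9ac,occ_k27 Numeric vectors of promoter occupancy.
#' @param m_k4,m_k9ac,m_k27 Mean-occupancy thresholds M for the three marks.
#' @return Factor with levels active, repressive, bivalent, none.
#' @export
classify_state <- function(occ_k4, occ_k9ac, occ_k27, m_k4, m_k9ac, m_k27) {
  if (any(c(occ_k4, occ_k9ac, occ_k27) < 0)) {
    stop("negative occupancy", call. = FALSE)
  }
  a <- (occ_k4 >= 2 * m_k4) | (occ_k9ac >= 2 * m_k9ac)
  r <- occ_k27 >= m_k27
  state <- dplyr::case_when(
    a & !r ~ "active",
    a & r ~ "bivalent",
    r & !a ~ "repressive",
    .default = "none"
  )
  factor(state, levels = .PS_STATES)
}

#' Promoter chromatin states from an occupancy table
#'
#' Computes thresholds (unless supplied) and classifies every promoter in
#' every condition.
#'
#' @inheritParams normalize_occupancy
#' @param thresholds Optional threshold tibble from [compute_thresholds()];
#'   computed from `occupancy` when NULL.
#' @inheritParams compute_thresholds
#' @return Tibble `gene_id`, `condition`, `state`.
#' @export
classify_states <- function(occupancy, thresholds = NULL,
                            mode = c("per-condition", "pooled")) {
  if (is.null(thresholds)) thresholds <- compute_thresholds(occupancy, mode)
  wide <- occupancy |>
    dplyr::filter(.data$mark %in% .PS_PROMOTER_MARKS) |>
    tidyr::pivot_wider(id_cols = c("gene_id", "condition"),
                       names_from = "mark", values_from = "occupancy",
                       values_fill = 0)
  for (mk in .PS_PROMOTER_MARKS) {
    if (is.null(wide[[mk]])) {
      stop("occupancy table lacks mark ", mk, call. = FALSE)
    }
  }
  thr <- tidyr::pivot_wider(thresholds, names_from = "mark",
                            values_from = "M", names_prefix = "M_")
  wide <- dplyr::left_join(wide, thr, by = "condition")
  tibble::tibble(
    gene_id = wide$gene_id,
    condition = wide$condition,
    state = classify_state(wide$H3K4me3, wide$H3K9ac, wide$H3K27me3,
                           wide$M_H3K4me3, wide$M_H3K9ac, wide$M_H3K27me3)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
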