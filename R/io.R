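#' Read aligned ChIP-seq tags from BED6
#'
#' Tag midpoints are `floor((start + end) / 2)` in 0-based half-open BED
#' coordinates. Missing strand (`"."` or absent column) is allowed;
#' malformed lines are reported with their line numbers.
#'
#' @param path BED file (3-6 whitespace-delimited columns, no header).
#' @param mark,condition Optional labels attached as columns.
#' @return Tibble `chrom`, `start`, `end`, `midpoint`, `strand` (plus `mark`,
#'   `condition` when given), sorted by chrom and midpoint, with the library
#'   size (number of tags) in attribute `"library_size"`.
#' @export
read_tags <- function(path, mark = NULL, condition = NULL) {
  if (!file.exists(path)) stop("tag file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(
    path, col_names = FALSE, col_types = readr::cols(.default = "c"),
    progress = FALSE
  )
  if (ncol(raw) < 3) stop("BED file needs at least 3 columns: ", path,
                          call. = FALSE)
  start <- suppressWarnings(as.integer(raw[[2]]))
  end <- suppressWarnings(as.integer(raw[[3]]))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad)) {
    stop("malformed BED lines in ", path, " at line(s): ",
         paste(utils::head(bad, 20), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    chrom = raw[[1]],
    start = start,
    end = end,
    midpoint = (start + end) %/% 2L,
    strand = if (ncol(raw) >= 6) raw[[6]] else "."
  )
  if (!is.null(mark)) out$mark <- mark
  if (!is.null(condition)) out$condition <- condition
  out <- dplyr::arrange(out, .data$chrom, .data$midpoint)
  attr(out, "library_size") <- nrow(out)
  out
}

#' Read gene models from BED6 or minimal GTF
#'
#' BED input is used as-is (0-based half-open); GTF `transcript` (or `gene`)
#' features are converted from 1-based closed to 0-based half-open
#' coordinates and must carry a `gene_id` attribute. One row per gene: with
#' multiple transcripts per gene the first listed is kept. Duplicate rows
#' for the same gene at conflicting coordinates are rejected.
#'
#' @param path Path to `.bed` or `.gtf`/`.gff` file (format inferred from
#'   the extension, override with `format`).
#' @param format `"bed"` or `"gtf"`.
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_genes <- function(path, format = NULL) {
  if (!file.exists(path)) stop("gene file not found: ", path, call. = FALSE)
  format <- format %||%
    (if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE)) "gtf" else "bed")
  if (format == "gtf") {
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type %in% c("transcript", "gene")]
    out <- tibble::tibble(
      gene_id = gr$gene_id,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,  # 1-based closed -> 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))
    )
  } else {
    raw <- readr::read_tsv(path, col_names = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    if (ncol(raw) < 6) stop("gene BED needs 6 columns: ", path, call. = FALSE)
    out <- tibble::tibble(
      gene_id = raw[[4]],
      chrom = raw[[1]],
      start = as.integer(raw[[2]]),
      end = as.integer(raw[[3]]),
      strand = raw[[6]]
    )
  }
  # first listed transcript per gene
  first <- !duplicated(out$gene_id)
  dup_conflict <- out |>
    dplyr::distinct(.data$gene_id, .data$chrom, .data$start,
                    .data$end, .data$strand) |>
    dplyr::count(.data$gene_id) |>
    dplyr::filter(.data$n > 1)
  out <- out[first, ]
  if (nrow(dup_conflict) && format == "bed") {
    stop("duplicate gene ids with conflicting coordinates: ",
         paste(utils::head(dup_conflict$gene_id, 20), collapse = ", "),
         call. = FALSE)
  }
  if (!all(out$strand %in% c("+", "-"))) {
    stop("gene strands must be '+' or '-'", call. = FALSE)
  }
  out
}

#' Read an expression table
#'
#' TSV with header: `gene_id` and one FPKM column per condition
#' (`fpkm_NR`, `fpkm_R`). Duplicate gene ids are rejected.
#'
#' @param path TSV path.
#' @return Tibble `gene_id`, `fpkm_NR`, `fpkm_R`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path,
                               call. = FALSE)
  out <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", .default = "d"), progress = FALSE)
  stopifnot(all(c("gene_id", "fpkm_NR", "fpkm_R") %in% names(out)))
  dups <- unique(out$gene_id[duplicated(out$gene_id)])
  if (length(dups)) {
    stop("duplicate gene ids in expression table: ",
         paste(utils::head(dups, 20), collapse = ", "), call. = FALSE)
  }
  if (any(out$fpkm_NR < 0 | out$fpkm_R < 0)) {
    stop("FPKM values must be non-negative", call. = FALSE)
  }
  out
}
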