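#' Chromatin-state transition table between two conditions
#'
#' Cross-tabulates per-promoter states in a "from" condition against a "to"
#' condition: counts and row-wise proportions (each row conditions on the
#' starting state; empty rows have NA proportions). Optionally stratified by
#' CpG class.
#'
#' @param states Long state tibble (`gene_id`, `condition`, `state`) from
#'   [classify_states()], or a wide tibble with `gene_id`, `state_from`,
#'   `state_to` columns.
#' @param from,to Condition labels selecting the two compared conditions
#'   (ignored for wide input).
#' @param cpg_class Optional tibble `gene_id`, `cpg_class` for stratification.
#' @return An object of class `transition_table`: list with `counts` and
#'   `proportions` (4 x 4 matrices, from-states in rows), `by_class` (the
#'   same per CpG class, when given), `data` (per-gene tibble) and `n`.
#'   [tidy()] returns the long form.
#' @examples
#' st <- tibble::tibble(
#'   gene_id = rep(paste0("g", 1:10), 2),
#'   condition = rep(c("NR", "R"), each = 10),
#'   state = factor(c(rep("bivalent", 10), rep(c("active", "bivalent"), c(8, 2))),
#'                  levels = c("active", "repressive", "bivalent", "none"))
#' )
#' transition_table(st, from = "NR", to = "R")$proportions["bivalent", ]
#' @export
transition_table <- function(states, from = "LLC-NR", to = "LLC-R",
                             cpg_class = NULL) {
  if (all(c("state_from", "state_to") %in% names(states))) {
    data <- tibble::tibble(
      gene_id = states$gene_id,
      state_from = factor(states$state_from, levels = .PS_STATES),
      state_to = factor(states$state_to, levels = .PS_STATES)
    )
  } else {
    a <- dplyr::filter(states, .data$condition == from)
    b <- dplyr::filter(states, .data$condition == to)
    only_a <- setdiff(a$gene_id, b$gene_id)
    only_b <- setdiff(b$gene_id, a$gene_id)
    if (length(only_a) || length(only_b)) {
      stop("gene universes differ between conditions; missing genes: ",
           paste(utils::head(c(only_a, only_b), 20), collapse = ", "),
           call. = FALSE)
    }
    data <- tibble::tibble(
      gene_id = a$gene_id,
      state_from = factor(a$state, levels = .PS_STATES),
      state_to = factor(b$state, levels = .PS_STATES)[match(a$gene_id, b$gene_id)]
    )
  }
  if (!is.null(cpg_class)) {
    data <- dplyr::left_join(data, cpg_class[, c("gene_id", "cpg_class")],
                             by = "gene_id")
  }
  tab <- function(d) {
    counts <- table(from = d$state_from, to = d$state_to)
    counts <- unclass(counts)[.PS_STATES, .PS_STATES, drop = FALSE]
    rs <- rowSums(counts)
    props <- sweep(counts, 1, rs, "/")
    props[rs == 0, ] <- NA_real_
    list(counts = counts, proportions = props)
  }
  res <- tab(data)
  out <- list(counts = res$counts, proportions = res$proportions,
              data = data, n = nrow(data),
              from = from, to = to)
  if (!is.null(cpg_class)) {
    out$by_class <- lapply(split(data, data$cpg_class), tab)
  }
  structure(out, class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat("Chromatin-state transitions (", x$from, " -> ", x$to, "), n = ",
      x$n, "\n\nCounts:\n", sep = "")
  print(x$counts)
  cat("\nRow proportions:\n")
  print(round(x$proportions, 3))
  invisible(x)
}

#' @describeIn transition_table Long tibble of counts and row proportions
#'   (overall rows have `cpg_class = "all"`; stratified rows follow when the
#'   table was built with CpG classes).
#' @param x A `transition_table`.
#' @param ... Unused.
#' @method tidy transition_table
#' @export
tidy.transition_table <- function(x, ...) {
  longify <- function(t, label) {
    tibble::tibble(
      cpg_class = label,
      state_from = rep(rownames(t$counts), times = ncol(t$counts)),
      state_to = rep(colnames(t$counts), each = nrow(t$counts)),
      n = as.vector(t$counts),
      proportion = as.vector(t$proportions)
    )
  }
  out <- longify(x, "all")
  if (!is.null(x$by_class)) {
    out <- dplyr::bind_rows(
      out,
      dplyr::bind_rows(purrr::imap(x$by_class, longify))
    )
  }
  out
}

#' @method glance transition_table
#' @export
glance.transition_table <- function(x, ...) {
  diag_n <- sum(diag(x$counts))
  tibble::tibble(
    n = x$n,
    n_stable = diag_n,
    prop_stable = diag_n / x$n,
    n_gain_active = sum(x$counts[c("repressive", "bivalent", "none"), "active"]),
    n_lose_repressive = sum(x$counts["repressive", c("none", "active")])
  )
}

#' Spearman correlation between promoter occupancy and expression
#'
#' Rank correlation (average ranks on ties) between one mark's promoter
#' occupancy and gene expression, the standard check that active marks
#' correlate positively and repressive marks negatively with transcription.
#'
#' @param occ,fpkm Paired numeric vectors (same genes, same order), n >= 3.
#' @return Spearman's rho; NA with a warning if either vector is constant.
#' @export
spearman_occupancy_expression <- function(occ, fpkm) {
  stopifnot(length(occ) == length(fpkm))
  if (length(occ) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(occ) == 0 || stats::sd(fpkm) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(occ, fpkm, method = "spearman")
}

#' Two-sample Student's t comparison of expression groups
#'
#' Pooled-variance two-sided t test with the conventional significance tiers
#' (`**` p <= 0.01, `*` p <= 0.05, `n.s.` otherwise). Degenerate input with
#' zero pooled variance yields t = 0, p = 1 when the means are equal.
#'
#' @param group_a,group_b Numeric vectors (each n >= 2), e.g. FPKM of two
#'   gene groups.
#' @return Tibble `t`, `df`, `p_value`, `significance`.
#' @export
compare_expression_groups <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      res <- list(statistic = 0, parameter = length(group_a) + length(group_b) - 2,
                  p.value = 1)
    } else {
      res <- list(statistic = sign(mean(group_a) - mean(group_b)) * Inf,
                  parameter = length(group_a) + length(group_b) - 2,
                  p.value = 0)
    }
  } else {
    ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
    res <- list(statistic = unname(ht$statistic),
                parameter = unname(ht$parameter), p.value = ht$p.value)
  }
  tibble::tibble(
    t = res$statistic,
    df = res$parameter,
    p_value = res$p.value,
    significance = dplyr::case_when(
      res$p.value <= 0.01 ~ "**",
      res$p.value <= 0.05 ~ "*",
      .default = "n.s."
    )
  )
}

#' Per-gene log2 fold changes of marks and expression
#'
#' For a gene list (e.g. angiogenesis-related genes), computes
#' `log2((x_to + c) / (x_from + c))` for each mark's promoter occupancy and
#' for FPKM, with pseudocount `c` guarding zeros.
#'
#' @param occupancy Long occupancy tibble covering both conditions.
#' @param expression Tibble `gene_id`, `fpkm_NR`, `fpkm_R` (or columns named
#'   `fpkm_<from>`, `fpkm_<to>` matching the condition labels).
#' @param gene_list Character vector of gene ids, ordered as desired.
#' @param from,to Condition labels.
#' @param pseudocount Pseudocount `c` (default 1 normalized unit).
#' @return Tibble `gene_id` plus one `log2fc_<mark>` column per mark and
#'   `log2fc_expression`, in `gene_list` order. Unknown ids are dropped with
#'   a warning.
#' @export
fold_change_table <- function(occupancy, expression, gene_list,
                              from = "LLC-NR", to = "LLC-R",
                              pseudocount = 1) {
  stopifnot(pseudocount > 0)
  known <- unique(occupancy$gene_id)
  unknown <- setdiff(gene_list, known)
  if (length(unknown)) {
    warning("unknown gene ids skipped: ", paste(unknown, collapse = ", "))
    gene_list <- setdiff(gene_list, unknown)
  }
  occ_fc <- occupancy |>
    dplyr::filter(.data$gene_id %in% gene_list) |>
    tidyr::pivot_wider(id_cols = c("gene_id", "mark"),
                       names_from = "condition", values_from = "occupancy") |>
    dplyr::mutate(log2fc = log2((.data[[to]] + pseudocount) /
                                  (.data[[from]] + pseudocount))) |>
    tidyr::pivot_wider(id_cols = "gene_id", names_from = "mark",
                       values_from = "log2fc", names_prefix = "log2fc_")
  expr_cols <- intersect(c("fpkm_NR", "fpkm_R"), names(expression))
  if (length(expr_cols) != 2) {
    expr_cols <- c(paste0("fpkm_", from), paste0("fpkm_", to))
  }
  expr_fc <- tibble::tibble(
    gene_id = expression$gene_id,
    log2fc_expression = log2((expression[[expr_cols[2]]] + pseudocount) /
                               (expression[[expr_cols[1]]] + pseudocount))
  )
  tibble::tibble(gene_id = gene_list) |>
    dplyr::left_join(occ_fc, by = "gene_id") |>
    dplyr::left_join(expr_fc, by = "gene_id")
}

#' Select genes by state-transition category
#'
#' Default categories: **gain_active** (promoter not active in the "from"
#' condition, active in the "to" condition) and **lose_repressive**
#' (repressive becoming none or active). Custom categories are given as
#' named lists with `from` and `to` state vectors. Gene lists are emitted
#' overall and per CpG class when classes are present, ready for external
#' GO/KEGG tools.
#'
#' @param transitions A [transition_table()] object or its `$data` tibble.
#' @param categories Named list; each element is `list(from = <states>,
#'   to = <states>)`.
#' @return Named list of character vectors of gene ids. When CpG classes are
#'   available, additional elements named `<category>.<class>`.
#' @export
select_transition_genes <- function(
    transitions,
    categories = list(
      gain_active = list(from = c("repressive", "none", "bivalent"),
                         to = "active"),
      lose_repressive = list(from = "repressive", to = c("none", "active"))
    )) {
  data <- if (inherits(transitions, "transition_table")) transitions$data
          else transitions
  bad <- vapply(categories, function(cc) {
    !all(c(cc$from, cc$to) %in% .PS_STATES)
  }, logical(1))
  if (any(bad)) {
    stop("unknown state in category definition: ",
         paste(names(categories)[bad], collapse = ", "), call. = FALSE)
  }
  pick <- function(d, cc) {
    d$gene_id[d$state_from %in% cc$from & d$state_to %in% cc$to]
  }
  out <- lapply(categories, pick, d = data)
  if ("cpg_class" %in% names(data)) {
    for (nm in names(categories)) {
      for (cl in levels(factor(data$cpg_class))) {
        out[[paste(nm, cl, sep = ".")]] <-
          pick(data[data$cpg_class == cl, ], categories[[nm]])
      }
    }
  }
  out
}

#' Strand-oriented gene-body coverage profile
#'
#' Bins tag midpoints into `n_bins` equal-width bins over each gene body
#' (TSS to TES, 5' to 3'), normalizes to tags per million, and averages
#' within gene groups — the standard metagene view of an elongation mark
#' such as H3K36me3.
#'
#' @param tags Tag tibble (`chrom`, `midpoint`), one mark and condition.
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param groups Optional tibble `gene_id`, `group` (e.g. chromatin state);
#'   genes without a group are dropped.
#' @param n_bins Number of bins (default 40). Genes shorter than `n_bins` bp
#'   are skipped with a warning.
#' @param library_size Total mapped tags for per-million scaling (default
#'   `nrow(tags)`).
#' @return Tibble `group`, `bin`, `mean_coverage` (bin 1 = 5' end).
#' @export
genebody_coverage_profile <- function(tags, genes, groups = NULL,
                                      n_bins = 40L, library_size = NULL) {
  library_size <- library_size %||% nrow(tags)
  short <- genes$end - genes$start < n_bins
  if (any(short)) {
    warning(sum(short), " genes shorter than n_bins skipped")
    genes <- genes[!short, ]
  }
  by_chrom <- split(tags$midpoint, tags$chrom)
  prof <- matrix(0, nrow = nrow(genes), ncol = n_bins)
  for (i in seq_len(nrow(genes))) {
    mids <- sort(by_chrom[[genes$chrom[i]]] %||% numeric(0))
    edges <- seq(genes$start[i], genes$end[i], length.out = n_bins + 1L)
    cnt <- .count_in(mids, edges[-(n_bins + 1L)], edges[-1L])
    if (genes$strand[i] == "-") cnt <- rev(cnt)
    prof[i, ] <- cnt * 1e6 / library_size
  }
  df <- tibble::tibble(gene_id = genes$gene_id) |>
    dplyr::bind_cols(tibble::as_tibble(prof, .name_repair = ~ paste0("bin", seq_len(n_bins))))
  if (is.null(groups)) {
    groups <- tibble::tibble(gene_id = genes$gene_id, group = "all")
  }
  df |>
    dplyr::inner_join(groups, by = "gene_id") |>
    tidyr::pivot_longer(dplyr::starts_with("bin"), names_to = "bin",
                        values_to = "coverage") |>
    dplyr::mutate(bin = as.integer(sub("bin", "", .data$bin))) |>
    dplyr::group_by(.data$group, .data$bin) |>
    dplyr::summarise(mean_coverage = mean(.data$coverage), .groups = "drop")
}
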