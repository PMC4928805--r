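#' Pipeline configuration
#'
#' Collects input paths and analysis parameters for [run_pipeline()]. All
#' referenced files must exist when the pipeline starts; tag files are keyed
#' `"mark:condition"` and must cover H3K4me3, H3K9ac and H3K27me3 in both
#' conditions (H3K36me3 is optional and used for gene-body profiles only).
#'
#' @param genome FASTA path.
#' @param genes Gene BED6 or GTF path.
#' @param tags Named character vector or list of tag BED paths, keyed
#'   `"mark:condition"`.
#' @param expression Expression TSV path (see [read_expression()]).
#' @param outdir Output directory.
#' @param conditions The two condition labels, "from" first.
#' @param upstream,downstream Promoter extent around the TSS (bp).
#' @param window,step CpG-class scan parameters (bp).
#' @param sigma,exclusion,min_occupancy Peak-calling parameters (bp, bp,
#'   smoothed-height units).
#' @param pseudocount Pseudocount for fold changes.
#' @param threshold_mode `"per-condition"` (default) or `"pooled"` mean
#'   occupancy thresholds.
#' @param state_method Occupancy quantification used for state calls:
#'   `"raw_count"` (default) or `"peak_sum"`; the other method is always
#'   computed alongside for comparison.
#' @param n_bins Gene-body profile bins.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, genes, tags, expression, outdir,
                            conditions = c("LLC-NR", "LLC-R"),
                            upstream = 1000L, downstream = 500L,
                            window = 500L, step = 1L,
                            sigma = 20, exclusion = 147L, min_occupancy = 2,
                            pseudocount = 1,
                            threshold_mode = c("per-condition", "pooled"),
                            state_method = c("raw_count", "peak_sum"),
                            n_bins = 40L, seed = 1L) {
  tags <- as.list(tags)
  cfg <- list(genome = genome, genes = genes, tags = tags,
              expression = expression, outdir = outdir,
              conditions = conditions,
              upstream = upstream, downstream = downstream,
              window = window, step = step, sigma = sigma,
              exclusion = exclusion, min_occupancy = min_occupancy,
              pseudocount = pseudocount,
              threshold_mode = match.arg(threshold_mode),
              state_method = match.arg(state_method),
              n_bins = n_bins, seed = as.integer(seed))
  needed <- as.vector(outer(.PS_PROMOTER_MARKS, conditions, paste, sep = ":"))
  missing_keys <- setdiff(needed, names(tags))
  if (length(missing_keys)) {
    stop("missing tag sets for: ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  for (key in names(tags)) {
    if (!file.exists(tags[[key]])) {
      stop("tag file for ", key, " not found: ", tags[[key]], call. = FALSE)
    }
  }
  for (f in c("genome", "genes", "expression")) {
    if (!file.exists(cfg[[f]])) {
      stop(f, " file not found: ", cfg[[f]], call. = FALSE)
    }
  }
  stopifnot(cfg$upstream >= 0, cfg$downstream >= 0, cfg$sigma > 0,
            cfg$exclusion > 0, cfg$pseudocount > 0, cfg$n_bins >= 2)
  structure(cfg, class = "pipeline_config")
}

.stage <- function(log, name) {
  message(sprintf("[promstates] stage %d: %s", length(log) + 1L, name))
  c(log, name)
}

#' Run the full promoter chromatin-state pipeline
#'
#' Stage order: promoter extraction and CpG classification, peak calling,
#' occupancy quantification (both approaches), mean-occupancy thresholds,
#' state classification per condition, state transitions, and
#' expression analyses (Spearman correlations, expression by state,
#' fold-change table for transition genes, H3K36me3 gene-body profile).
#' Every table is written to `outdir` as TSV and a JSON manifest records
#' parameters, stages and output checksums.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `promstates_result`: list with `promoters`,
#'   `occupancy` (list raw_count/peak_sum), `thresholds`, `states`,
#'   `transitions`, `correlations`, `expression_by_state`, `fold_changes`,
#'   `gene_lists`, `genebody_profile`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  cond <- config$conditions
  stages <- character(0)
  fail <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  # -- promoters ------------------------------------------------------------
  stages <- .stage(stages, "promoters")
  res <- tryCatch({
    genome <- Biostrings::readDNAStringSet(config$genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    chrom_sizes <- stats::setNames(Biostrings::width(genome), names(genome))
    genes <- read_genes(config$genes)
    promoters <- promoter_windows(genes, chrom_sizes,
                                  upstream = config$upstream,
                                  downstream = config$downstream)
    promoters <- classify_promoters(promoters, genome,
                                    window = config$window, step = config$step)
    list(genome = genome, chrom_sizes = chrom_sizes, genes = genes,
         promoters = promoters)
  }, error = function(e) fail("promoters", e))

  # -- tags and peaks -------------------------------------------------------
  stages <- .stage(stages, "peaks")
  pk <- tryCatch({
    tag_sets <- purrr::imap(config$tags, function(p, key) read_tags(p))
    library_sizes <- tibble::tibble(
      mark = sub(":.*", "", names(tag_sets)),
      condition = sub(".*:", "", names(tag_sets)),
      library_size = vapply(tag_sets, nrow, integer(1))
    )
    prom_keys <- as.vector(outer(.PS_PROMOTER_MARKS, cond, paste, sep = ":"))
    peak_sets <- purrr::imap(tag_sets[prom_keys], function(tags, key) {
      call_peaks_genome(tags, res$chrom_sizes, sigma = config$sigma,
                        exclusion = config$exclusion,
                        min_occupancy = config$min_occupancy)
    })
    list(tag_sets = tag_sets, peak_sets = peak_sets,
         library_sizes = library_sizes)
  }, error = function(e) fail("peaks", e))

  # -- occupancy (both methods), thresholds, states -------------------------
  stages <- .stage(stages, "occupancy")
  occ <- tryCatch({
    prom_keys <- names(pk$peak_sets)
    raw <- promoter_occupancy(res$promoters, pk$tag_sets[prom_keys],
                              method = "raw_count") |>
      normalize_occupancy(pk$library_sizes)
    attr(raw, "method") <- "raw_count"
    psum <- promoter_occupancy(res$promoters, pk$tag_sets[prom_keys],
                               peak_sets = pk$peak_sets, method = "peak_sum") |>
      normalize_occupancy(pk$library_sizes)
    attr(psum, "method") <- "peak_sum"
    list(raw_count = raw, peak_sum = psum)
  }, error = function(e) fail("occupancy", e))

  stages <- .stage(stages, "states")
  st <- tryCatch({
    primary <- occ[[config$state_method]]
    thresholds <- compute_thresholds(primary, mode = config$threshold_mode)
    states <- classify_states(primary, thresholds)
    states_alt <- classify_states(
      occ[[setdiff(c("raw_count", "peak_sum"), config$state_method)]],
      mode = config$threshold_mode)
    agreement <- mean(states$state ==
                        states_alt$state[match(paste(states$gene_id, states$condition),
                                               paste(states_alt$gene_id,
                                                     states_alt$condition))])
    list(thresholds = thresholds, states = states,
         method_agreement = agreement)
  }, error = function(e) fail("states", e))

  # -- transitions ----------------------------------------------------------
  stages <- .stage(stages, "transitions")
  tr <- tryCatch({
    transitions <- transition_table(
      st$states, from = cond[1], to = cond[2],
      cpg_class = res$promoters[, c("gene_id", "cpg_class")])
    gene_lists <- select_transition_genes(transitions)
    list(transitions = transitions, gene_lists = gene_lists)
  }, error = function(e) fail("transitions", e))

  # -- expression analyses --------------------------------------------------
  stages <- .stage(stages, "expression")
  ex <- tryCatch({
    expression <- read_expression(config$expression)
    expression <- expression[match(res$promoters$gene_id, expression$gene_id), ]
    if (anyNA(expression$gene_id)) {
      stop("expression table lacks some annotated genes")
    }
    fpkm_col <- stats::setNames(c("fpkm_NR", "fpkm_R"), cond)
    primary <- occ[[config$state_method]]
    correlations <- primary |>
      dplyr::group_by(.data$mark, .data$condition) |>
      dplyr::summarise(
        rho = spearman_occupancy_expression(
          .data$occupancy[match(res$promoters$gene_id, .data$gene_id)],
          expression[[fpkm_col[[.data$condition[1]]]]]),
        .groups = "drop")
    expr_by_state <- st$states |>
      dplyr::mutate(fpkm = purrr::map2_dbl(
        .data$gene_id, .data$condition,
        ~ expression[[fpkm_col[[.y]]]][match(.x, expression$gene_id)]))
    pairs <- list(c("active", "bivalent"), c("bivalent", "repressive"),
                  c("active", "repressive"))
    state_tests <- purrr::map_dfr(cond, function(cd) {
      d <- dplyr::filter(expr_by_state, .data$condition == cd)
      purrr::map_dfr(pairs, function(pp) {
        a <- d$fpkm[d$state == pp[1]]
        b <- d$fpkm[d$state == pp[2]]
        if (length(a) < 2 || length(b) < 2) return(NULL)
        dplyr::mutate(compare_expression_groups(a, b),
                      condition = cd, group_a = pp[1], group_b = pp[2],
                      .before = 1)
      })
    })
    fc_genes <- unique(unlist(tr$gene_lists[c("gain_active", "lose_repressive")]))
    fold_changes <- fold_change_table(primary, expression, fc_genes,
                                      from = cond[1], to = cond[2],
                                      pseudocount = config$pseudocount)
    k36_keys <- paste("H3K36me3", cond, sep = ":")
    profile <- NULL
    if (all(k36_keys %in% names(pk$tag_sets))) {
      profile <- purrr::map_dfr(cond, function(cd) {
        grp <- dplyr::filter(st$states, .data$condition == cd)
        genebody_coverage_profile(
          pk$tag_sets[[paste("H3K36me3", cd, sep = ":")]], res$genes,
          groups = tibble::tibble(gene_id = grp$gene_id,
                                  group = as.character(grp$state)),
          n_bins = config$n_bins) |>
          dplyr::mutate(condition = cd, .before = 1)
      })
    }
    list(expression = expression, correlations = correlations,
         expression_by_state = expr_by_state, state_tests = state_tests,
         fold_changes = fold_changes, genebody_profile = profile)
  }, error = function(e) fail("expression", e))

  # -- exports + manifest ---------------------------------------------------
  stages <- .stage(stages, "export")
  out <- tryCatch({
    w <- function(x, name) {
      p <- file.path(config$outdir, name)
      readr::write_tsv(x, p)
      p
    }
    files <- c(
      w(dplyr::select(res$promoters, -dplyr::any_of("sequence")), "promoters.tsv"),
      purrr::imap_chr(pk$peak_sets, function(p, key) {
        w(p, paste0("peaks_", gsub(":", "_", key), ".tsv"))
      }),
      w(occ$raw_count, "occupancy_raw_count.tsv"),
      w(occ$peak_sum, "occupancy_peak_sum.tsv"),
      w(st$thresholds, "thresholds.tsv"),
      w(st$states, "states.tsv"),
      w(tidy(tr$transitions), "transitions.tsv"),
      w(ex$correlations, "correlations.tsv"),
      w(ex$state_tests, "expression_state_tests.tsv"),
      w(ex$fold_changes, "fold_changes.tsv")
    )
    if (!is.null(ex$genebody_profile)) {
      files <- c(files, w(ex$genebody_profile, "genebody_profile.tsv"))
    }
    for (nm in names(tr$gene_lists)) {
      p <- file.path(config$outdir, paste0("genes_", nm, ".txt"))
      writeLines(tr$gene_lists[[nm]], p)
      files <- c(files, p)
    }
    univ <- file.path(config$outdir, "genes_universe.txt")
    writeLines(res$promoters$gene_id, univ)
    files <- c(files, univ)

    params <- config[setdiff(names(config),
                             c("genome", "genes", "tags", "expression",
                               "outdir"))]
    manifest <- list(
      package = "promstates",
      stages = stages,
      parameters = params,
      inputs = as.list(tools::md5sum(c(
        genome = config$genome, genes = config$genes,
        expression = config$expression,
        unlist(config$tags)))),
      outputs = {
        md5s <- tools::md5sum(sort(files))
        names(md5s) <- basename(names(md5s))
        as.list(md5s)
      },
      library_sizes = stats::setNames(
        as.list(pk$library_sizes$library_size),
        paste(pk$library_sizes$mark, pk$library_sizes$condition, sep = ":")),
      method_agreement = st$method_agreement
    )
    mpath <- file.path(config$outdir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    manifest
  }, error = function(e) fail("export", e))

  structure(list(
    promoters = res$promoters, genes = res$genes,
    peaks = pk$peak_sets, library_sizes = pk$library_sizes,
    occupancy = occ, thresholds = st$thresholds, states = st$states,
    method_agreement = st$method_agreement,
    transitions = tr$transitions, gene_lists = tr$gene_lists,
    expression = ex$expression, correlations = ex$correlations,
    expression_by_state = ex$expression_by_state,
    state_tests = ex$state_tests, fold_changes = ex$fold_changes,
    genebody_profile = ex$genebody_profile,
    manifest = out, config = config
  ), class = "promstates_result")
}

#' @export
print.promstates_result <- function(x, ...) {
  cat("promstates pipeline result\n")
  cat("  promoters:", nrow(x$promoters), "\n")
  cat("  CpG classes:",
      paste(names(table(x$promoters$cpg_class)),
            table(x$promoters$cpg_class), collapse = ", "), "\n")
  cat("  quantification for states:", attr(x$occupancy[[x$config$state_method]],
                                           "method"), "\n")
  cat("  raw-count vs peak-sum state agreement:",
      sprintf("%.1f%%", 100 * x$method_agreement), "\n")
  print(x$transitions)
  invisible(x)
}

#' @describeIn run_pipeline Per-gene summary tibble: CpG class, state in both
#'   conditions, FPKM, and log2 expression fold change.
#' @param x A `promstates_result`.
#' @param ... Unused.
#' @method tidy promstates_result
#' @export
tidy.promstates_result <- function(x, ...) {
  cond <- x$config$conditions
  states_wide <- tidyr::pivot_wider(x$states, names_from = "condition",
                                    values_from = "state")
  names(states_wide)[match(cond, names(states_wide))] <-
    c("state_from", "state_to")
  x$promoters |>
    dplyr::select("gene_id", "chrom", "start", "end", "strand", "cpg_class") |>
    dplyr::left_join(states_wide, by = "gene_id") |>
    dplyr::left_join(x$expression, by = "gene_id") |>
    dplyr::mutate(log2fc_expression = log2(
      (.data$fpkm_R + x$config$pseudocount) /
        (.data$fpkm_NR + x$config$pseudocount)))
}

#' @describeIn run_pipeline One-row run summary (promoter counts per class,
#'   state counts, correlation extremes, method agreement).
#' @method glance promstates_result
#' @export
glance.promstates_result <- function(x, ...) {
  cls <- table(x$promoters$cpg_class)
  st <- table(x$states$state[x$states$condition == x$config$conditions[1]])
  tibble::tibble(
    n_genes = nrow(x$promoters),
    n_hcp = as.integer(cls["HCP"]), n_icp = as.integer(cls["ICP"]),
    n_lcp = as.integer(cls["LCP"]),
    n_active_from = as.integer(st["active"]),
    n_bivalent_from = as.integer(st["bivalent"]),
    rho_max = max(x$correlations$rho), rho_min = min(x$correlations$rho),
    method_agreement = x$method_agreement
  )
}
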