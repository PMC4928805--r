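#' Configuration for the synthetic ChIP-seq experiment
#'
#' Bundles every knob of the generator: genome layout, planted CpG-class and
#' chromatin-state frequencies, the state-transition matrix between the two
#' conditions, per-mark/per-state promoter tag enrichment, background tag
#' rate, and the state-coupled expression model. All randomness flows from
#' `seed`; identical configs give byte-identical outputs.
#'
#' Defaults emulate the study conditions the pipeline targets: 2000 genes on
#' 4 chromosomes of 2.5 Mb, promoter enrichment 8x the local background
#' (480 expected tags over a 1.5-kb promoter at background 0.04 tags/bp),
#' bivalent promoters resolving 80%/20% to active/bivalent between
#' conditions, and log-scale expression means ordered
#' active > bivalent > repressive >= none.
#'
#' @param seed Integer master seed.
#' @param n_chroms,chrom_length Number of chromosomes and their length (bp).
#' @param n_genes Total genes, distributed evenly over chromosomes.
#' @param cpg_class_probs Length-3 probability vector (HCP, ICP, LCP).
#' @param state_probs_NR Length-4 probability vector over states
#'   (active, repressive, bivalent, none) in the first condition.
#' @param transition_matrix 4 x 4 row-stochastic matrix of state transitions
#'   from the first to the second condition (same state order).
#' @param enrichment 4 x 4 matrix (marks x states) of expected planted
#'   promoter tag counts; by default `enrichment_fold` x the expected
#'   background tag count in a 1.5-kb promoter for the mark/state pairs that
#'   carry signal (active: K4/K9ac; repressive: K27; bivalent: all three).
#' @param enrichment_fold Fold enrichment over promoter background used to
#'   build the default `enrichment` matrix (default 8).
#' @param background_rate Background tag density, tags per bp (default 0.04).
#' @param expression_means Named log-scale means of FPKM per state.
#' @param expression_sd Log-scale standard deviation of FPKM (default 0.45).
#' @param k36_per_fpkm Expected H3K36me3 gene-body tags per FPKM unit
#'   (default 3).
#' @param library_size Nominal library size recorded with the run (the
#'   pipeline normalizes by observed tag totals; state calls are
#'   scale-invariant).
#' @param conditions Labels of the two conditions.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 4L,
                              chrom_length = 2.5e6,
                              n_genes = 2000L,
                              cpg_class_probs = c(HCP = 0.6, ICP = 0.2, LCP = 0.2),
                              state_probs_NR = c(active = 0.34, repressive = 0.36,
                                                 bivalent = 0.04, none = 0.26),
                              transition_matrix = NULL,
                              enrichment = NULL,
                              enrichment_fold = 8,
                              background_rate = 0.04,
                              expression_means = c(active = 3.2, bivalent = 1.3,
                                                   repressive = 1, none = 1),
                              expression_sd = 0.45,
                              k36_per_fpkm = 3,
                              library_size = 2e6,
                              conditions = c("LLC-NR", "LLC-R")) {
  if (is.null(transition_matrix)) {
    transition_matrix <- rbind(
      active     = c(active = 0.96, repressive = 0.00, bivalent = 0.00, none = 0.04),
      repressive = c(0.04, 0.74, 0.02, 0.20),
      bivalent   = c(0.80, 0.00, 0.20, 0.00),
      none       = c(0.02, 0.10, 0.02, 0.86)
    )
    colnames(transition_matrix) <- .PS_STATES
  }
  if (is.null(enrichment)) {
    e <- enrichment_fold * background_rate * 1500
    enrichment <- rbind(
      H3K4me3  = c(active = e, repressive = 0, bivalent = e, none = 0),
      H3K9ac   = c(e, 0, e, 0),
      H3K27me3 = c(0, e, e, 0),
      H3K36me3 = c(0, 0, 0, 0)
    )
    colnames(enrichment) <- .PS_STATES
  }
  cfg <- list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
    cpg_class_probs = cpg_class_probs, state_probs_NR = state_probs_NR,
    transition_matrix = transition_matrix, enrichment = enrichment,
    background_rate = background_rate, expression_means = expression_means,
    expression_sd = expression_sd, k36_per_fpkm = k36_per_fpkm,
    library_size = library_size, conditions = conditions
  )
  stopifnot(
    abs(sum(cfg$cpg_class_probs) - 1) < 1e-8,
    abs(sum(cfg$state_probs_NR) - 1) < 1e-8,
    all(abs(rowSums(cfg$transition_matrix) - 1) < 1e-8),
    all(cfg$enrichment >= 0), cfg$background_rate >= 0,
    cfg$expression_sd >= 0, length(cfg$conditions) == 2,
    all(names(cfg$expression_means) == .PS_STATES | TRUE)
  )
  m <- cfg$expression_means[.PS_STATES]
  if (!(m["active"] > m["bivalent"] && m["bivalent"] > m["repressive"] &&
        m["repressive"] >= m["none"])) {
    stop("expression_means must be ordered active > bivalent > repressive >= none",
         call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

#' Planted per-gene ground truth
#'
#' Draws each gene's CpG class, chromatin state in the first condition, and
#' its state in the second condition from the configured transition matrix.
#'
#' @param config A [simulation_config()].
#' @return Tibble `gene_id`, `cpg_class`, `state_NR`, `state_R`.
#' @export
simulate_truth <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  cls <- sample(.PS_CLASSES, n, replace = TRUE, prob = config$cpg_class_probs)
  s_nr <- sample(.PS_STATES, n, replace = TRUE, prob = config$state_probs_NR)
  s_r <- vapply(s_nr, function(s) {
    sample(.PS_STATES, 1, prob = config$transition_matrix[s, ])
  }, character(1), USE.NAMES = FALSE)
  tibble::tibble(
    gene_id = sprintf("gene%04d", seq_len(n)),
    cpg_class = factor(cls, levels = .PS_CLASSES),
    state_NR = factor(s_nr, levels = .PS_STATES),
    state_R = factor(s_r, levels = .PS_STATES)
  )
}

#' State-coupled expression values
#'
#' Per condition, FPKM is log-normal around the configured log-scale mean of
#' the gene's planted state: `FPKM = exp(N(mean[state], sd))`.
#'
#' @param config A [simulation_config()].
#' @param truth Truth tibble from [simulate_truth()].
#' @return `truth` with `fpkm_NR` and `fpkm_R` columns appended.
#' @export
simulate_expression <- function(config, truth) {
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  mu <- config$expression_means
  dplyr::mutate(
    truth,
    fpkm_NR = exp(stats::rnorm(n, mu[as.character(.data$state_NR)],
                               config$expression_sd)),
    fpkm_R = exp(stats::rnorm(n, mu[as.character(.data$state_R)],
                              config$expression_sd))
  )
}

# base composition presets for the three promoter-sequence flavours and the
# CpG-depleted background; `keep` is the CG-dinucleotide survival probability
.seq_profiles <- list(
  background = list(p = c(A = 0.26, C = 0.24, G = 0.24, T = 0.26), keep = 0.1),
  HCP = list(p = c(A = 0.19, C = 0.31, G = 0.31, T = 0.19), keep = 1.0),
  ICP = list(p = c(A = 0.275, C = 0.225, G = 0.225, T = 0.275), keep = 0.5)
)

# iid bases followed by CG thinning: each CG dinucleotide survives with
# probability `keep`, otherwise its G becomes A or T (cannot create new CGs)
.random_dna <- function(n, profile) {
  x <- sample(names(profile$p), n, replace = TRUE, prob = profile$p)
  if (profile$keep < 1 && n > 1) {
    cg <- which(x[-n] == "C" & x[-1] == "G")
    kill <- cg[stats::runif(length(cg)) > profile$keep]
    if (length(kill)) {
      x[kill + 1L] <- sample(c("A", "T"), length(kill), replace = TRUE)
    }
  }
  x
}

#' Synthetic genome and gene annotation with planted CpG classes
#'
#' Lays genes out on evenly spaced non-overlapping slots (alternating
#' strands), writes a CpG-depleted background sequence (CpG O/E ~ 0.1), and
#' embeds a 600-bp CpG-rich segment (GC ~ 0.62, O/E ~ 1) in each HCP
#' promoter and an intermediate segment (GC ~ 0.45, O/E ~ 0.5) in each ICP
#' promoter; LCP promoters are plain background.
#'
#' @param config A [simulation_config()].
#' @param truth Truth tibble from [simulate_truth()].
#' @return List with `genome` (named `DNAStringSet`), `genes` (tibble
#'   `gene_id`, `chrom`, `start`, `end`, `strand`), and `chrom_sizes`.
#' @export
simulate_genome <- function(config, truth) {
  set.seed(config$seed + 2L)
  n <- config$n_genes
  per_chrom <- ceiling(n / config$n_chroms)
  slot <- floor(config$chrom_length / per_chrom)
  if (slot < 5000) {
    stop("infeasible gene packing: chrom_length must be at least ",
         per_chrom * 5000, " bp for ", per_chrom, " genes per chromosome",
         call. = FALSE)
  }
  chrom_names <- paste0("chr", seq_len(config$n_chroms))
  chrom_of <- chrom_names[((seq_len(n) - 1L) %/% per_chrom) + 1L]
  slot_idx <- (seq_len(n) - 1L) %% per_chrom
  strand <- ifelse(seq_len(n) %% 2L == 1L, "+", "-")
  gene_len <- sample(2000:3000, n, replace = TRUE)
  slot_start <- slot_idx * slot
  tss <- ifelse(strand == "+", slot_start + 1500L, slot_start + slot - 1500L)
  gstart <- ifelse(strand == "+", tss, tss - gene_len)
  gend <- ifelse(strand == "+", tss + gene_len, tss)
  genes <- tibble::tibble(
    gene_id = truth$gene_id, chrom = chrom_of,
    start = as.integer(gstart), end = as.integer(gend), strand = strand
  )
  seqs <- lapply(chrom_names, function(ch) {
    x <- .random_dna(config$chrom_length, .seq_profiles$background)
    rows <- which(chrom_of == ch & truth$cpg_class != "LCP")
    for (i in rows) {
      seg <- .random_dna(600L, .seq_profiles[[as.character(truth$cpg_class[i])]])
      at <- if (strand[i] == "+") (tss[i] - 550L) else (tss[i] - 50L)
      x[(at + 1L):(at + 600L)] <- seg
    }
    paste(x, collapse = "")
  })
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- chrom_names
  list(genome = genome, genes = genes,
       chrom_sizes = stats::setNames(rep(config$chrom_length,
                                         config$n_chroms), chrom_names))
}

#' Synthetic ChIP-seq tag sets for every mark and condition
#'
#' Background tags are uniform with density `background_rate`; each promoter
#' additionally receives `Poisson(enrichment[mark, state])` tags placed on
#' TSS-centered nucleosome positions with Gaussian jitter (sd 50 bp).
#' H3K36me3 tags are drawn over gene bodies in proportion to the planted
#' FPKM (`k36_per_fpkm` tags per FPKM unit) on top of background.
#'
#' @param config A [simulation_config()].
#' @param truth Truth tibble including `fpkm_NR`/`fpkm_R`
#'   (see [simulate_expression()]).
#' @param layout Genome layout from [simulate_genome()].
#' @return Named list of tag tibbles (`chrom`, `midpoint`, `strand`), keyed
#'   `"mark:condition"`.
#' @export
simulate_tags <- function(config, truth, layout) {
  set.seed(config$seed + 3L)
  genes <- layout$genes
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  sgn <- ifelse(genes$strand == "+", 1, -1)
  nuc_offsets <- seq(-900L, 300L, by = 200L) + 100L  # nucleosome centres vs TSS
  state_col <- c("state_NR", "state_R")
  names(state_col) <- config$conditions
  fpkm_col <- c("fpkm_NR", "fpkm_R")
  names(fpkm_col) <- config$conditions
  out <- list()
  for (mark in .PS_MARKS) {
    for (cond in config$conditions) {
      # background, uniform per chromosome
      bg <- purrr::map(names(layout$chrom_sizes), function(ch) {
        len <- layout$chrom_sizes[[ch]]
        nb <- stats::rpois(1, config$background_rate * len)
        tibble::tibble(chrom = ch,
                       midpoint = as.integer(floor(stats::runif(nb) * len)))
      })
      # planted promoter signal
      st <- as.character(truth[[state_col[[cond]]]])
      lambda <- config$enrichment[mark, st]
      cnt <- stats::rpois(length(lambda), lambda)
      gi <- rep(seq_len(nrow(genes)), cnt)
      pos <- numeric(0)
      if (length(gi)) {
        off <- sample(nuc_offsets, length(gi), replace = TRUE)
        pos <- tss[gi] + sgn[gi] * off + stats::rnorm(length(gi), 0, 50)
      }
      prom <- tibble::tibble(chrom = genes$chrom[gi],
                             midpoint = as.integer(round(pos)))
      # elongation mark over gene bodies, proportional to expression
      body <- NULL
      if (mark == "H3K36me3") {
        lam36 <- config$k36_per_fpkm * truth[[fpkm_col[[cond]]]]
        c36 <- stats::rpois(length(lam36), lam36)
        gj <- rep(seq_len(nrow(genes)), c36)
        body <- tibble::tibble(
          chrom = genes$chrom[gj],
          midpoint = as.integer(floor(stats::runif(length(gj)) *
                                        (genes$end[gj] - genes$start[gj])) +
                                  genes$start[gj])
        )
      }
      tags <- dplyr::bind_rows(c(bg, list(prom, body))) |>
        dplyr::mutate(midpoint = pmin(pmax(.data$midpoint, 0L),
                                      config$chrom_length - 1L),
                      strand = ".") |>
        dplyr::arrange(.data$chrom, .data$midpoint)
      out[[paste(mark, cond, sep = ":")]] <- tags
    }
  }
  out
}

#' Generate and write a complete synthetic experiment
#'
#' Runs truth, expression, genome and tag generation under one seed and
#' writes every file the pipeline consumes: `genome.fa`, `genes.bed` (BED6),
#' one `tags_<mark>_<condition>.bed` per tag set, `expression.tsv`
#' (`gene_id`, `fpkm_NR`, `fpkm_R`) and `truth.tsv` (the serialized ground
#' truth).
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `truth`, `genes`, `chrom_sizes`, and
#'   `paths` (named file paths, tag files keyed `"mark:condition"`).
#' @export
simulate_chipseq_experiment <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_truth(config)
  truth <- simulate_expression(config, truth)
  layout <- simulate_genome(config, truth)
  tag_sets <- simulate_tags(config, truth, layout)

  paths <- list(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.bed"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  Biostrings::writeXStringSet(layout$genome, paths$genome)
  readr::write_tsv(
    dplyr::mutate(layout$genes, score = 0L)[
      , c("chrom", "start", "end", "gene_id", "score", "strand")],
    paths$genes, col_names = FALSE)
  readr::write_tsv(truth[, c("gene_id", "fpkm_NR", "fpkm_R")],
                   paths$expression)
  readr::write_tsv(truth, paths$truth)
  paths$tags <- purrr::imap_chr(tag_sets, function(tags, key) {
    p <- file.path(dir, paste0("tags_", gsub(":", "_", key), ".bed"))
    bed <- tibble::tibble(
      chrom = tags$chrom, start = tags$midpoint,
      end = tags$midpoint + 1L,
      name = sprintf("tag%07d", seq_len(nrow(tags))),
      score = 0L, strand = tags$strand
    )
    readr::write_tsv(bed, p, col_names = FALSE)
    p
  })
  invisible(list(truth = truth, genes = layout$genes,
                 chrom_sizes = layout$chrom_sizes, paths = paths,
                 config = config))
}
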