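random_spacers <- function(n, exclude = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    cand <- vapply(seq_len(need * 2L), function(i) {
      paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE),
            collapse = "")
    }, "")
    cand <- setdiff(unique(cand), c(out, exclude))
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

#' Simulate the focused gene-panel sgRNA library
#'
#' Emulates a focused dropout-screen library of 36 RNA/DNA-methylation
#' machinery genes with 25 guides each (900 gene-targeting guides), plus
#' 41 negative-control guides targeting non-essential sequences and 22
#' positive-control guides targeting common essential genes (MYC, BRD4 and
#' the like) -- 963 guides in total by default.
#'
#' @param seed integer seed.
#' @param n_genes,guides_per_gene,n_neg,n_pos composition parameters.
#' @return An [sgrna_library()].
#' @export
simulate_panel_library <- function(seed, n_genes = 36, guides_per_gene = 25,
                                   n_neg = 41, n_pos = 22) {
  set.seed(seed)
  genes <- sprintf("GENE%02d", seq_len(n_genes))
  n_total <- n_genes * guides_per_gene + n_neg + n_pos
  spacers <- random_spacers(n_total)
  records <- data.frame(
    guide_id = c(
      sprintf("%s_sg%02d", rep(genes, each = guides_per_gene),
              rep(seq_len(guides_per_gene), n_genes)),
      sprintf("neg_%03d", seq_len(n_neg)),
      sprintf("pos_%03d", seq_len(n_pos))
    ),
    spacer = spacers,
    category = c(rep("gene_panel", n_genes * guides_per_gene),
                 rep("negative_control", n_neg),
                 rep("positive_control", n_pos)),
    target_gene = c(rep(genes, each = guides_per_gene),
                    rep("", n_neg),
                    rep(c("MYC", "BRD4"), length.out = n_pos)),
    stringsAsFactors = FALSE
  )
  sgrna_library(records, name = "panel")
}

#' Fabricate a coding sequence with a forced PAM count
#'
#' Builds a synthetic CDS over an A/T background (which contains no NGG or
#' CCN sites of its own) and plants isolated `GG` dinucleotides so that
#' [enumerate_tiling_guides()] recovers exactly `n_guides` plus-strand
#' protospacers at near-uniform spacing. By default 416 guides over a
#' 3,120-nt CDS, i.e. a tiling density of 7.5 bp (2.5 amino acids) per
#' guide.
#'
#' @param seed integer seed.
#' @param n_guides number of tiling guides to force.
#' @param cds_length CDS length in nt (multiple of 3).
#' @return List with `cds` (character), `cut_sites` (planted coding-strand
#'   cut positions) and `protein_length`.
#' @export
simulate_tiling_cds <- function(seed, n_guides = 416, cds_length = 3120) {
  if (cds_length %% 3L != 0L) stop("cds_length must be a multiple of 3")
  set.seed(seed)
  # cut site c needs protospacer 21..c+3 inside the CDS: 17 <= c <= L - 6
  lo <- 17L
  hi <- cds_length - 6L
  if (n_guides > (hi - lo) %/% 7L + 1L) stop("too many guides to place")
  cuts <- unique(round(seq(lo, hi, length.out = n_guides)))
  if (length(cuts) != n_guides || any(diff(cuts) < 3L)) {
    stop("cannot place ", n_guides, " isolated PAMs in ", cds_length, " nt")
  }
  repeat {
    chars <- sample(c("A", "T"), cds_length, replace = TRUE)
    chars[cuts + 5L] <- "G"  # PAM starts at c + 4; GG occupies c+5, c+6
    chars[cuts + 6L] <- "G"
    cds <- paste(chars, collapse = "")
    guides <- enumerate_tiling_guides(cds)
    if (nrow(guides) == n_guides && !anyDuplicated(guides$spacer)) break
  }
  list(cds = cds, cut_sites = cuts, protein_length = cds_length %/% 3L)
}

#' Simulate the gene-tiling sgRNA library
#'
#' Tiling guides enumerated from a fabricated CDS (see
#' [simulate_tiling_cds()]), plus 40 negative and 22 positive controls --
#' 478 guides in total by default.
#'
#' @param seed integer seed.
#' @param n_tiling,n_neg,n_pos composition parameters.
#' @param cds_length CDS length in nt.
#' @param gene tiled gene label.
#' @return List with `library` (an [sgrna_library()]), `cds`,
#'   `protein_length`.
#' @export
simulate_tiling_library <- function(seed, n_tiling = 416, n_neg = 40,
                                    n_pos = 22, cds_length = 3120,
                                    gene = "ZNF217") {
  cds <- simulate_tiling_cds(seed, n_guides = n_tiling,
                             cds_length = cds_length)
  tiles <- enumerate_tiling_guides(cds$cds, gene = gene)
  controls <- data.frame(
    guide_id = c(sprintf("neg_%03d", seq_len(n_neg)),
                 sprintf("pos_%03d", seq_len(n_pos))),
    spacer = random_spacers(n_neg + n_pos, exclude = tiles$spacer),
    category = c(rep("negative_control", n_neg),
                 rep("positive_control", n_pos)),
    target_gene = c(rep("", n_neg), rep(c("MYC", "BRD4"),
                                        length.out = n_pos)),
    cds_cut_nt = NA_integer_,
    strand = NA_character_,
    stringsAsFactors = FALSE
  )
  lib <- sgrna_library(rbind(tiles, controls), name = "tiling")
  list(library = lib, cds = cds$cds, protein_length = cds$protein_length)
}

#' Ground-truth parameters of a simulated dropout screen
#'
#' Holds the per-guide fitness effects (log2 units per population doubling,
#' <= 0 for depleting guides), the total doublings of the amplification
#' phase, sequencing coverage and replicate count. Defaults mirror the
#' screen design being emulated: amplification to 5,000-fold
#' (`doublings = log2(5000) ~ 12.3`, the lower bound of the 5,000-10,000x
#' range), a minimum of 1,000x library coverage, and 3 biological
#' replicates. Negative-control guides must carry effect 0.
#'
#' @param library an [sgrna_library()].
#' @param effects named numeric vector of per-guide effects (log2 per
#'   doubling); guides absent from the vector get 0.
#' @param doublings total population doublings.
#' @param coverage reads per guide per sample (>= 1000 when emulating the
#'   study design).
#' @param replicates number of biological replicates.
#' @param seed integer seed.
#' @return A `screen_truth` list.
#' @export
screen_truth <- function(library, effects = numeric(0),
                         doublings = log2(5000), coverage = 1000,
                         replicates = 3, seed = 1) {
  if (coverage <= 0) stop("coverage must be positive")
  eff <- stats::setNames(numeric(nrow(library)), library$guide_id)
  if (length(effects) > 0L) {
    unknown <- setdiff(names(effects), library$guide_id)
    if (length(unknown) > 0L) {
      stop("effects for unknown guides: ", paste(unknown, collapse = ", "))
    }
    eff[names(effects)] <- effects
  }
  neg <- library$category == "negative_control"
  if (any(eff[neg] != 0)) stop("negative-control effects must be 0")
  structure(list(effects = eff, doublings = doublings, coverage = coverage,
                 replicates = replicates, seed = seed),
            class = "screen_truth")
}

#' Default effect assignment for a panel screen
#'
#' Gene-panel guides of the named essential genes and all positive-control
#' guides receive the given depleting effect; everything else is neutral.
#'
#' @param library an [sgrna_library()].
#' @param essential_genes character vector of essential panel genes.
#' @param effect fitness effect per doubling for essential-gene guides.
#' @param positive_effect effect for positive-control guides.
#' @return Named effect vector for [screen_truth()].
#' @export
panel_effects <- function(library, essential_genes = character(0),
                          effect = -0.5, positive_effect = -0.5) {
  eff <- stats::setNames(numeric(nrow(library)), library$guide_id)
  eff[library$category == "positive_control"] <- positive_effect
  eff[library$category == "gene_panel" &
        library$target_gene %in% essential_genes] <- effect
  eff
}

#' Planted per-guide effects for a tiling screen
#'
#' Guide effect equals the effect of the annotated feature containing its
#' cut residue (0 outside all features), plus Gaussian noise. Positive
#' controls receive `positive_effect`; negative controls stay 0.
#'
#' @param library an [sgrna_library()] with tiling guides.
#' @param protein_length residues.
#' @param features data frame `label`, `start_res`, `end_res`, `effect`
#'   (non-overlapping intervals).
#' @param noise_sd Gaussian noise sd on tiling-guide effects.
#' @param positive_effect effect of positive-control guides.
#' @param seed integer seed.
#' @return Named effect vector for [screen_truth()].
#' @export
simulate_tiling_truth <- function(library, protein_length, features,
                                  noise_sd = 0, positive_effect = -0.5,
                                  seed = 1) {
  cov <- rep(0L, protein_length)
  for (i in seq_len(nrow(features))) {
    span <- features$start_res[i]:features$end_res[i]
    if (any(cov[span] != 0L)) stop("overlapping features")
    cov[span] <- i
  }
  set.seed(seed)
  eff <- stats::setNames(numeric(nrow(library)), library$guide_id)
  is_tiling <- library$category == "tiling"
  res <- cut_to_residue(library$cds_cut_nt[is_tiling], protein_length)
  feat <- cov[res]
  base <- ifelse(feat > 0L, features$effect[pmax(feat, 1L)], 0)
  eff[is_tiling] <- base + stats::rnorm(sum(is_tiling), 0, noise_sd)
  eff[library$category == "positive_control"] <- positive_effect
  eff
}

#' Simulate a dropout screen
#'
#' Initial guide abundances are log-normal (sd 0.5) and shared across
#' replicates up to a small log-normal replicate jitter (sd 0.1); final
#' abundances are `initial x 2^(effect x doublings)`; each sample's read
#' counts are one multinomial draw of `coverage x library size` reads from
#' the sample's relative abundances. The multinomial draws are the emitted
#' read counts (the read model is error-free), so the returned count matrix
#' is simultaneously the bookkeeping truth for oracle tests;
#' [write_screen_fastq()] materializes the same counts as FASTQ.
#'
#' @param library an [sgrna_library()].
#' @param truth a [screen_truth()].
#' @return A `screen_sim`: list with `counts` (guide x sample integer
#'   matrix), `sample_sheet`, `expected_freq` (guide x sample matrix of
#'   true sampling frequencies), `library`, `truth`.
#' @export
simulate_screen <- function(library, truth) {
  set.seed(truth$seed)
  n <- nrow(library)
  n_reads <- round(truth$coverage * n)
  growth <- 2^(truth$effects * truth$doublings)
  abundance <- exp(stats::rnorm(n, 0, 0.5))
  samples <- list()
  sheet <- list()
  efreq <- list()
  for (r in seq_len(truth$replicates)) {
    jitter <- exp(stats::rnorm(n, 0, 0.1))
    w0 <- abundance * jitter
    w1 <- w0 * growth
    f0 <- w0 / sum(w0)
    f1 <- w1 / sum(w1)
    for (tp in c("initial", "final")) {
      nm <- sprintf("rep%d_%s", r, tp)
      f <- if (tp == "initial") f0 else f1
      samples[[nm]] <- as.integer(stats::rmultinom(1L, n_reads, f))
      efreq[[nm]] <- f
      sheet[[nm]] <- data.frame(sample = nm, replicate = r, timepoint = tp,
                                stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, samples)
  rownames(counts) <- library$guide_id
  expected_freq <- do.call(cbind, efreq)
  rownames(expected_freq) <- library$guide_id
  structure(list(
    counts = counts,
    sample_sheet = do.call(rbind, c(sheet, list(make.row.names = FALSE))),
    expected_freq = expected_freq,
    library = library,
    truth = truth
  ), class = "screen_sim")
}

READ_PREFIX <- "TTGTGGAAAG"
READ_SUFFIX <- "AAAAAAGCTTGGCGTAACTAGATCTTGAGACAAATG"

#' Reads of one simulated sample
#'
#' Deterministic read layout: a fixed 10-nt vector prefix, the `CACCG`
#' cloning scar, the 20-nt spacer, the `GTTT` scaffold start, and a fixed
#' suffix padding to 75 nt. Reads are emitted in library order.
#'
#' @param sim a `screen_sim`.
#' @param sample sample name (a column of `sim$counts`).
#' @return Character vector of read sequences.
#' @export
simulated_reads <- function(sim, sample) {
  counts <- sim$counts[, sample]
  reads <- paste0(READ_PREFIX, "CACCG", sim$library$spacer, "GTTT",
                  READ_SUFFIX)
  rep(reads, counts)
}

#' Write a simulated screen as FASTQ files
#'
#' One plain FASTQ per sample (`<sample>.fastq`), 75-nt reads with constant
#' quality strings, plus `truth_counts.tsv` holding the emitted per-sample
#' draw counts. Byte-identical on rerun for the same `screen_sim`.
#'
#' @param sim a `screen_sim`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written FASTQ paths.
#' @export
write_screen_fastq <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  qual <- strrep("I", 75L)
  paths <- vapply(colnames(sim$counts), function(sample) {
    reads <- simulated_reads(sim, sample)
    ids <- sprintf("@%s_read%07d", sample, seq_along(reads))
    path <- file.path(dir, paste0(sample, ".fastq"))
    writeLines(rbind(ids, reads, "+", qual), path)
    path
  }, "")
  truth <- data.frame(guide_id = rownames(sim$counts), sim$counts,
                      check.names = FALSE)
  utils::write.table(truth, file.path(dir, "truth_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Simulate a multi-species protein alignment with planted conservation
#'
#' Invariant columns share one residue across all rows; variable columns
#' draw residues independently from the background distribution per
#' sequence, with optional gaps injected into non-reference rows. The
#' reference row never carries a gap, so the profile covers the full
#' reference length.
#'
#' @param seed integer seed.
#' @param length alignment columns.
#' @param n_sequences number of species (default 8).
#' @param fraction_invariant fraction of columns planted invariant.
#' @param gap_rate per-cell gap probability in variable columns of
#'   non-reference rows.
#' @param reference_id name of the reference row.
#' @return List with `alignment` (a [protein_alignment()]) and `truth`
#'   (data frame `column`, `invariant`).
#' @export
simulate_alignment <- function(seed, length = 500, n_sequences = 8,
                               fraction_invariant = 0.5, gap_rate = 0.05,
                               reference_id = "human") {
  if (fraction_invariant < 0 || fraction_invariant > 1) {
    stop("fraction_invariant must lie in [0, 1]")
  }
  set.seed(seed)
  bg <- blosum62_background()
  species <- c(reference_id, "chimp", "rhesus", "horse", "pig", "cat",
               "hamster", "mouse", sprintf("sp%02d", seq_len(n_sequences)))
  species <- species[seq_len(n_sequences)]
  n_inv <- round(fraction_invariant * length)
  invariant <- rep(FALSE, length)
  invariant[sample.int(length, n_inv)] <- TRUE
  m <- matrix("", nrow = n_sequences, ncol = length,
              dimnames = list(species, NULL))
  for (i in seq_len(length)) {
    if (invariant[i]) {
      m[, i] <- sample(AA20, 1L, prob = bg)
    } else {
      col <- sample(AA20, n_sequences, replace = TRUE, prob = bg)
      gap <- c(FALSE, stats::runif(n_sequences - 1L) < gap_rate)
      col[gap] <- "-"
      m[, i] <- col
    }
  }
  seqs <- apply(m, 1L, paste, collapse = "")
  list(alignment = protein_alignment(seqs, reference_id),
       truth = data.frame(column = seq_len(length), invariant = invariant))
}

#' Simulate a gene model table
#'
#' Genes on one chromosome with well-separated TSSs (20 kb apart) and
#' random strands.
#'
#' @param n number of genes.
#' @param seed integer seed.
#' @return A [gene_models()] table.
#' @export
simulate_genes <- function(n, seed = 1) {
  set.seed(seed)
  gene_models(data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    chrom = "chr1",
    tss = 5000L + 20000L * (seq_len(n) - 1L),
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  ))
}

#' Plant target classes and DE status over a gene set
#'
#' @param genes a [gene_models()] table.
#' @param seed integer seed.
#' @param p_bound fraction of genes bound by the factor.
#' @param p_dependent fraction of bound genes that are CoREST-dependent
#'   (default 1/3, emulating the roughly two-thirds-independent split of
#'   the design being modelled).
#' @param p_up,p_down marginal probabilities of up/down DE status.
#' @return Data frame `gene_id`, `class`, `de_status`.
#' @export
simulate_planted_classes <- function(genes, seed = 1, p_bound = 0.5,
                                     p_dependent = 1 / 3, p_up = 0.1,
                                     p_down = 0.06) {
  set.seed(seed)
  n <- nrow(genes)
  bound <- stats::runif(n) < p_bound
  dep <- bound & stats::runif(n) < p_dependent
  class <- ifelse(!bound, "unbound",
                  ifelse(dep, "corest_dependent", "corest_independent"))
  u <- stats::runif(n)
  de_status <- ifelse(u < p_up, "up",
                      ifelse(u < p_up + p_down, "down", "none"))
  data.frame(gene_id = genes$gene_id, class = class, de_status = de_status,
             stringsAsFactors = FALSE)
}

#' Simulate occupancy peak sets and a DE table from planted classes
#'
#' Every gene receives a promoter peak per factor and condition whose
#' signals realize its planted class under the default classification
#' thresholds, multiplied by log-normal noise: bound genes lose 5-fold
#' factor occupancy upon knockdown; CoREST-dependent genes additionally
#' lose 5-fold LSD1 signal or gain 5-fold in one histone mark
#' (H3K4me1/H3K4me2/H3K27ac, chosen at random per gene); unbound and
#' CoREST-independent genes keep flat ratios. A non-significant decoy peak
#' (FDR 0.2) with a large score is planted in every promoter to exercise
#' the peak-FDR filter. DE fold changes are 4x (up), 0.25x (down) or ~1
#' (none, non-significant), with the same log-normal noise.
#'
#' @param genes a [gene_models()] table.
#' @param planted data frame from [simulate_planted_classes()].
#' @param noise_sd log-normal noise sd (0 for noiseless identity).
#' @param seed integer seed.
#' @param base_signal control-condition peak score scale.
#' @return List with `peak_sets` (named list of narrowPeak-layout data
#'   frames, keys `<factor>_<condition>`), `de_table`, `genes`, `truth`
#'   (the planted table).
#' @export
simulate_occupancy_and_de <- function(genes, planted, noise_sd = 0.2,
                                      seed = 1, base_signal = 100) {
  set.seed(seed)
  stopifnot(identical(genes$gene_id, planted$gene_id))
  n <- nrow(genes)
  factors <- c("ZNF217", "LSD1", "H3K4me1", "H3K4me2", "H3K27ac")
  bound <- planted$class != "unbound"
  dep <- planted$class == "corest_dependent"
  # knockdown/control signal ratios realizing each class
  ratio <- matrix(1, nrow = n, ncol = length(factors),
                  dimnames = list(genes$gene_id, factors))
  ratio[bound, "ZNF217"] <- 0.2
  mechanism <- sample(c("LSD1", "H3K4me1", "H3K4me2", "H3K27ac"), n,
                      replace = TRUE)
  for (i in which(dep)) {
    if (mechanism[i] == "LSD1") {
      ratio[i, "LSD1"] <- 0.2
    } else {
      ratio[i, mechanism[i]] <- 5
    }
  }
  lognoise <- function(k) exp(stats::rnorm(k, 0, noise_sd))
  peak_sets <- list()
  for (f in factors) {
    ctrl <- base_signal * lognoise(n)
    kd <- base_signal * ratio[, f] * lognoise(n)
    for (cond in c("control", "kd")) {
      score <- if (cond == "control") ctrl else kd
      peak_sets[[paste0(f, "_", cond)]] <- data.frame(
        chrom = rep(genes$chrom, 2L),
        start = rep(genes$tss - 50L, 2L),
        end = rep(genes$tss + 50L, 2L),
        name = paste0(f, "_", cond, "_", rep(genes$gene_id, 2L),
                      c(rep("", n), rep("_decoy", n))),
        score = c(score, rep(10 * base_signal, n)),
        strand = ".",
        signal_value = c(score, rep(10 * base_signal, n)),
        p_value = 4,
        fdr = c(rep(0.001, n), rep(0.2, n)),
        peak_offset = 50L,
        stringsAsFactors = FALSE
      )
    }
  }
  fc <- rep(1, n)
  fc[planted$de_status == "up"] <- 4
  fc[planted$de_status == "down"] <- 0.25
  de_table <- data.frame(
    gene_id = genes$gene_id,
    fold_change = fc * lognoise(n),
    significant = planted$de_status != "none",
    stringsAsFactors = FALSE
  )
  list(peak_sets = peak_sets, de_table = de_table, genes = genes,
       truth = planted)
}
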