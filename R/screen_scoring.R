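#' Per-guide log10 fold changes from initial to final timepoints
#'
#' The raw CRISPR score of a guide is the log10 fold change of its library
#' frequency from the "initial" to the "final" sampling point of the screen,
#' computed per replicate. A small frequency pseudocount guards against
#' minus infinity when a guide drops out completely; by default it is
#' 1/(total matched reads) of each sample, i.e. one read's worth of
#' frequency.
#'
#' @param freq guide x sample frequency matrix (see [guide_frequencies()]).
#' @param sample_sheet data frame with columns `sample`, `replicate`,
#'   `timepoint` (`initial`/`final`); every replicate needs exactly one of
#'   each timepoint.
#' @param pseudocount frequency offset added to both timepoints before the
#'   log ratio. A scalar, or a named per-sample vector; `NULL` (default)
#'   uses 1/colSums(counts) when `counts` is supplied, else 1e-6.
#' @param counts optional guide x sample count matrix used to derive the
#'   default per-sample pseudocount.
#' @return guide x replicate matrix of raw log10 fold changes.
#' @export
log10_fold_change <- function(freq, sample_sheet, pseudocount = NULL,
                              counts = NULL) {
  reps <- unique(sample_sheet$replicate)
  if (is.null(pseudocount)) {
    if (!is.null(counts)) {
      totals <- colSums(counts)
      pseudocount <- stats::setNames(1 / pmax(totals, 1), colnames(counts))
    } else {
      pseudocount <- 1e-6
    }
  }
  eps_for <- function(sample) {
    if (length(pseudocount) == 1L && is.null(names(pseudocount))) {
      pseudocount
    } else {
      unname(pseudocount[sample])
    }
  }
  cols <- lapply(reps, function(r) {
    rows <- sample_sheet[sample_sheet$replicate == r, , drop = FALSE]
    ini <- rows$sample[rows$timepoint == "initial"]
    fin <- rows$sample[rows$timepoint == "final"]
    if (length(ini) != 1L || length(fin) != 1L) {
      stop("replicate ", r, " must have exactly one initial and one final sample")
    }
    log10((freq[, fin] + eps_for(fin)) / (freq[, ini] + eps_for(ini)))
  })
  lfc <- do.call(cbind, cols)
  colnames(lfc) <- as.character(reps)
  rownames(lfc) <- rownames(freq)
  lfc
}

#' Panel-scheme normalization: negative-control mean anchored at 0
#'
#' For the focused gene-panel screen, per-replicate scores are normalized
#' against the average log10 fold change of the negative-control sgRNAs
#' targeting non-essential sequences, which is thereby set at 0.0.
#'
#' @param raw_lfc guide x replicate matrix from [log10_fold_change()].
#' @param library an [sgrna_library()] with rows matching `raw_lfc` rows.
#' @return Normalized guide x replicate matrix.
#' @export
normalize_panel <- function(raw_lfc, library) {
  neg <- match_controls(raw_lfc, library, "negative_control")
  shift <- colMeans(raw_lfc[neg, , drop = FALSE])
  if (any(!is.finite(shift))) stop("non-finite negative-control mean")
  sweep(raw_lfc, 2L, shift, "-")
}

#' Tiling-scheme normalization: dual control-median anchors at 0 and -1
#'
#' For the gene-tiling screen, per-replicate scores are rescaled so the
#' median of negative-control sgRNAs sits at 0.0 and the median of
#' positive-control sgRNAs (targeting common essential genes) sits at -1.0:
#' `score = (raw - median_neg) / (median_neg - median_pos)`.
#'
#' @inheritParams normalize_panel
#' @return Normalized guide x replicate matrix.
#' @export
normalize_tiling <- function(raw_lfc, library) {
  neg <- match_controls(raw_lfc, library, "negative_control")
  pos <- match_controls(raw_lfc, library, "positive_control")
  m_neg <- apply(raw_lfc[neg, , drop = FALSE], 2L, stats::median)
  m_pos <- apply(raw_lfc[pos, , drop = FALSE], 2L, stats::median)
  if (any(m_neg == m_pos)) {
    stop("control medians coincide; dual anchors are degenerate")
  }
  sweep(sweep(raw_lfc, 2L, m_neg, "-"), 2L, m_neg - m_pos, "/")
}

match_controls <- function(mat, library, category) {
  idx <- match(rownames(mat), library$guide_id)
  if (anyNA(idx)) stop("score rows not found in library")
  which(library$category[idx] == category) -> sel
  if (length(sel) == 0L) stop("no ", category, " guides present")
  sel
}

#' Aggregate normalized scores across replicates
#'
#' @param normalized guide x replicate matrix.
#' @return Data frame `guide_id`, `score_mean` (arithmetic mean across
#'   replicates), `score_sd`.
#' @export
aggregate_replicates <- function(normalized) {
  data.frame(
    guide_id = rownames(normalized),
    score_mean = rowMeans(normalized),
    score_sd = apply(normalized, 1L, stats::sd),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Score a screen end-to-end
#'
#' Convenience wrapper: frequencies, per-replicate log10 fold changes with
#' the per-sample default pseudocount, control-anchored normalization under
#' the chosen scheme, and replicate aggregation. Guides with zero counts at
#' every timepoint of every replicate are dropped from scoring and reported.
#'
#' @param counts `count_table` or guide x sample count matrix.
#' @param sample_sheet data frame `sample`, `replicate`, `timepoint`.
#' @param library an [sgrna_library()].
#' @param scheme `"panel_anchor"` (negative mean at 0) or `"dual_anchor"`
#'   (negative median 0, positive median -1).
#' @param pseudocount see [log10_fold_change()].
#' @return A `score_table`: list with `raw_lfc`, `normalized`, `aggregated`,
#'   `scheme`, `dropped` (guide ids with all-zero counts).
#' @export
score_screen <- function(counts, sample_sheet, library,
                         scheme = c("panel_anchor", "dual_anchor"),
                         pseudocount = NULL) {
  scheme <- match.arg(scheme)
  m <- if (inherits(counts, "count_table")) counts$counts else as.matrix(counts)
  dropped <- rownames(m)[rowSums(m) == 0]
  keep <- rowSums(m) > 0
  fr <- guide_frequencies(m)
  lfc <- log10_fold_change(fr$freq, sample_sheet,
                           pseudocount = pseudocount, counts = m)
  lfc <- lfc[keep, , drop = FALSE]
  normalized <- switch(scheme,
    panel_anchor = normalize_panel(lfc, library),
    dual_anchor = normalize_tiling(lfc, library)
  )
  structure(list(
    raw_lfc = lfc,
    normalized = normalized,
    aggregated = aggregate_replicates(normalized),
    scheme = scheme,
    dropped = dropped
  ), class = "score_table")
}

#' Rank genes by a robust-rank-aggregation order statistic
#'
#' A simplified single-level implementation of the alpha-RRA idea used for
#' negative-selection CRISPR screens: guides are ranked ascending by
#' aggregated score (most depleted first) and converted to percentiles
#' u = rank/N (average ranks for ties). For each gene, only its guides with
#' u <= alpha are kept; with m such guides and sorted percentiles
#' u(1) <= ... <= u(m), the gene score is
#' rho = min_k pbeta(u(k), k, m - k + 1). Genes with no guide under the
#' alpha cutoff get rho = 1. Significance is a permutation tail
#' probability: guide labels are reassigned at random B times and
#' p = (1 + #\{rho* <= rho\}) / (B + 1). This follows the ranking principle
#' of MAGeCK's alpha-RRA but is not a bit-compatible reimplementation.
#'
#' @param aggregated data frame `guide_id`, `score_mean` (from
#'   [aggregate_replicates()] or a `score_table$aggregated`).
#' @param library an [sgrna_library()]; only `gene_panel` guides enter the
#'   per-gene statistic, but all scored guides define the percentiles.
#' @param alpha percentile cutoff in (0, 1]; default 0.25.
#' @param permutations number of label permutations B (>= 100).
#' @param seed integer seed for the permutation null.
#' @return Data frame `gene`, `n_guides`, `rra_score`, `p_value`, `rank`,
#'   sorted by rank; attributes record `alpha`, `permutations`, `seed`.
#' @export
rra_gene_rank <- function(aggregated, library, alpha = 0.25,
                          permutations = 10000, seed = 1) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (permutations < 100) stop("need at least 100 permutations")
  idx <- match(aggregated$guide_id, library$guide_id)
  if (anyNA(idx)) stop("scored guides not found in library")
  gene <- library$target_gene[idx]
  panel <- library$category[idx] == "gene_panel"
  u <- rank(aggregated$score_mean, ties.method = "average") /
    nrow(aggregated)

  rho_of <- function(uu) {
    sel <- sort(uu[uu <= alpha])
    m <- length(sel)
    if (m == 0L) return(1)
    min(stats::pbeta(sel, seq_len(m), m - seq_len(m) + 1L))
  }

  genes <- sort(unique(gene[panel]))
  n_guides <- vapply(genes, function(g) sum(panel & gene == g), integer(1))
  rho <- vapply(genes, function(g) rho_of(u[panel & gene == g]), numeric(1))

  set.seed(seed)
  p_value <- numeric(length(genes))
  for (size in unique(n_guides)) {
    null_rho <- vapply(seq_len(permutations), function(b) {
      rho_of(sample(u, size))
    }, numeric(1))
    sel <- n_guides == size
    p_value[sel] <- vapply(rho[sel], function(r) {
      (1 + sum(null_rho <= r)) / (permutations + 1)
    }, numeric(1))
  }

  ord <- order(rho, p_value, genes)
  out <- data.frame(
    gene = genes, n_guides = n_guides, rra_score = rho, p_value = p_value,
    stringsAsFactors = FALSE, row.names = NULL
  )[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "permutations") <- permutations
  attr(out, "seed") <- seed
  out
}

#' Control behaviour summary of a scored screen
#'
#' Reports mean and median aggregated scores for positive- and
#' negative-control guides and a one-sided Wilcoxon rank-sum test of the
#' screen's key sanity property: positive controls (targeting common
#' essential genes) deplete, negative controls do not.
#'
#' @param aggregated data frame `guide_id`, `score_mean`.
#' @param library an [sgrna_library()] containing both control categories.
#' @return List with `summary` (per-category mean/median/n) and `test`
#'   (the `htest` from `wilcox.test(pos, neg, alternative = "less")`).
#' @export
control_behavior_report <- function(aggregated, library) {
  idx <- match(aggregated$guide_id, library$guide_id)
  cat_of <- library$category[idx]
  pos <- aggregated$score_mean[cat_of == "positive_control"]
  neg <- aggregated$score_mean[cat_of == "negative_control"]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both control categories must be present")
  }
  test <- stats::wilcox.test(pos, neg, alternative = "less", exact = FALSE)
  list(
    summary = data.frame(
      category = c("positive_control", "negative_control"),
      n = c(length(pos), length(neg)),
      mean = c(mean(pos), mean(neg)),
      median = c(stats::median(pos), stats::median(neg)),
      stringsAsFactors = FALSE
    ),
    test = test
  )
}
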