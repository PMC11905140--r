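#' Map a coding-strand cut position to a protein residue
#'
#' Residues are indexed 1-based over trinucleotide codons, so nucleotides
#' 1-3 belong to residue 1: `residue = ceiling(nt / 3)`.
#'
#' @param cds_cut_nt coding-strand nucleotide position(s), 1-based.
#' @param protein_length protein length in residues (bounds check).
#' @return Integer residue position(s).
#' @export
cut_to_residue <- function(cds_cut_nt, protein_length) {
  if (any(cds_cut_nt < 1L | cds_cut_nt > 3L * protein_length)) {
    stop("cut position outside 1..", 3L * protein_length)
  }
  as.integer(ceiling(cds_cut_nt / 3))
}

#' Average guide scores within each residue
#'
#' @param scores numeric guide scores.
#' @param residues integer residue assignment per guide.
#' @return Data frame `residue`, `score` (arithmetic mean of the guides cut
#'   at that residue), `support` (guide count); residues with no guide are
#'   absent.
#' @export
per_residue_average <- function(scores, residues) {
  if (length(scores) == 0L) stop("no guide scores")
  stopifnot(length(scores) == length(residues))
  agg <- tapply(scores, residues, mean)
  support <- tapply(scores, residues, length)
  data.frame(
    residue = as.integer(names(agg)),
    score = as.numeric(agg),
    support = as.integer(support),
    row.names = NULL
  )
}

#' Gaussian kernel smoothing of a per-residue score map
#'
#' Nadaraya-Watson smoothing over the protein axis: for every residue t in
#' 1..protein_length,
#' `score(t) = sum_j w(t,j) s_j / sum_j w(t,j)` over observed residues j,
#' with Gaussian weights `w(t,j) = exp(-(t-j)^2 / (2 sigma^2))`. Weights are
#' renormalized by their own sum, so boundaries use the same truncated
#' one-sided kernel and the output is always a convex combination of the
#' inputs (extremes bounded by input extremes; constants preserved).
#'
#' @param residue_scores data frame `residue`, `score` (and optionally
#'   `support`) from [per_residue_average()].
#' @param sigma kernel bandwidth in residues (> 0); default 5.
#' @param protein_length protein length in residues.
#' @return A `tiling_profile`: data frame `residue`, `score`, `support`
#'   (contributing-guide count at that exact residue, 0 where none), with
#'   attributes `sigma` and `protein_length`.
#' @export
smooth_profile <- function(residue_scores, sigma = 5, protein_length) {
  if (nrow(residue_scores) == 0L) stop("empty residue score map")
  if (sigma <= 0) stop("sigma must be positive")
  t_grid <- seq_len(protein_length)
  j <- residue_scores$residue
  s <- residue_scores$score
  # protein_length x n_observed weight matrix; profiles are short (<= ~1200
  # residues) so the dense outer product is the clearest implementation
  w <- exp(-outer(t_grid, j, "-")^2 / (2 * sigma^2))
  smoothed <- as.numeric((w %*% s) / rowSums(w))
  support <- integer(protein_length)
  if ("support" %in% names(residue_scores)) {
    support[j] <- residue_scores$support
  } else {
    support[j] <- 1L
  }
  structure(
    data.frame(residue = t_grid, score = smoothed, support = support),
    sigma = sigma, protein_length = protein_length,
    class = c("tiling_profile", "data.frame")
  )
}

#' Build a smoothed tiling profile from scored tiling guides
#'
#' Order of operations: guide scores are first averaged within each residue
#' (so dense regions do not dominate by guide count), then Gaussian
#' smoothed. `average_first = FALSE` smooths raw guide-level points instead
#' (each guide one observation at its cut residue).
#'
#' @param aggregated data frame `guide_id`, `score_mean`.
#' @param library an [sgrna_library()] with tiling guides carrying
#'   `cds_cut_nt`.
#' @param protein_length residues.
#' @param sigma kernel bandwidth in residues.
#' @param average_first average within residues before smoothing (default).
#' @return A `tiling_profile` (see [smooth_profile()]).
#' @export
tiling_profile <- function(aggregated, library, protein_length, sigma = 5,
                           average_first = TRUE) {
  idx <- match(aggregated$guide_id, library$guide_id)
  keep <- !is.na(idx) & library$category[idx] == "tiling"
  cuts <- library$cds_cut_nt[idx[keep]]
  res <- cut_to_residue(cuts, protein_length)
  scores <- aggregated$score_mean[keep]
  if (average_first) {
    map <- per_residue_average(scores, res)
  } else {
    map <- data.frame(residue = res, score = scores)
    # smooth_profile expects one row per location; duplicate residues are
    # passed as separate kernel points by jittering nothing: keep raw rows
  }
  prof <- smooth_profile(map, sigma = sigma, protein_length = protein_length)
  if (!average_first) {
    support <- integer(protein_length)
    tab <- table(res)
    support[as.integer(names(tab))] <- as.integer(tab)
    prof$support <- support
  }
  prof
}

#' Summarize a tiling profile over annotated protein features
#'
#' @param profile a `tiling_profile`.
#' @param features data frame `label`, `start_res`, `end_res` (1-based
#'   closed intervals within the protein; labels unique).
#' @return Data frame `label`, `start_res`, `end_res`, `mean_score`,
#'   `min_score`, ranked by mean score ascending (most essential first).
#' @export
annotate_profile <- function(profile, features) {
  L <- attr(profile, "protein_length")
  if (any(features$start_res < 1L | features$end_res > L |
            features$start_res > features$end_res)) {
    stop("feature intervals outside protein bounds")
  }
  if (anyDuplicated(features$label)) stop("feature labels must be unique")
  stats_df <- do.call(rbind, lapply(seq_len(nrow(features)), function(i) {
    sel <- profile$score[features$start_res[i]:features$end_res[i]]
    data.frame(mean_score = mean(sel), min_score = min(sel))
  }))
  out <- cbind(features[, c("label", "start_res", "end_res")], stats_df)
  out <- out[order(out$mean_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlation between CRISPR scores and predicted on-target efficacy
#'
#' Used to check that a tiling pattern reflects biology rather than guide
#' editing efficiency: reports Pearson and Spearman coefficients with
#' two-sided p-values for the paired score/efficacy vectors.
#'
#' @param scores numeric CRISPR scores.
#' @param efficacy numeric predicted on-target efficacy scores, same length.
#' @return Data frame with rows `pearson` and `spearman`: `estimate`,
#'   `p_value`, `n`, `degenerate` (TRUE when a constant input makes the
#'   coefficient undefined).
#' @export
efficacy_correlation <- function(scores, efficacy) {
  ok <- is.finite(scores) & is.finite(efficacy)
  x <- scores[ok]
  y <- efficacy[ok]
  if (length(x) < 3L) stop("need at least 3 paired finite values")
  degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
  if (degenerate) {
    return(data.frame(
      method = c("pearson", "spearman"), estimate = NA_real_,
      p_value = NA_real_, n = length(x), degenerate = TRUE,
      stringsAsFactors = FALSE
    ))
  }
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  data.frame(
    method = c("pearson", "spearman"),
    estimate = c(unname(pe$estimate), unname(sp$estimate)),
    p_value = c(pe$p.value, sp$p.value),
    n = length(x),
    degenerate = FALSE,
    stringsAsFactors = FALSE
  )
}
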