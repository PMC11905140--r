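#' Amino-acid alphabet used by the conservation scorer
#' @keywords internal
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' BLOSUM62 background amino-acid distribution
#'
#' The marginal amino-acid frequencies underlying the BLOSUM62 substitution
#' matrix (Henikoff alignment-block counts), the conventional background
#' for divergence-based conservation scoring. Renormalized to sum exactly
#' to 1 and returned in the [AA20] order.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
blosum62_background <- function() {
  p <- c(A = 0.078, R = 0.051, N = 0.041, D = 0.052, C = 0.024,
         Q = 0.034, E = 0.059, G = 0.083, H = 0.025, I = 0.062,
         L = 0.092, K = 0.056, M = 0.024, F = 0.044, P = 0.043,
         S = 0.059, T = 0.055, W = 0.014, Y = 0.034, V = 0.072)
  p / sum(p)
}

#' Read a multi-species protein alignment
#'
#' Loads an aligned FASTA into a character matrix (rows = sequences,
#' columns = alignment columns), rejecting rows of unequal length and
#' symbols outside the 20 amino acids plus the gap character `-`.
#'
#' @param path aligned FASTA file.
#' @param reference_id name of the reference (e.g. human) sequence; must be
#'   present among the FASTA names.
#' @return A `protein_alignment`: list with `matrix` (character matrix with
#'   sequence rownames) and `reference_id`.
#' @export
read_alignment <- function(path, reference_id) {
  seqs <- Biostrings::readAAStringSet(path)
  protein_alignment(stats::setNames(as.character(seqs), names(seqs)),
                    reference_id)
}

#' Build a protein alignment object from named sequences
#'
#' @param sequences named character vector of equal-length aligned amino
#'   acid strings (gap `-`).
#' @param reference_id name of the reference row.
#' @return A `protein_alignment` (see [read_alignment()]).
#' @export
protein_alignment <- function(sequences, reference_id) {
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) stop("alignment rows have unequal length")
  if (!reference_id %in% names(sequences)) {
    stop("reference sequence '", reference_id, "' not found")
  }
  m <- do.call(rbind, strsplit(toupper(sequences), ""))
  rownames(m) <- names(sequences)
  bad <- setdiff(unique(as.vector(m)), c(AA20, "-"))
  if (length(bad) > 0L) {
    stop("alignment contains unsupported symbols: ",
         paste(bad, collapse = ", "))
  }
  structure(list(matrix = m, reference_id = reference_id),
            class = "protein_alignment")
}

#' Residue distribution of one alignment column
#'
#' Relative frequencies of the 20 amino acids over the non-gap residues of
#' the column, with a uniform pseudocount added to every amino acid and the
#' result renormalized to sum to 1. All-gap columns are flagged degenerate
#' (they score 0 downstream).
#'
#' @param column character vector of aligned residues (one alignment
#'   column, gaps as `-`).
#' @param pseudocount uniform count added to every amino acid.
#' @return List with `p` (named length-20 probability vector),
#'   `gap_fraction`, and `degenerate`.
#' @export
column_distribution <- function(column, pseudocount = 1e-7) {
  if (length(column) == 0L) stop("empty column")
  gaps <- column == "-"
  counts <- table(factor(column[!gaps], levels = AA20))
  total <- sum(counts)
  if (total == 0L) {
    return(list(p = stats::setNames(rep(NA_real_, 20L), AA20),
                gap_fraction = 1, degenerate = TRUE))
  }
  p <- (as.numeric(counts) + pseudocount) / (total + 20 * pseudocount)
  list(p = stats::setNames(p, AA20),
       gap_fraction = mean(gaps),
       degenerate = FALSE)
}

#' Jensen-Shannon divergence between two distributions
#'
#' `JSD(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`, base-2
#' logarithms (so the value is bounded in `[0, 1]`), symmetric, and with
#' the convention `0 * log 0 = 0`.
#'
#' @param p,q probability vectors over the same support.
#' @return Divergence in `[0, 1]`.
#' @export
jsd <- function(p, q) {
  stopifnot(length(p) == length(q))
  m <- (p + q) / 2
  kl <- function(a) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / m[nz]))
  }
  d <- (kl(p) + kl(q)) / 2
  min(max(d, 0), 1)
}

#' Per-residue conservation profile of the reference sequence
#'
#' Scores each alignment column by the Jensen-Shannon divergence between
#' the column's residue distribution and a BLOSUM62-derived background,
#' optionally down-weighted by the column's gap fraction and mixed with the
#' mean base score of the flanking window. Columns where the reference
#' sequence holds a gap (deletion sites in the reference protein) are
#' omitted, and the remaining scores are re-indexed to reference residue
#' numbering 1..L.
#'
#' Per column: `base = JSD(column distribution, background)`, multiplied by
#' `(1 - gap fraction)` when `gap_penalty` is on; the windowed score is
#' `(1 - lambda) * base + lambda * mean(base over the w - 1 flanking
#' columns)`, truncated at the alignment ends. All-gap columns score 0.
#'
#' @param aln a `protein_alignment`.
#' @param window odd window width w >= 1 (w = 1 disables windowing);
#'   default 3 (one column each side).
#' @param lambda window mixing weight in `[0, 1]`; default 0.5.
#' @param pseudocount residue-count pseudocount; default 1e-7.
#' @param gap_penalty multiply base scores by (1 - gap fraction); default
#'   TRUE.
#' @param background background distribution; default
#'   [blosum62_background()].
#' @return A `conservation_profile`: data frame `ref_residue`, `ref_aa`,
#'   `score`, with attribute `omitted_columns` (alignment columns where the
#'   reference is gapped) and the parameters used.
#' @export
conservation_profile <- function(aln, window = 3, lambda = 0.5,
                                 pseudocount = 1e-7, gap_penalty = TRUE,
                                 background = blosum62_background()) {
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  m <- aln$matrix
  ref <- m[aln$reference_id, ]
  n_col <- ncol(m)

  base <- vapply(seq_len(n_col), function(i) {
    cd <- column_distribution(m[, i], pseudocount = pseudocount)
    if (cd$degenerate) return(0)
    sc <- jsd(cd$p, background)
    if (gap_penalty) sc <- sc * (1 - cd$gap_fraction)
    sc
  }, numeric(1))

  half <- (window - 1) / 2
  if (half > 0 && lambda > 0) {
    flank_mean <- vapply(seq_len(n_col), function(i) {
      lo <- max(1L, i - half)
      hi <- min(n_col, i + half)
      idx <- setdiff(lo:hi, i)
      if (length(idx) == 0L) base[i] else mean(base[idx])
    }, numeric(1))
    score <- (1 - lambda) * base + lambda * flank_mean
  } else {
    score <- base
  }

  keep <- ref != "-"
  out <- data.frame(
    ref_residue = seq_len(sum(keep)),
    ref_aa = ref[keep],
    score = score[keep],
    row.names = NULL
  )
  structure(out,
            omitted_columns = which(!keep),
            window = window, lambda = lambda,
            pseudocount = pseudocount, gap_penalty = gap_penalty,
            class = c("conservation_profile", "data.frame"))
}
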