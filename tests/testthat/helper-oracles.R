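# Independent oracles used across the suite. Each is a deliberately naive
# re-derivation (brute force / direct summation) kept free of package code
# paths beyond trivial constructors.

# exhaustive 23-mer scan of both strands for NGG protospacers
brute_force_pam_scan <- function(cds) {
  n <- nchar(cds)
  plus <- 0L
  minus <- 0L
  cuts_plus <- integer(0)
  cuts_minus <- integer(0)
  for (i in seq_len(max(0L, n - 22L))) {
    w <- substr(cds, i, i + 22L)
    if (substr(w, 22L, 23L) == "GG") {     # protospacer i..i+19, PAM i+20..i+22
      plus <- plus + 1L
      cuts_plus <- c(cuts_plus, i + 16L)   # 5' side of cut on coding strand
    }
    if (substr(w, 1L, 2L) == "CC") {       # minus-strand PAM as plus-strand CCN
      minus <- minus + 1L
      # duplex cut 3 bp from the PAM: between plus positions (i+3)+2 and
      # (i+3)+3 for a protospacer occupying plus i+3..i+22
      cuts_minus <- c(cuts_minus, i + 5L)
    }
  }
  list(n_plus = plus, n_minus = minus,
       cuts = sort(c(cuts_plus, cuts_minus)))
}

# direct double-sum Jensen-Shannon divergence, base 2
direct_jsd <- function(p, q) {
  m <- (p + q) / 2
  total <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) total <- total + 0.5 * p[i] * log2(p[i] / m[i])
    if (q[i] > 0) total <- total + 0.5 * q[i] * log2(q[i] / m[i])
  }
  total
}

# brute-force Nadaraya-Watson kernel smoother (double loop)
direct_smooth <- function(residues, scores, sigma, protein_length) {
  out <- numeric(protein_length)
  for (t in seq_len(protein_length)) {
    w <- numeric(length(residues))
    for (k in seq_along(residues)) {
      w[k] <- exp(-(t - residues[k])^2 / (2 * sigma^2))
    }
    out[t] <- sum(w * scores) / sum(w)
  }
  out
}

# quadratic all-pairs promoter-overlap signal sum
quad_overlap_signal <- function(peaks, genes_win, peak_fdr = 0.05) {
  signal <- stats::setNames(numeric(nrow(genes_win)), genes_win$gene_id)
  for (i in seq_len(nrow(peaks))) {
    if (peaks$fdr[i] > peak_fdr) next
    for (j in seq_len(nrow(genes_win))) {
      if (peaks$chrom[i] == genes_win$chrom[j] &&
            peaks$start[i] <= genes_win$end[j] &&
            peaks$end[i] >= genes_win$start[j]) {
        signal[j] <- signal[j] + peaks$score[i]
      }
    }
  }
  signal
}

# rank-based AUC of scores for separating labelled positives
rank_auc <- function(scores, is_positive) {
  r <- rank(scores)
  n1 <- sum(is_positive)
  n0 <- sum(!is_positive)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# a small fixed hand-written library used by several unit tests
tiny_library <- function() {
  sgrna_library(data.frame(
    guide_id = c("gA_1", "gA_2", "gB_1", "gB_2", "neg_1", "neg_2", "pos_1"),
    spacer = c("ACGTACGTACGTACGTACGT", "TTTTGGGGCCCCAAAATTTT",
               "GATTACAGATTACAGATTAC", "CCCCGGGGAAAATTTTACGT",
               "AAAACCCCGGGGTTTTACGT", "TGCATGCATGCATGCATGCA",
               "GTACGTACGTACGTACGTAC"),
    category = c("gene_panel", "gene_panel", "gene_panel", "gene_panel",
                 "negative_control", "negative_control", "positive_control"),
    target_gene = c("GA", "GA", "GB", "GB", "", "", "MYC"),
    stringsAsFactors = FALSE
  ), name = "tiny")
}

random_aa_distribution <- function() {
  x <- stats::runif(20)
  x / sum(x)
}
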