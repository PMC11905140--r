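#' Validate a gene model table
#'
#' @param genes data frame `gene_id`, `chrom`, `tss` (1-based), `strand`
#'   (`+`/`-`).
#' @return The validated data frame.
#' @export
gene_models <- function(genes) {
  required <- c("gene_id", "chrom", "tss", "strand")
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0L) stop("gene table missing: ",
                                 paste(missing, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop("gene_id must be unique")
  if (any(genes$tss < 1L)) stop("TSS positions must be >= 1")
  if (any(!genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  genes
}

#' Strand-aware promoter windows
#'
#' Promoters are defined as -1 kb to +100 bp relative to the transcription
#' start site: `[TSS - 1000, TSS + 100]` on the plus strand, mirrored to
#' `[TSS - 100, TSS + 1000]` on the minus strand, clipped at position 1.
#' Coordinates are 1-based closed intervals.
#'
#' @param genes a [gene_models()] table.
#' @param upstream,downstream window extent in bp relative to transcription
#'   direction (defaults 1000 and 100).
#' @return `genes` with added `start` and `end` columns.
#' @export
promoter_window <- function(genes, upstream = 1000, downstream = 100) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  genes$start <- pmax(start, 1L)
  genes$end <- end
  genes
}

#' Read a narrowPeak file
#'
#' Standard 6+4 narrowPeak columns. BED-style 0-based half-open intervals
#' are converted to the package's 1-based closed convention on read
#' (start + 1, end unchanged). Column 7 (`signalValue`) is kept, the score
#' column (5) is used as the peak signal, and column 9 (`qValue`,
#' -log10 FDR) is converted to an `fdr` column.
#'
#' @param path narrowPeak file.
#' @return Data frame `chrom`, `start`, `end`, `name`, `score`, `strand`,
#'   `signal_value`, `p_value`, `fdr`, `peak_offset`.
#' @export
read_narrowpeak <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signal_value", "p_value", "q_value", "peak_offset")
  tab <- utils::read.delim(path, header = FALSE, col.names = cols,
                           stringsAsFactors = FALSE)
  tab$start <- tab$start + 1L  # BED 0-based half-open -> 1-based closed
  tab$fdr <- 10^(-tab$q_value)
  tab$q_value <- NULL
  if (any(tab$start > tab$end)) {
    bad <- which(tab$start > tab$end)
    stop("malformed peak intervals at rows: ", paste(bad, collapse = ", "))
  }
  tab
}

#' Write peaks as narrowPeak (inverse of [read_narrowpeak()])
#'
#' @param peaks data frame in the [read_narrowpeak()] layout (1-based
#'   closed `start`/`end`, `fdr` column).
#' @param path output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  out <- data.frame(
    chrom = peaks$chrom,
    start = peaks$start - 1L,  # back to BED 0-based half-open
    end = peaks$end,
    name = peaks$name,
    score = peaks$score,
    strand = peaks$strand,
    signal_value = peaks$signal_value,
    p_value = peaks$p_value,
    q_value = -log10(peaks$fdr),
    peak_offset = peaks$peak_offset
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Sum significant peak signal over promoter windows
#'
#' Each peak passing the FDR filter contributes its score to every gene
#' whose promoter window it overlaps (closed-interval overlap on the same
#' chromosome); genes without any overlapping passing peak get signal 0.
#'
#' @param peaks data frame from [read_narrowpeak()] (or same layout; must
#'   have `chrom`, `start`, `end`, `score`, `fdr`).
#' @param genes a [gene_models()] table (promoter windows are computed
#'   internally via [promoter_window()] unless `start`/`end` are present).
#' @param peak_fdr significance cutoff; only peaks with `fdr <= peak_fdr`
#'   contribute. Default 0.05.
#' @return Named numeric vector of per-gene summed signal.
#' @export
assign_signal <- function(peaks, genes, peak_fdr = 0.05) {
  if (!all(c("start", "end") %in% names(genes))) {
    genes <- promoter_window(genes)
  }
  if (any(peaks$start > peaks$end)) {
    stop("malformed peak intervals at rows: ",
         paste(which(peaks$start > peaks$end), collapse = ", "))
  }
  signal <- stats::setNames(numeric(nrow(genes)), genes$gene_id)
  pass <- peaks[peaks$fdr <= peak_fdr, , drop = FALSE]
  if (nrow(pass) == 0L) return(signal)
  gr_peaks <- GenomicRanges::GRanges(
    pass$chrom, IRanges::IRanges(pass$start, pass$end))
  gr_prom <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end))
  ov <- GenomicRanges::findOverlaps(gr_peaks, gr_prom)
  if (length(ov) > 0L) {
    contrib <- tapply(pass$score[S4Vectors::queryHits(ov)],
                      S4Vectors::subjectHits(ov), sum)
    signal[as.integer(names(contrib))] <- as.numeric(contrib)
  }
  signal
}

#' Assemble an occupancy set from per-factor/condition peak tables
#'
#' @param peak_sets named list of peak data frames; names must be
#'   `"<factor>_<condition>"` for every factor in `factors` and condition
#'   in `control`/`kd` (e.g. `ZNF217_control`, `H3K27ac_kd`).
#' @param genes a [gene_models()] table.
#' @param peak_fdr peak significance cutoff (see [assign_signal()]).
#' @param factors factor names; default the five-profile design
#'   `ZNF217, LSD1, H3K4me1, H3K4me2, H3K27ac`.
#' @return An `occupancy_set`: gene x (factor_condition) signal matrix with
#'   a `genes` attribute.
#' @export
occupancy_set <- function(peak_sets, genes, peak_fdr = 0.05,
                          factors = c("ZNF217", "LSD1", "H3K4me1",
                                      "H3K4me2", "H3K27ac")) {
  needed <- as.vector(outer(factors, c("control", "kd"), paste, sep = "_"))
  missing <- setdiff(needed, names(peak_sets))
  if (length(missing) > 0L) {
    stop("missing occupancy tracks: ", paste(missing, collapse = ", "))
  }
  genes <- promoter_window(gene_models(genes))
  sig <- vapply(needed, function(nm) {
    assign_signal(peak_sets[[nm]], genes, peak_fdr = peak_fdr)
  }, numeric(nrow(genes)))
  structure(sig, genes = genes, factors = factors, class = "occupancy_set")
}

#' Classify bound targets as CoREST-dependent or CoREST-independent
#'
#' Implements the knockdown stratification workflow: a gene is a bound
#' target when it carries factor signal in the control condition and loses
#' at least a `1/delta_bind`-fold share of it upon knockdown
#' (`(kd + floor) / (ctrl + floor) <= delta_bind`). Bound targets showing a
#' marked decrease in LSD1 binding (same ratio rule with `delta_mark`) or a
#' marked increase in any of H3K4me1/H3K4me2/H3K27ac
#' (`ratio >= 1/delta_mark`) are CoREST-dependent; the remaining bound
#' targets are CoREST-independent.
#'
#' @param occ an [occupancy_set()].
#' @param delta_bind fold threshold for occupancy loss (default 0.5, i.e.
#'   at least 2-fold reduction).
#' @param delta_mark fold threshold for LSD1 loss / mark gain (default
#'   0.5).
#' @param floor pseudo-signal offset stabilizing ratios at low signal
#'   (default 1).
#' @return A `target_classification` data frame: `gene_id`, `bound`,
#'   `class` (`corest_dependent` / `corest_independent` / `unbound`);
#'   attributes echo the thresholds.
#' @export
classify_targets <- function(occ, delta_bind = 0.5, delta_mark = 0.5,
                             floor = 1) {
  genes <- attr(occ, "genes")
  ratio <- function(factor) {
    (occ[, paste0(factor, "_kd")] + floor) /
      (occ[, paste0(factor, "_control")] + floor)
  }
  bound <- occ[, "ZNF217_control"] > 0 & ratio("ZNF217") <= delta_bind
  lsd1_loss <- ratio("LSD1") <= delta_mark
  mark_gain <- ratio("H3K4me1") >= 1 / delta_mark |
    ratio("H3K4me2") >= 1 / delta_mark |
    ratio("H3K27ac") >= 1 / delta_mark
  class <- ifelse(!bound, "unbound",
                  ifelse(lsd1_loss | mark_gain,
                         "corest_dependent", "corest_independent"))
  structure(
    data.frame(gene_id = genes$gene_id, bound = bound, class = class,
               row.names = NULL, stringsAsFactors = FALSE),
    delta_bind = delta_bind, delta_mark = delta_mark, floor = floor,
    class = c("target_classification", "data.frame")
  )
}

#' Intersect a target classification with differential expression
#'
#' @param classification a [classify_targets()] result.
#' @param de_table data frame `gene_id`, `fold_change`, `significant`
#'   (logical). Fold changes are knockdown/control ratios on the linear
#'   scale.
#' @param fc_threshold fold-change cutoff (> 1); a gene is `up` when
#'   `fold_change >= fc_threshold` and significant, `down` when
#'   `fold_change <= 1/fc_threshold` and significant, else `none`.
#' @return The classification with a `de_status` column plus a
#'   `partition_counts` attribute (see [partition_counts()]).
#' @export
integrate_de <- function(classification, de_table, fc_threshold = 2) {
  if (fc_threshold <= 1) stop("fc_threshold must exceed 1")
  idx <- match(classification$gene_id, de_table$gene_id)
  fc <- de_table$fold_change[idx]
  sig <- de_table$significant[idx]
  status <- rep("none", nrow(classification))
  status[!is.na(fc) & sig & fc >= fc_threshold] <- "up"
  status[!is.na(fc) & sig & fc <= 1 / fc_threshold] <- "down"
  classification$de_status <- status
  attr(classification, "partition_counts") <- partition_counts(classification)
  classification
}

#' Partition counts of a target classification
#'
#' @param classification a classification with `de_status`.
#' @return Named integer vector: `bound`, `independent`, `bound_up`,
#'   `independent_up`, `bound_down`, `independent_down`. By construction
#'   `dependent + independent = bound` and every `independent_*` count is
#'   bounded by the matching `bound_*` count.
#' @export
partition_counts <- function(classification) {
  bound <- classification$bound
  indep <- classification$class == "corest_independent"
  up <- classification$de_status == "up"
  down <- classification$de_status == "down"
  c(bound = sum(bound),
    dependent = sum(bound & !indep),
    independent = sum(indep),
    bound_up = sum(bound & up),
    independent_up = sum(indep & up),
    bound_down = sum(bound & down),
    independent_down = sum(indep & down))
}
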