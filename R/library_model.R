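#' sgRNA library objects
#'
#' An `sgrna_library` is a validated data frame of guide records with columns
#' `guide_id`, `spacer` (20-nt DNA), `category` (one of `gene_panel`,
#' `tiling`, `positive_control`, `negative_control`), `target_gene`,
#' `cds_cut_nt` and `strand`. Tiling guides carry the coding-strand
#' coordinate of their Cas9 cut site (`cds_cut_nt`, 1-based, the nucleotide
#' 5' of the blunt cut between protospacer positions 17 and 18) and the
#' strand the protospacer lies on; all other categories leave both fields
#' empty (`NA`).
#'
#' @param records data frame with the columns above. `cds_cut_nt`/`strand`
#'   may be omitted for libraries without tiling guides.
#' @param name library name, kept as an attribute.
#' @return A validated `sgrna_library` (a data frame subclass).
#' @export
sgrna_library <- function(records, name = "library") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c("guide_id", "spacer", "category", "target_gene")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0L) {
    stop("library table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!"cds_cut_nt" %in% names(records)) records$cds_cut_nt <- NA_integer_
  if (!"strand" %in% names(records)) records$strand <- NA_character_
  records$guide_id <- as.character(records$guide_id)
  records$spacer <- toupper(as.character(records$spacer))
  records$category <- as.character(records$category)
  records$target_gene <- as.character(records$target_gene)
  records$target_gene[is.na(records$target_gene)] <- ""
  records$cds_cut_nt <- as.integer(records$cds_cut_nt)
  records$strand <- as.character(records$strand)

  validate_sgrna_records(records)
  structure(records,
            name = name,
            class = c("sgrna_library", "data.frame"))
}

sgrna_categories <- c("gene_panel", "tiling", "positive_control",
                      "negative_control")

validate_sgrna_records <- function(records) {
  bad_cat <- setdiff(unique(records$category), sgrna_categories)
  if (length(bad_cat) > 0L) {
    stop("unknown guide categories: ", paste(bad_cat, collapse = ", "))
  }
  bad_len <- records$guide_id[nchar(records$spacer) != 20L]
  if (length(bad_len) > 0L) {
    stop("spacers are not 20 nt for guides: ", paste(bad_len, collapse = ", "))
  }
  bad_alpha <- records$guide_id[grepl("[^ACGT]", records$spacer)]
  if (length(bad_alpha) > 0L) {
    stop("non-ACGT spacers for guides: ", paste(bad_alpha, collapse = ", "))
  }
  dup_id <- records$guide_id[duplicated(records$guide_id)]
  if (length(dup_id) > 0L) {
    stop("duplicate guide_id: ", paste(unique(dup_id), collapse = ", "))
  }
  dup_sp <- unique(records$spacer[duplicated(records$spacer)])
  if (length(dup_sp) > 0L) {
    offenders <- records$guide_id[records$spacer %in% dup_sp]
    stop("duplicate spacers shared by guides: ",
         paste(offenders, collapse = ", "))
  }
  is_tiling <- records$category == "tiling"
  if (any(is_tiling & is.na(records$cds_cut_nt))) {
    stop("tiling guides missing cds_cut_nt: ",
         paste(records$guide_id[is_tiling & is.na(records$cds_cut_nt)],
               collapse = ", "))
  }
  if (any(!is_tiling & !is.na(records$cds_cut_nt))) {
    stop("cds_cut_nt set on non-tiling guides: ",
         paste(records$guide_id[!is_tiling & !is.na(records$cds_cut_nt)],
               collapse = ", "))
  }
  if (any(is_tiling & !records$strand %in% c("+", "-"))) {
    stop("tiling guides need strand '+' or '-'")
  }
  if (sum(records$category == "negative_control") < 1L) {
    stop("library must contain at least one negative_control guide ",
         "(required by every normalization)")
  }
  invisible(records)
}

#' Read an sgRNA library table
#'
#' Reads a TSV with header
#' `guide_id spacer category target_gene cds_cut_nt strand` (the last two may
#' be empty or absent for non-tiling libraries) and validates it.
#'
#' @param path path to the TSV file.
#' @param name library name; defaults to the file name.
#' @return An [sgrna_library()].
#' @export
read_sgrna_library <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("no such library file: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if ("cds_cut_nt" %in% names(tab)) {
    tab$cds_cut_nt <- suppressWarnings(as.integer(tab$cds_cut_nt))
  }
  if ("strand" %in% names(tab)) {
    tab$strand[tab$strand == ""] <- NA_character_
  }
  sgrna_library(tab, name = name)
}

#' Write an sgRNA library table
#'
#' Inverse of [read_sgrna_library()]: writes the six-column TSV with empty
#' strings for absent `cds_cut_nt`/`strand` fields so that a read/write
#' round trip reproduces the table field-for-field.
#'
#' @param library an [sgrna_library()].
#' @param path output path.
#' @export
write_sgrna_library <- function(library, path) {
  out <- as.data.frame(library)[, c("guide_id", "spacer", "category",
                                    "target_gene", "cds_cut_nt", "strand")]
  out$cds_cut_nt <- ifelse(is.na(out$cds_cut_nt), "",
                           as.character(out$cds_cut_nt))
  out$strand <- ifelse(is.na(out$strand), "", out$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Enumerate tiling guides over a coding sequence
#'
#' Scans both strands of a coding DNA sequence for 20-nt protospacers
#' immediately 5' of an NGG PAM and returns one tiling record per site.
#' The cut site is the blunt Cas9 cut between protospacer positions 17 and
#' 18 (3 bp 5' of the PAM); `cds_cut_nt` records the nucleotide on the 5'
#' side of the cut projected onto the coding strand, so minus-strand guides
#' share the single coding-strand axis used by tiling profiles.
#'
#' @param cds coding sequence (character string or `Biostrings::DNAString`);
#'   length must be >= 23 and a multiple of 3, alphabet strictly ACGT.
#' @param gene target gene label for the records.
#' @return Data frame of tiling records (columns as in [sgrna_library()]),
#'   sorted by `cds_cut_nt` then strand.
#' @export
enumerate_tiling_guides <- function(cds, gene = "TILED") {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n < 23L) stop("cds too short for a 23-nt protospacer+PAM window")
  if (n %% 3L != 0L) stop("cds length must be a multiple of 3")
  if (grepl("[^ACGT]", cds)) stop("ambiguity codes in cds are not supported")

  chars <- strsplit(cds, "")[[1]]
  # plus strand: PAM N G G at p..p+2, protospacer p-20..p-1, needs p >= 21
  gg <- which(chars[-n] == "G" & chars[-1L] == "G")  # positions i with GG at i,i+1
  p_plus <- gg[gg >= 22L & gg <= n - 1L] - 1L        # PAM start p (N at p)
  plus_spacers <- if (length(p_plus) > 0L) {
    substring(cds, p_plus - 20L, p_plus - 1L)
  } else {
    character(0)
  }
  plus <- data.frame(
    spacer = plus_spacers,
    cds_cut_nt = p_plus - 4L,
    strand = rep("+", length(p_plus)),
    stringsAsFactors = FALSE
  )
  # minus strand: plus-strand CC at q,q+1 is the reverse-complement PAM GG;
  # protospacer occupies plus positions q+3..q+22, cut between q+5 and q+6
  cc <- which(chars[-n] == "C" & chars[-1L] == "C")
  q <- cc[cc >= 1L & cc + 22L <= n]
  minus_spacers <- if (length(q) > 0L) {
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(substring(cds, q + 3L, q + 22L))))
  } else {
    character(0)
  }
  minus <- data.frame(
    spacer = minus_spacers,
    cds_cut_nt = q + 5L,
    strand = rep("-", length(q)),
    stringsAsFactors = FALSE
  )
  rec <- rbind(plus, minus)
  rec <- rec[order(rec$cds_cut_nt, rec$strand), , drop = FALSE]
  rec <- data.frame(
    guide_id = sprintf("tile_%04d_%s", seq_len(nrow(rec)),
                       ifelse(rec$strand == "+", "p", "m")),
    spacer = rec$spacer,
    category = rep("tiling", nrow(rec)),
    target_gene = rep(gene, nrow(rec)),
    cds_cut_nt = rec$cds_cut_nt,
    strand = rec$strand,
    stringsAsFactors = FALSE
  )
  rownames(rec) <- NULL
  rec
}

#' Tiling density of a library
#'
#' Average spacing of tiling guides along the coding sequence, in base pairs
#' per guide (e.g. 416 guides over a 3,120-nt CDS give 7.5 bp/guide, i.e.
#' 2.5 amino acids per guide).
#'
#' @param library an [sgrna_library()].
#' @param cds_length coding-sequence length in nucleotides.
#' @return bp per guide (numeric scalar).
#' @export
tiling_density <- function(library, cds_length) {
  n_tiling <- sum(library$category == "tiling")
  if (n_tiling == 0L) stop("library contains no tiling guides")
  cds_length / n_tiling
}

#' Library composition summary
#'
#' Counts of guides per category and per target gene. The category counts
#' always partition the library.
#'
#' @param library an [sgrna_library()] (or an empty data frame).
#' @return List with `per_category` (named integer vector over all four
#'   categories), `per_gene` (table of target genes, non-empty targets only)
#'   and `n_records`.
#' @export
composition_summary <- function(library) {
  cats <- factor(library$category, levels = sgrna_categories)
  per_category <- table(cats)
  targeted <- library$target_gene[library$target_gene != ""]
  list(
    per_category = stats::setNames(as.integer(per_category),
                                   names(per_category)),
    per_gene = table(targeted),
    n_records = nrow(library)
  )
}

#' @export
print.sgrna_library <- function(x, ...) {
  cs <- composition_summary(x)
  cat("sgRNA library '", attr(x, "name"), "': ", nrow(x), " guides (",
      paste(sprintf("%s=%d", names(cs$per_category), cs$per_category),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}
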