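#!/usr/bin/env Rscript
# Step 1 -- generate the study inputs with known ground truth.
#
# Builds the focused 963-guide panel library (36 genes x 25 guides + 41
# negative + 22 positive controls) and the 478-guide tiling library (416
# guides saturating a fabricated 3,120-nt CDS at 7.5 bp/guide + 40
# negative + 22 positive controls), then simulates dropout screens for
# both: 3 replicates, 1000x coverage, log2(5000) ~ 12.3 population
# doublings. GENE05 is planted essential in the panel (-0.5 per
# doubling); a zinc-finger block (residues 100-400) and a ZF5-like motif
# (520-560) are planted essential in the tiling screen.

suppressPackageStartupMessages(library(tilescreen))
dir.create("results", showWarnings = FALSE)
seed <- 20260920L %% 100000L

panel_lib <- simulate_panel_library(seed)
write_sgrna_library(panel_lib, "results/panel_library.tsv")
panel_sim <- simulate_screen(panel_lib, screen_truth(
  panel_lib, panel_effects(panel_lib, "GENE05", effect = -0.5),
  seed = seed + 1L))
write.table(data.frame(guide_id = rownames(panel_sim$counts),
                       panel_sim$counts, check.names = FALSE),
            "results/panel_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(panel_sim$sample_sheet, "results/panel_samples.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

tl <- simulate_tiling_library(seed + 2L)
write_sgrna_library(tl$library, "results/tiling_library.tsv")
writeLines(c(">synthetic_cds", tl$cds), "results/tiling_cds.fa")
features <- data.frame(label = c("ZF_block", "ZF5"),
                       start_res = c(100L, 520L), end_res = c(400L, 560L),
                       effect = -1)
write.table(features, "results/tiling_features.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
eff <- simulate_tiling_truth(tl$library, tl$protein_length, features,
                             noise_sd = 0.1, seed = seed + 3L)
tiling_sim <- simulate_screen(tl$library, screen_truth(tl$library, eff,
                                                       seed = seed + 4L))
write.table(data.frame(guide_id = rownames(tiling_sim$counts),
                       tiling_sim$counts, check.names = FALSE),
            "results/tiling_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(tiling_sim$sample_sheet, "results/tiling_samples.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# a small FASTQ sample (one panel replicate at reduced coverage) showing
# the read layout consumed by count_reads()
small_lib <- simulate_panel_library(seed, n_genes = 4, guides_per_gene = 5,
                                    n_neg = 4, n_pos = 2)
small_sim <- simulate_screen(small_lib, screen_truth(small_lib,
                                                     coverage = 50,
                                                     replicates = 1,
                                                     seed = seed + 5L))
write_screen_fastq(small_sim, "results/fastq_demo")

cs <- composition_summary(panel_lib)
cat("panel library:", cs$n_records, "guides;",
    cs$per_category["gene_panel"], "gene-targeting,",
    cs$per_category["negative_control"], "negative,",
    cs$per_category["positive_control"], "positive controls\n")
cat("tiling library:", sum(tl$library$category == "tiling"),
    "guides at", tiling_density(tl$library, nchar(tl$cds)), "bp/guide over",
    nchar(tl$cds), "nt\n")
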