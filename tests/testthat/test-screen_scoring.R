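make_freq <- function(values, samples) {
  m <- matrix(values, ncol = length(samples),
              dimnames = list(paste0("g", seq_len(length(values) /
                                                    length(samples))),
                              samples))
  m
}

sheet1 <- data.frame(sample = c("ini", "fin"), replicate = 1,
                     timepoint = c("initial", "final"))

test_that("log10 fold change is the log frequency ratio", {
  freq <- make_freq(c(0.001, 0.5, 0.0001, 0.5), c("ini", "fin"))
  lfc <- log10_fold_change(freq, sheet1, pseudocount = 0)
  expect_equal(unname(lfc["g1", "1"]), -1)
  expect_equal(unname(lfc["g2", "1"]), 0)

  set.seed(3)
  f <- matrix(runif(40, 0.001, 0.1), ncol = 2,
              dimnames = list(paste0("g", 1:20), c("ini", "fin")))
  eps <- 1e-4
  lfc <- log10_fold_change(f, sheet1, pseudocount = eps)
  # element-wise reference recomputation
  for (g in rownames(f)) {
    expect_equal(unname(lfc[g, "1"]),
                 log10((f[g, "fin"] + eps) / (f[g, "ini"] + eps)))
  }
  bad <- data.frame(sample = "ini", replicate = 1, timepoint = "initial")
  expect_error(log10_fold_change(f, bad), "replicate 1")
})

test_that("panel normalization anchors the negative-control mean at zero", {
  lib <- tiny_library()
  raw <- matrix(c(-0.7, 0.1, 0.2, -0.2, 0.4, 0.2, -0.5), ncol = 1,
                dimnames = list(lib$guide_id, "1"))
  norm <- normalize_panel(raw, lib)
  # negatives raw mean = 0.3; a -0.7 guide lands at -1.0
  expect_equal(unname(norm["gA_1", "1"]), -1)
  expect_equal(mean(norm[c("neg_1", "neg_2"), "1"]), 0, tolerance = 1e-12)

  same <- matrix(0.4, nrow = 7, ncol = 2,
                 dimnames = list(lib$guide_id, c("1", "2")))
  expect_true(all(normalize_panel(same, lib) == 0))
  no_neg <- lib[lib$category != "negative_control", ]
  expect_error(normalize_panel(raw[no_neg$guide_id, , drop = FALSE],
                               sgrna_library(tiny_library())),
               "not found|negative")
})

test_that("dual-anchor normalization pins control medians at 0 and -1", {
  lib <- tiny_library()
  raw <- matrix(c(0.05, -0.8, 0.3, -0.35, 0.1, 0.3, -0.6), ncol = 1,
                dimnames = list(lib$guide_id, "1"))
  # m_neg = 0.2 (median of 0.1, 0.3), m_pos = -0.6
  norm <- normalize_tiling(raw, lib)
  expect_equal(unname(norm["pos_1", "1"]), -1)
  expect_equal(median(norm[c("neg_1", "neg_2"), "1"]), 0)
  # raw at the negative anchor scores 0; halfway scores -0.5
  expect_equal(unname(norm["gA_1", "1"]), (0.05 - 0.2) / 0.8)
  halfway <- matrix(c(-0.2, -0.8, 0.3, -0.35, 0.1, 0.3, -0.6), ncol = 1,
                    dimnames = list(lib$guide_id, "1"))
  expect_equal(unname(normalize_tiling(halfway, lib)["gA_1", "1"]), -0.5)

  degenerate <- matrix(0.2, nrow = 7, ncol = 1,
                       dimnames = list(lib$guide_id, "1"))
  expect_error(normalize_tiling(degenerate, lib), "degenerate")
})

test_that("dual-anchor normalization is invariant to affine raw transforms", {
  lib <- tiny_library()
  set.seed(4)
  raw <- matrix(rnorm(14), ncol = 2, dimnames = list(lib$guide_id, 1:2))
  base <- normalize_tiling(raw, lib)
  shifted <- normalize_tiling(3.2 * raw + 0.7, lib)
  expect_equal(base, shifted, tolerance = 1e-12)
})

test_that("replicate aggregation returns row means and sds", {
  m <- matrix(c(-1, -1, -1, 0, -2, -1), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), NULL))
  agg <- aggregate_replicates(m)
  expect_equal(agg$score_mean, c(-1, -1))
  expect_equal(agg$score_sd, c(0, 1))
  set.seed(5)
  r <- matrix(rnorm(60), nrow = 12,
              dimnames = list(paste0("g", 1:12), NULL))
  expect_equal(aggregate_replicates(r)$score_mean, unname(rowMeans(r)))
})

test_that("decreasing a guide's final count never raises its score", {
  lib <- simulate_panel_library(21, n_genes = 3, guides_per_gene = 4,
                                n_neg = 4, n_pos = 2)
  sim <- simulate_screen(lib, screen_truth(lib, coverage = 200, seed = 22))
  counts <- sim$counts
  target <- "GENE01_sg01"
  scores <- sapply(c(counts[target, "rep1_final"], 50L, 10L, 1L, 0L),
                   function(k) {
    counts[target, "rep1_final"] <- k
    st <- score_screen(counts, sim$sample_sheet, lib, "panel_anchor")
    st$normalized[target, "1"]
  })
  expect_true(all(diff(scores) <= 1e-12))
})

test_that("all-zero guides are dropped from scoring and reported", {
  lib <- tiny_library()
  counts <- matrix(10L, nrow = 7, ncol = 2,
                   dimnames = list(lib$guide_id, c("ini", "fin")))
  counts["gB_2", ] <- 0L
  st <- score_screen(counts, sheet1, lib, "panel_anchor")
  expect_equal(st$dropped, "gB_2")
  expect_false("gB_2" %in% rownames(st$normalized))
})

test_that("rra places a fully depleted gene first with the floor p-value", {
  lib <- simulate_panel_library(31)
  n <- nrow(lib)
  agg <- data.frame(guide_id = lib$guide_id, score_mean = seq_len(n) / n)
  # hand GENE01's 25 guides the 25 most-depleted ranks
  g1 <- lib$guide_id[lib$target_gene == "GENE01"]
  agg$score_mean[match(g1, agg$guide_id)] <- seq(-2, -1, length.out = 25)
  rr <- rra_gene_rank(agg, lib, alpha = 0.25, permutations = 200, seed = 8)
  expect_equal(rr$gene[1], "GENE01")
  expect_equal(rr$p_value[1], 1 / 201)
  expect_equal(sort(rr$rank), seq_len(nrow(rr)))
})

test_that("a gene with no guide under the alpha cutoff scores rho = 1", {
  lib <- tiny_library()
  agg <- data.frame(
    guide_id = lib$guide_id,
    score_mean = c(0.9, 1.0, -2, -1.9, 0, 0.1, -3)  # GA guides at the top
  )
  # ranks: pos -3 (1), gB_1 (2), gB_2 (3), negs (4, 5), GA guides (6, 7);
  # alpha 0.3 admits only gB_1 (u = 2/7)
  rr <- rra_gene_rank(agg, lib, alpha = 0.3, permutations = 100, seed = 1)
  expect_equal(rr$rra_score[rr$gene == "GA"], 1)
  expect_lt(rr$rra_score[rr$gene == "GB"], 1)
  expect_error(rra_gene_rank(agg, lib, alpha = 0), "alpha")
})

test_that("permutation p-values match exhaustive label enumeration", {
  # 10 guides, one 2-guide gene: 45 possible label assignments
  lib <- sgrna_library(data.frame(
    guide_id = paste0("g", 1:10),
    spacer = replicate(10, paste(sample(c("A", "C", "G", "T"), 20,
                                        replace = TRUE), collapse = "")),
    category = c(rep("gene_panel", 2), rep("negative_control", 8)),
    target_gene = c("GX", "GX", rep("", 8))
  ))
  agg <- data.frame(guide_id = lib$guide_id,
                    score_mean = c(-2, -1.5, seq(-1, 2, length.out = 8)))
  rr <- rra_gene_rank(agg, lib, alpha = 0.5, permutations = 10000, seed = 2)
  rho_obs <- rr$rra_score[rr$gene == "GX"]

  # exhaustive oracle over all choose(10, 2) assignments
  u <- rank(agg$score_mean) / 10
  rho_of <- function(uu) {
    sel <- sort(uu[uu <= 0.5])
    if (length(sel) == 0) return(1)
    m <- length(sel)
    min(pbeta(sel, seq_len(m), m - seq_len(m) + 1))
  }
  all_rho <- apply(combn(10, 2), 2, function(ix) rho_of(u[ix]))
  exact_p <- mean(all_rho <= rho_obs)
  expect_lt(abs(rr$p_value[rr$gene == "GX"] - exact_p), 0.03)
})

test_that("control report separates planted essential positives", {
  lib <- simulate_panel_library(41)
  sim <- simulate_screen(lib, screen_truth(
    lib, panel_effects(lib, positive_effect = -1), coverage = 1000,
    seed = 42))
  st <- score_screen(sim$counts, sim$sample_sheet, lib, "panel_anchor")
  rep <- control_behavior_report(st$aggregated, lib)
  med <- rep$summary$median
  expect_lt(med[rep$summary$category == "positive_control"],
            med[rep$summary$category == "negative_control"] - 1)
  expect_lt(rep$test$p.value, 0.05)
})
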