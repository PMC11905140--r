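test_that("cut positions map to residues over trinucleotide codons", {
  expect_equal(cut_to_residue(1, 10), 1L)
  expect_equal(cut_to_residue(3, 10), 1L)
  expect_equal(cut_to_residue(4, 10), 2L)
  expect_equal(cut_to_residue(30, 10), 10L)
  expect_error(cut_to_residue(31, 10), "outside")
  expect_error(cut_to_residue(0, 10), "outside")

  tl <- simulate_tiling_library(13)
  cuts <- tl$library$cds_cut_nt[tl$library$category == "tiling"]
  got <- cut_to_residue(cuts, tl$protein_length)
  expect_equal(got, as.integer((cuts - 1) %/% 3 + 1))  # arithmetic oracle
})

test_that("per-residue averaging groups guide scores by residue", {
  avg <- per_residue_average(c(-0.4, -0.6), c(10L, 10L))
  expect_equal(avg$score, -0.5)
  expect_equal(avg$support, 2L)

  one <- per_residue_average(-0.3, 7L)
  expect_equal(nrow(one), 1L)
  expect_equal(one$score, -0.3)

  set.seed(6)
  scores <- rnorm(200)
  res <- sample.int(40, 200, replace = TRUE)
  avg <- per_residue_average(scores, res)
  oracle <- tapply(scores, res, mean)  # group-by recomputation
  expect_equal(avg$score, unname(as.numeric(oracle)))
  expect_equal(sum(avg$support), 200L)
})

test_that("gaussian smoothing matches the brute-force double loop", {
  set.seed(7)
  obs <- sort(sample.int(120, 30))
  s <- rnorm(30)
  prof <- smooth_profile(data.frame(residue = obs, score = s),
                         sigma = 5, protein_length = 120)
  expect_equal(prof$score, direct_smooth(obs, s, 5, 120),
               tolerance = 1e-10)
})

test_that("smoothing preserves constants, symmetry and input bounds", {
  const <- smooth_profile(data.frame(residue = c(5L, 50L, 95L),
                                     score = c(-1, -1, -1)),
                          sigma = 4, protein_length = 100)
  expect_equal(const$score, rep(-1, 100), tolerance = 1e-12)

  # a lone observation smooths to a flat profile (weights renormalize)
  single <- smooth_profile(data.frame(residue = 100L, score = -2),
                           sigma = 6, protein_length = 199)
  expect_equal(single$score, rep(-2, 199), tolerance = 1e-12)
  # a dip flanked by symmetric neutral anchors is symmetric and deepest
  # at the observation
  dip <- smooth_profile(data.frame(residue = c(40L, 100L, 160L),
                                   score = c(0, -2, 0)),
                        sigma = 25, protein_length = 199)
  expect_equal(which.min(dip$score), 100L)
  expect_equal(dip$score[100 - 7], dip$score[100 + 7], tolerance = 1e-10)

  set.seed(8)
  obs <- sample.int(80, 25)
  s <- rnorm(25)
  prof <- smooth_profile(data.frame(residue = obs, score = s),
                         sigma = 3, protein_length = 80)
  expect_true(all(prof$score >= min(s) - 1e-12 &
                    prof$score <= max(s) + 1e-12))
  # shift equivariance
  shifted <- smooth_profile(data.frame(residue = obs, score = s + 2.5),
                            sigma = 3, protein_length = 80)
  expect_equal(shifted$score, prof$score + 2.5, tolerance = 1e-10)

  expect_error(smooth_profile(data.frame(residue = integer(0),
                                         score = numeric(0)),
                              sigma = 3, protein_length = 10), "empty")
  expect_error(smooth_profile(data.frame(residue = 1L, score = 0),
                              sigma = 0, protein_length = 10), "sigma")
})

test_that("averaging before smoothing is the pinned order of operations", {
  # two guides stacked on one residue vs one on another: averaging first
  # weighs residues equally; smoothing raw guide points would not
  lib <- sgrna_library(data.frame(
    guide_id = c("t1", "t2", "t3", "neg_1"),
    spacer = c("ACGTACGTACGTACGTACGT", "TTTTGGGGCCCCAAAATTTT",
               "GATTACAGATTACAGATTAC", "AAAACCCCGGGGTTTTACGT"),
    category = c("tiling", "tiling", "tiling", "negative_control"),
    target_gene = c("Z", "Z", "Z", ""),
    cds_cut_nt = c(4L, 5L, 10L, NA),
    strand = c("+", "+", "+", NA)
  ))
  agg <- data.frame(guide_id = c("t1", "t2", "t3"),
                    score_mean = c(-1, -0.2, 0.4))
  averaged <- tiling_profile(agg, lib, protein_length = 5, sigma = 2)
  raw <- tiling_profile(agg, lib, protein_length = 5, sigma = 2,
                        average_first = FALSE)
  man <- smooth_profile(data.frame(residue = c(2L, 4L),
                                   score = c(-0.6, 0.4)),
                        sigma = 2, protein_length = 5)
  expect_equal(averaged$score, man$score)
  expect_false(isTRUE(all.equal(averaged$score, raw$score)))
})

test_that("feature annotation ranks planted essential domains first", {
  tl <- simulate_tiling_library(17)
  feats <- data.frame(label = c("ZF1", "ZF2", "Cterm"),
                      start_res = c(40L, 300L, 820L),
                      end_res = c(120L, 380L, 1020L))
  eff <- simulate_tiling_truth(tl$library, tl$protein_length,
                               cbind(feats[1:2, ], effect = -1), seed = 18)
  sim <- simulate_screen(tl$library, screen_truth(tl$library, eff,
                                                  seed = 19))
  st <- score_screen(sim$counts, sim$sample_sheet, tl$library,
                     "dual_anchor")
  prof <- tiling_profile(st$aggregated, tl$library, tl$protein_length)
  ann <- annotate_profile(prof, feats)
  expect_equal(sort(ann$label[1:2]), c("ZF1", "ZF2"))
  expect_lt(max(ann$mean_score[ann$label != "Cterm"]),
            ann$mean_score[ann$label == "Cterm"])

  flat <- smooth_profile(data.frame(residue = 1L, score = -1),
                         sigma = 5, protein_length = 50)
  ann_flat <- annotate_profile(flat, data.frame(label = c("a", "b"),
                                                start_res = c(1L, 20L),
                                                end_res = c(10L, 50L)))
  expect_equal(ann_flat$mean_score, c(-1, -1))
  whole <- annotate_profile(prof, data.frame(label = "all", start_res = 1L,
                                             end_res = tl$protein_length))
  expect_equal(whole$mean_score, mean(prof$score))
  expect_error(annotate_profile(flat, data.frame(label = "x",
                                                 start_res = 0L,
                                                 end_res = 10L)),
               "bounds")
})

test_that("efficacy correlation returns both coefficients with p-values", {
  set.seed(9)
  x <- rnorm(50)
  ec <- efficacy_correlation(x, x)
  expect_equal(ec$estimate[ec$method == "pearson"], 1)
  anti <- efficacy_correlation(x, -x)
  expect_equal(anti$estimate[anti$method == "spearman"], -1)

  const <- efficacy_correlation(x, rep(1, 50))
  expect_true(all(const$degenerate))
  expect_true(all(is.na(const$estimate)))
  expect_error(efficacy_correlation(1:2, 1:2), "at least 3")
})
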