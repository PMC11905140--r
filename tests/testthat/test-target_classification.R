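test_that("promoter windows are strand-aware and clipped at 1", {
  g <- gene_models(data.frame(
    gene_id = c("a", "b", "c"), chrom = "chr1",
    tss = c(5000L, 5000L, 500L), strand = c("+", "-", "+")
  ))
  w <- promoter_window(g)
  expect_equal(w$start, c(4000L, 4900L, 1L))
  expect_equal(w$end, c(5100L, 6000L, 600L))
  expect_error(gene_models(data.frame(gene_id = c("a", "a"), chrom = "x",
                                      tss = 1L, strand = "+")), "unique")
  expect_error(gene_models(data.frame(gene_id = "a", chrom = "x",
                                      tss = 0L, strand = "+")), "TSS")
})

test_that("narrowPeak reading converts BED coordinates and FDR", {
  tmp <- tempfile(fileext = ".narrowPeak")
  writeLines(paste(c("chr1", 999, 1200, "p1", 85, ".", 8.5, 10, 2, 100),
                   collapse = "\t"), tmp)
  pk <- read_narrowpeak(tmp)
  expect_equal(pk$start, 1000L)  # 0-based half-open -> 1-based closed
  expect_equal(pk$end, 1200L)
  expect_equal(pk$fdr, 0.01)    # column 9 is -log10 FDR
  # round trip
  out <- tempfile(fileext = ".narrowPeak")
  write_narrowpeak(pk, out)
  expect_equal(read_narrowpeak(out), pk)
})

test_that("signal assignment honours overlap and the FDR filter", {
  g <- gene_models(data.frame(gene_id = c("a", "b"), chrom = "chr1",
                              tss = c(5000L, 50000L), strand = "+"))
  peaks <- data.frame(
    chrom = "chr1", start = c(4500L, 4500L, 49900L),
    end = c(4700L, 4700L, 50000L),
    score = c(10, 99, 7), fdr = c(0.01, 0.2, 0.05)
  )
  sig <- assign_signal(peaks, g, peak_fdr = 0.05)
  expect_equal(unname(sig["a"]), 10)   # the FDR 0.2 peak contributes nowhere
  expect_equal(unname(sig["b"]), 7)
  none <- assign_signal(peaks[peaks$fdr > 0.1, , drop = FALSE], g)
  expect_equal(unname(none), c(0, 0))
  bad <- data.frame(chrom = "chr1", start = 10L, end = 5L, score = 1,
                    fdr = 0.01)
  expect_error(assign_signal(bad, g), "malformed")
})

test_that("overlap assignment equals the quadratic brute-force oracle", {
  set.seed(13)
  for (rep in 1:5) {
    n_genes <- 40
    g <- promoter_window(simulate_genes(n_genes, seed = rep))
    peaks <- data.frame(
      chrom = sample(c("chr1", "chr2"), 300, replace = TRUE),
      start = sample.int(8e5, 300),
      score = runif(300, 1, 100),
      fdr = sample(c(0.001, 0.04, 0.2), 300, replace = TRUE)
    )
    peaks$end <- peaks$start + sample.int(3000, 300)
    got <- assign_signal(peaks, g, peak_fdr = 0.05)
    expect_equal(got, quad_overlap_signal(peaks, g, 0.05))
  }
})

test_that("classification applies the occupancy-loss and mark rules", {
  g <- simulate_genes(2, seed = 1)
  mk_peaks <- function(scores) {
    lapply(scores, function(s) data.frame(
      chrom = g$chrom, start = g$tss - 50L, end = g$tss + 50L,
      score = s, fdr = 0.001))
  }
  # gene 1: ZNF217 100 -> 10, everything else flat => bound, independent
  # gene 2: ZNF217 100 -> 10, H3K27ac 50 -> 150    => bound, dependent
  occ <- occupancy_set(mk_peaks(list(
    ZNF217_control = c(100, 100), ZNF217_kd = c(10, 10),
    LSD1_control = c(80, 80), LSD1_kd = c(80, 80),
    H3K4me1_control = c(30, 30), H3K4me1_kd = c(30, 30),
    H3K4me2_control = c(30, 30), H3K4me2_kd = c(30, 30),
    H3K27ac_control = c(50, 50), H3K27ac_kd = c(50, 150)
  )), g)
  cls <- classify_targets(occ)
  expect_equal(cls$class, c("corest_independent", "corest_dependent"))
  expect_true(all(cls$bound))
  expect_equal(cls$bound, cls$class != "unbound")
})

test_that("missing occupancy tracks are rejected", {
  g <- simulate_genes(2, seed = 2)
  expect_error(occupancy_set(list(ZNF217_control = data.frame()), g),
               "missing occupancy tracks")
})

test_that("DE integration thresholds fold changes and emits partitions", {
  g <- simulate_genes(3, seed = 3)
  pl <- data.frame(gene_id = g$gene_id,
                   class = c("corest_independent", "corest_dependent",
                             "unbound"),
                   de_status = "none")
  occ_in <- simulate_occupancy_and_de(g, pl, noise_sd = 0, seed = 4)
  cls <- classify_targets(occupancy_set(occ_in$peak_sets, g))
  de <- data.frame(gene_id = g$gene_id,
                   fold_change = c(3, 1.5, 5),
                   significant = c(TRUE, TRUE, TRUE))
  out <- integrate_de(cls, de, fc_threshold = 2)
  expect_equal(out$de_status, c("up", "none", "up"))
  pc <- attr(out, "partition_counts")
  expect_equal(unname(pc["bound_up"]), 1L)        # unbound up gene not counted
  expect_equal(unname(pc["independent_up"]), 1L)
  expect_equal(unname(pc["dependent"] + pc["independent"]),
               unname(pc["bound"]))
  expect_error(integrate_de(cls, de, fc_threshold = 1), "exceed 1")
})

test_that("noiseless planted classes and partition counts recover exactly", {
  g <- simulate_genes(120, seed = 5)
  pl <- simulate_planted_classes(g, seed = 6)
  occ_in <- simulate_occupancy_and_de(g, pl, noise_sd = 0, seed = 7)
  occ <- occupancy_set(occ_in$peak_sets, g)
  cls <- integrate_de(classify_targets(occ), occ_in$de_table)
  expect_equal(cls$class, pl$class)
  expect_equal(cls$de_status, pl$de_status)
  pc <- attr(cls, "partition_counts")
  bound <- pl$class != "unbound"
  indep <- pl$class == "corest_independent"
  expect_equal(unname(pc["bound"]), sum(bound))
  expect_equal(unname(pc["independent_up"]),
               sum(indep & pl$de_status == "up"))
  expect_equal(unname(pc["bound_down"]), sum(bound & pl$de_status == "down"))
  expect_true(pc["bound_up"] >= pc["independent_up"])
  expect_true(pc["bound_down"] >= pc["independent_down"])
})

test_that("loosening thresholds is monotone in bound count and signal", {
  g <- simulate_genes(80, seed = 8)
  pl <- simulate_planted_classes(g, seed = 9)
  occ_in <- simulate_occupancy_and_de(g, pl, noise_sd = 0.5, seed = 10)
  occ <- occupancy_set(occ_in$peak_sets, g)
  bound_at <- function(d) sum(classify_targets(occ, delta_bind = d)$bound)
  expect_true(bound_at(0.3) <= bound_at(0.5))
  expect_true(bound_at(0.5) <= bound_at(0.9))

  pk <- occ_in$peak_sets$ZNF217_control
  strict <- assign_signal(pk, g, peak_fdr = 0.01)
  loose <- assign_signal(pk, g, peak_fdr = 0.5)
  expect_true(all(loose >= strict))
})
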