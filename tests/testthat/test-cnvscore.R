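# constant-depth cohort helper: n samples over the bins of a small panel
const_depth_matrix <- function(n = 6, depth = 100, panel = tiny_panel(),
                               groups = "cohort", sexes = "female") {
  bins <- build_bins(panel)
  samples <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                        group = rep_len(groups, n), sex = rep_len(sexes, n))
  bin_matrix(matrix(depth, nrow = n, ncol = nrow(bins)), bins, samples, kind = "depth")
}

test_that("build_bins partitions the target into near-equal pieces", {
  p100 <- panel_target(genomic_intervals("chr1", 0L, 100L, "G|ex1"))
  expect_equal(nrow(build_bins(p100)), 1L)

  p250 <- panel_target(genomic_intervals("chr1", 0L, 250L, "G|ex1"))
  b <- build_bins(p250)
  expect_equal(nrow(b), 3L)
  expect_equal(sort(b$end - b$start), c(83L, 83L, 84L))

  # every target base in exactly one bin, for a multi-gene panel
  sp <- simulate_panel(n_genes = 4, seed = 2)
  bins <- build_bins(sp$panel)
  expect_equal(sum(bins$end - bins$start), panel_size(sp$panel))
  expect_equal(anyDuplicated(bins$bin_id), 0L)
  cover <- unlist(lapply(seq_len(nrow(bins)), function(i)
    paste(bins$chrom[i], seq.int(bins$start[i], bins$end[i] - 1L))))
  expect_equal(anyDuplicated(cover), 0L)
})

test_that("raw bin scores are log2 ratios against the cohort reference", {
  # identical constant cohort scores 0 everywhere
  sc <- raw_bin_scores(const_depth_matrix())
  expect_true(all(abs(sc$values) < 1e-12))

  # half-depth cell scores about -1 (hand-computed medians)
  p4 <- panel_target(genomic_intervals("chr1", 0L, 480L, "G|ex1"))  # 4 bins
  dm <- const_depth_matrix(n = 3, panel = p4)
  dm$values[3, 4] <- 50
  sc <- raw_bin_scores(dm)
  expect_equal(unname(sc$values[3, 4]), log2(50.5 / 100.5), tolerance = 1e-12)
  expect_equal(unname(sc$values[3, 4]), -0.9928, tolerance = 1e-3)
  others <- sc$values[-(3 * 4)]  # column-major index of [3,4] is the 12th cell
  expect_true(all(abs(others[seq_len(11)]) < 1e-12))

  # homozygous-deletion spike at a 100x cohort: pseudocount bounds the score
  dm2 <- const_depth_matrix(n = 10)
  dm2$values[1, 2] <- 0
  sc2 <- raw_bin_scores(dm2)
  expect_equal(sc2$values[1, 2], log2((0.5 / 100) / (100.5 / 100)), tolerance = 1e-12)
  expect_lt(sc2$values[1, 2], -7.5)

  expect_error(raw_bin_scores(const_depth_matrix(n = 2)), "at least 3")
})

test_that("group median normalization centers each group per bin", {
  bins <- build_bins(panel_target(genomic_intervals("chr1", 0L, 100L, "G|ex1")))
  mk <- function(col, group = "g") {
    bin_matrix(matrix(col, ncol = 1), bins,
               data.frame(sample_id = sprintf("S%d", seq_along(col)), group = group,
                          sex = "female"),
               kind = "raw_score")
  }
  nm <- group_median_normalize(mk(c(0.1, 0.0, -0.05)))
  expect_equal(as.numeric(nm$values), c(0.1, 0.0, -0.05))  # median already 0

  nm2 <- group_median_normalize(mk(rep(0.7, 5)))
  expect_true(all(nm2$values == 0))

  # odd group: per-bin median of output is exactly 0
  nm3 <- group_median_normalize(mk(c(0.4, 0.1, -0.2, 0.9, 0.3)))
  expect_equal(median(nm3$values[, 1]), 0)

  expect_error(group_median_normalize(mk(c(0.1, 0.2))), "smaller than 3")
})

test_that("the excess-call mask uses a strict 4% rule within sample groups", {
  bins <- build_bins(panel_target(genomic_intervals("chr1", 0L, 100L, "G|ex1")))
  mk_scores <- function(n_hit, n = 125) {
    v <- matrix(0, nrow = n, ncol = 1)
    if (n_hit > 0) v[seq_len(n_hit), 1] <- -1
    bin_matrix(v, bins, data.frame(sample_id = sprintf("S%03d", 1:n),
                                   group = "lab3", sex = "female"),
               kind = "normalized_score")
  }
  m6 <- mask_noninformative(mk_scores(6))   # 6/125 = 4.8% > 4%
  expect_true(m6$masked)
  expect_match(m6$reason, "excess_calls")
  m5 <- mask_noninformative(mk_scores(5))   # 5/125 = 4.0%, not exceeding
  expect_false(m5$masked)
})

test_that("X-chromosome bins are masked in male-containing cohorts unless sex-aware", {
  panel <- panel_target(genomic_intervals(c("chr1", "chrX"), c(0L, 0L), c(100L, 100L),
                                          c("G1|ex1", "GX|ex1")))
  dm <- const_depth_matrix(n = 6, panel = panel, sexes = c("female", "male"))
  sc <- group_median_normalize(raw_bin_scores(dm))
  m <- mask_noninformative(sc)
  xrow <- m[grepl("GX", m$bin_id), ]
  expect_true(xrow$masked)
  expect_match(xrow$reason, "x_in_males")
  expect_false(m$masked[grepl("G1", m$bin_id)])

  # all-female cohort: X bins stay
  dmf <- const_depth_matrix(n = 6, panel = panel, sexes = "female")
  mf <- mask_noninformative(group_median_normalize(raw_bin_scores(dmf)))
  expect_false(any(mf$masked))
})

test_that("low cohort depth marks bins non-informative", {
  dm <- const_depth_matrix(n = 6)
  dm$values[, 1] <- 5  # cohort median 5 < 20
  sc <- group_median_normalize(raw_bin_scores(dm))
  m <- mask_noninformative(sc, depths = dm)
  expect_true(m$masked[1])
  expect_match(m$reason[1], "low_reference_depth")
})

test_that("CNV calling uses strict thresholds and run-length confidence", {
  bins <- build_bins(panel_target(genomic_intervals("chr1", 0L, 500L, "G|ex1")))
  mk <- function(scores_row) {
    v <- matrix(0, nrow = 3, ncol = nrow(bins))
    v[1, seq_along(scores_row)] <- scores_row
    bin_matrix(v, bins, data.frame(sample_id = c("case", "n1", "n2"),
                                   group = "g", sex = "female"),
               kind = "normalized_score")
  }
  one <- call_cnvs(mk(c(-1.0)))
  expect_equal(one$direction, "deletion")
  expect_equal(one$confidence, "single_bin")
  expect_equal(one$sample_id, "case")

  dup <- call_cnvs(mk(c(0.58, 0.58, 0.58)))
  expect_equal(dup$direction, "duplication")
  expect_equal(dup$run_length, 3L)
  expect_equal(dup$confidence, "consecutive_run")

  # boundary values are not calls
  expect_equal(nrow(call_cnvs(mk(c(-0.6)))), 0L)
  expect_equal(nrow(call_cnvs(mk(c(0.45)))), 0L)
})

test_that("masked bins are excluded from calling", {
  bins <- build_bins(panel_target(genomic_intervals("chr1", 0L, 300L, "G|ex1")))
  v <- matrix(0, nrow = 3, ncol = nrow(bins))
  v[1, 1] <- -2
  nm <- bin_matrix(v, bins, data.frame(sample_id = c("a", "b", "c"), group = "g",
                                       sex = "female"),
                   kind = "normalized_score")
  mask <- data.frame(bin_id = bins$bin_id,
                     masked = c(TRUE, rep(FALSE, nrow(bins) - 1)),
                     reason = "excess_calls")
  expect_equal(nrow(call_cnvs(nm, mask)), 0L)
  expect_equal(nrow(call_cnvs(nm)), 1L)
})

test_that("suspected_samples lists unique callers per gene", {
  expect_equal(nrow(suspected_samples(call_cnvs(
    group_median_normalize(raw_bin_scores(const_depth_matrix()))), "GENEA")), 0L)

  sp <- simulate_panel(n_genes = 2, seed = 6)
  dm <- simulate_cohort_depth(sp$panel, sim_config(seed = 6, n_samples = 20))
  gene <- dm$bins$gene[1]
  gene_bins <- which(dm$bins$gene == gene)[1:3]
  dm <- spike_cnv(dm, "S003", gene_bins, 1)
  dm <- spike_cnv(dm, "S011", gene_bins, 3)
  calls <- call_cnvs(group_median_normalize(raw_bin_scores(dm)))
  sus <- suspected_samples(calls, gene)
  expect_setequal(sus$sample_id, c("S003", "S011"))
  expect_equal(sort(sus$directions), c("deletion", "duplication"))
})

test_that("an all-equal cohort yields zero calls and depth rescaling changes nothing", {
  dm <- simulate_cohort_depth(tiny_panel(), sim_config(seed = 15, n_samples = 12))
  calls0 <- call_cnvs(group_median_normalize(raw_bin_scores(dm)))
  # whole-sample depth scaling (library size) must not create or destroy calls
  dm2 <- dm
  dm2$values[4, ] <- dm2$values[4, ] * 1.8
  calls1 <- call_cnvs(group_median_normalize(raw_bin_scores(dm2)))
  expect_equal(nrow(calls0), 0L)
  expect_equal(nrow(calls1), 0L)

  dm3 <- spike_cnv(dm, "S002", 1:2, 1)
  dm4 <- dm3
  dm4$values[2, ] <- dm4$values[2, ] * 1.8
  c3 <- call_cnvs(group_median_normalize(raw_bin_scores(dm3)))
  c4 <- call_cnvs(group_median_normalize(raw_bin_scores(dm4)))
  expect_equal(c4[, c("sample_id", "gene", "direction", "first_bin", "run_length")],
               c3[, c("sample_id", "gene", "direction", "first_bin", "run_length")])
})

test_that("male X bins score near -1 against a female-majority reference", {
  # autosomal target dominates, as in a real panel, so the within-sample
  # median normalization is anchored on diploid bins
  panel <- panel_target(genomic_intervals(c("chr1", "chrX"), c(0L, 0L),
                                          c(2400L, 600L), c("G1|ex1", "GX|ex1")))
  dm <- simulate_cohort_depth(panel, sim_config(seed = 31, n_samples = 24),
                              sexes = c(rep("female", 20), rep("male", 4)))
  sc <- group_median_normalize(raw_bin_scores(dm))
  xbins <- grepl("GX", sc$bins$bin_id)
  males <- sc$samples$sex == "male"
  expect_equal(mean(sc$values[males, xbins]), -1, tolerance = 0.15)
  expect_equal(mean(abs(sc$values[!males, xbins])), 0, tolerance = 0.15)
})

test_that("sex-aware mode rescales male X depth instead of masking", {
  cfg <- cnv_config(sex_aware = TRUE)
  panel <- panel_target(genomic_intervals(c("chr1", "chrX"), c(0L, 0L),
                                          c(2400L, 600L), c("G1|ex1", "GX|ex1")))
  dm <- simulate_cohort_depth(panel, sim_config(seed = 32, n_samples = 24),
                              sexes = c(rep("female", 18), rep("male", 6)))
  sc <- group_median_normalize(raw_bin_scores(dm, cfg))
  m <- mask_noninformative(sc, cfg)
  expect_false(any(m$masked[grepl("GX", m$bin_id)]))
  xbins <- grepl("GX", sc$bins$bin_id)
  males <- sc$samples$sex == "male"
  expect_equal(mean(sc$values[males, xbins]), 0, tolerance = 0.15)
})

test_that("bin matrix TSV round trip preserves values and bin structure", {
  dm <- simulate_cohort_depth(tiny_panel(), sim_config(seed = 44, n_samples = 4))
  path <- tempfile(fileext = ".tsv")
  write_bin_matrix(dm, path)
  back <- read_bin_matrix_tsv(path, samples = dm$samples)
  expect_equal(back$bins$bin_id, dm$bins$bin_id)
  expect_equal(unname(back$values), unname(dm$values), tolerance = 1e-9)
})

test_that("gene score plots are written with threshold lines", {
  dm <- simulate_cohort_depth(tiny_panel(), sim_config(seed = 45, n_samples = 6))
  nm <- group_median_normalize(raw_bin_scores(dm))
  out <- tempfile(fileext = ".png")
  plot_gene_scores(nm, "GENEA", out_path = out, highlight = "S001")
  expect_true(file.exists(out) && file.size(out) > 0)
})
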