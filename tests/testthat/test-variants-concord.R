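test_that("normalize_variant trims shared bases per the minimal representation", {
  expect_equal(normalize_variant(100L, "CA", "CG"), list(pos = 101L, ref = "A", alt = "G"))
  expect_equal(normalize_variant(100L, "A", "G"), list(pos = 100L, ref = "A", alt = "G"))
  expect_equal(normalize_variant(100L, "ATT", "AT"), list(pos = 101L, ref = "TT", alt = "T"))
  expect_error(normalize_variant(100L, "A", "A"), "not a variant")
})

test_that("normalization is idempotent and preserves the edited haplotype", {
  apply_variant <- function(hap, pos, ref, alt) {
    stopifnot(substr(hap, pos, pos + nchar(ref) - 1) == ref)
    paste0(substr(hap, 1, pos - 1), alt, substr(hap, pos + nchar(ref), nchar(hap)))
  }
  set.seed(33)
  bases <- c("A", "C", "G", "T")
  for (i in 1:50) {
    hap <- paste(sample(bases, 30, replace = TRUE), collapse = "")
    pos <- sample(5:15, 1)
    ref <- substr(hap, pos, pos + sample(0:4, 1))
    alt <- paste(sample(bases, sample(1:5, 1), replace = TRUE), collapse = "")
    if (ref == alt) next
    v <- normalize_variant(pos, ref, alt)
    # idempotence
    expect_equal(normalize_variant(v$pos, v$ref, v$alt), v)
    # same edited sequence as the raw representation (brute-force oracle)
    expect_equal(apply_variant(hap, v$pos, v$ref, v$alt),
                 apply_variant(hap, pos, ref, alt))
  }
})

test_that("filter_calls applies strict quality, flanked-region and AF rules", {
  panel <- panel_target(genomic_intervals("chr1", 99L, 200L, "G|ex1")) # 1-based 100..200
  mk <- function(pos, quality = 500, af = NA_real_) {
    data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "G",
               quality = quality, allelic_fraction = af, stringsAsFactors = FALSE)
  }
  cfg <- concord_config()

  # quality exactly 100 fails the strict > rule
  cs <- call_set(mk(150L, quality = 100))
  expect_equal(nrow(filter_calls(cs, panel, cfg)$variants), 0L)

  # 12 bp into the intron passes, 13 bp fails (flank window is [88, 212] 1-based)
  expect_equal(nrow(filter_calls(call_set(mk(88L)), panel, cfg)$variants), 1L)
  expect_equal(nrow(filter_calls(call_set(mk(87L)), panel, cfg)$variants), 0L)
  expect_equal(nrow(filter_calls(call_set(mk(212L)), panel, cfg)$variants), 1L)
  expect_equal(nrow(filter_calls(call_set(mk(213L)), panel, cfg)$variants), 0L)

  # 5 variants, 2 failing (quality 50; AF 0.10); missing AF passes
  v <- rbind(mk(110L), mk(120L), mk(130L, quality = 50), mk(140L, af = 0.10),
             mk(150L, af = 0.5))
  kept <- filter_calls(call_set(v), panel, cfg)
  expect_equal(nrow(kept$variants), 3L)
  expect_equal(sort(kept$variants$pos), c(110L, 120L, 150L))

  # idempotence
  expect_equal(filter_calls(kept, panel, cfg)$variants, kept$variants)
})

test_that("concordance reports set algebra over normalized keys", {
  a <- snv_set(c(10L, 20L, 30L), "A")
  b <- snv_set(c(20L, 30L, 40L), "B")
  cc <- concordance(list(a, b), cfg = NULL)
  expect_equal(cc$summary$union, 4L)
  expect_equal(cc$summary$intersection, 2L)
  expect_equal(unname(cc$summary$per_set), c(3L, 3L))

  # identical sets: full concordance
  cc2 <- concordance(list(snv_set(1:5, "A"), snv_set(1:5, "B")), cfg = NULL)
  expect_equal(cc2$summary$intersection, cc2$summary$union)
  expect_equal(unname(cc2$summary$pct_of_union), c(100, 100))

  expect_error(concordance(list(a), cfg = NULL), "at least two")
})

test_that("concordance counts are permutation-invariant and properly ordered", {
  set.seed(4)
  sets <- lapply(1:4, function(i) snv_set(sample(1:60, 30), paste0("r", i)))
  cc <- concordance(sets, cfg = NULL)
  cc_perm <- concordance(rev(sets), cfg = NULL)
  expect_equal(cc$summary$union, cc_perm$summary$union)
  expect_equal(cc$summary$intersection, cc_perm$summary$intersection)
  expect_equal(unname(sort(cc$summary$per_set)), unname(sort(cc_perm$summary$per_set)))
  expect_lte(cc$summary$intersection, min(cc$summary$per_set))
  expect_lte(max(cc$summary$per_set), cc$summary$union)
})

test_that("replicate intersection matches the (1-d)^k closed form", {
  sp <- simulate_panel(n_genes = 4, seed = 8)
  d <- 0.02; k <- 3; n <- 300
  inter <- vapply(1:40, function(s) {
    reps <- simulate_callset_replicates(sp$panel, n, k,
                                        sim_config(seed = 1000 + s, dropout = d))
    concordance(reps, sp$panel)$summary$intersection
  }, numeric(1))
  expected <- n * (1 - d)^k
  mc_se <- sqrt(n * (1 - d)^k * (1 - (1 - d)^k)) / sqrt(40)
  expect_lt(abs(mean(inter) - expected), 4 * mc_se + 1e-9)
})

test_that("coverage_factor is the ratio of mean coverages over shared variants", {
  expect_equal(coverage_factor(c(100, 200), c(50, 100)), 2.0)
  expect_equal(coverage_factor(c(80, 90, 100), c(80, 90, 100)), 1.0)
  expect_error(coverage_factor(c(0, 0), c(1, 2)), "zero mean")
  expect_error(coverage_factor(1:3, 1:2), "equal positive length")
  expect_equal(coverage_factor(c(100, 200), c(50, 100), method = "median"), 2.0)
})

test_that("VUS prioritization needs rare MAFs and concordant deleterious verdicts", {
  expect_true(prioritize_vus(list(exac = 0.0005, g1000 = 0.002,
                                  sift = "deleterious", pp2 = "deleterious",
                                  mt = "deleterious"),
                             c("exac", "g1000"), c("sift", "pp2", "mt")))
  expect_false(prioritize_vus(list(exac = 0.02, sift = "deleterious"),
                              c("exac", "g1000"), c("sift")))
  expect_false(prioritize_vus(list(exac = 0.001, sift = "deleterious", pp2 = "benign"),
                              c("exac"), c("sift", "pp2")))
  # missing MAFs are treated as rare, but some verdict must exist
  expect_true(prioritize_vus(list(sift = "deleterious"), c("exac"), c("sift")))
  expect_false(prioritize_vus(list(exac = 0.001), c("exac"), c("sift")))
})

test_that("medium-indel flag is strict on inserted length", {
  cfg <- concord_config()
  expect_true(flag_medium_indel("A", paste(rep("T", 37), collapse = "")))   # +36
  expect_false(flag_medium_indel("A", paste(rep("T", 36), collapse = "")))  # +35
  expect_false(flag_medium_indel("A", "G"))
  expect_false(flag_medium_indel("ATTT", "A"))  # deletions are not flagged
})

test_that("VCF round trip preserves variant identity and metadata", {
  skip_if_not_installed("vcfR")
  cs <- call_set(data.frame(chrom = "chr1", pos = c(120L, 140L), ref = c("A", "CA"),
                            alt = c("G", "CG"), quality = c(500, 800),
                            coverage = c(90L, 110L), allelic_fraction = c(0.48, 0.52),
                            stringsAsFactors = FALSE))
  path <- tempfile(fileext = ".vcf")
  write_callset_vcf(cs, path)
  back <- read_callset_vcf(path)
  expect_equal(variant_key(back$variants), variant_key(cs$variants))
  expect_equal(back$variants$coverage, cs$variants$coverage)
})

test_that("replicate tables split into per-replicate call sets", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tcov.r1\tq.r1\tcov.r2\tq.r2",
               "chr1\t100\tA\tG\t90\t500\t85\t450",
               "chr1\t200\tC\tT\t70\t300\tNA\tNA"), path)
  sets <- read_replicate_table(path)
  expect_equal(names(sets), c("r1", "r2"))
  expect_equal(nrow(sets$r1$variants), 2L)
  expect_equal(nrow(sets$r2$variants), 1L)
})
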