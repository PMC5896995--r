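# Synthetic cohort simulator.
#
# Generates data with the statistical structure the analyses assume: a
# multi-gene capture panel, negative-binomial depth with GC bias and
# per-sample scale factors, CNV spike-ins at integer copy numbers, replicate
# call sets with dropout and a quality-fail fraction, truth/call pairs with
# planted FP/FN rates, and fragment cut sites that are uniform or
# motif-biased. Every generator is deterministic under a fixed seed and
# restores the caller's RNG state.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Simulation configuration
#'
#' Defaults describe a routine validation run: 30 pooled barcoded samples
#' per run at a targeted mean coverage of 100x, over-dispersed
#' negative-binomial depth noise (capture panels are noisier than Poisson),
#' a mild smooth GC bias, and small replicate dropout / quality-fail /
#' call-error rates.
#'
#' @param seed Integer seed; identical seeds give identical outputs.
#' @param n_samples Samples per simulated run (default 30).
#' @param mean_coverage Targeted mean depth (default 100).
#' @param nb_dispersion Inverse-size dispersion of the per-bin total read
#'   count (default 1/150, giving a bin log2-ratio SD of about 0.12 at 100x).
#' @param base_dispersion Inverse-size dispersion of per-base depth used for
#'   coverage profiles (default 0.05).
#' @param gc_bias_amplitude Strength of the quadratic GC bias on bin/interval
#'   coverage (default 0.3; 0 disables).
#' @param sample_scale_sd SD of the per-sample lognormal scale factor
#'   (default 0.1).
#' @param cut_bias_beta Mixture weight of motif-preferring fragment cuts
#'   (0 = uniform shearing; default 0).
#' @param dropout Per-replicate variant dropout probability (default 0.01).
#' @param q_fail_rate Fraction of retained calls drawn with caller quality
#'   at or below 100 (default 0).
#' @param fp_rate,fn_rate False-positive / false-negative call rates for
#'   truth-set simulation (defaults 0.01).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_samples = 30L, mean_coverage = 100,
                       nb_dispersion = 1 / 150, base_dispersion = 0.05,
                       gc_bias_amplitude = 0.3, sample_scale_sd = 0.1,
                       cut_bias_beta = 0, dropout = 0.01, q_fail_rate = 0,
                       fp_rate = 0.01, fn_rate = 0.01) {
  stopifnot(mean_coverage > 0, nb_dispersion >= 0, base_dispersion >= 0,
            cut_bias_beta >= 0, cut_bias_beta <= 1,
            dropout >= 0, dropout <= 1, q_fail_rate >= 0, q_fail_rate <= 1,
            fp_rate >= 0, fp_rate <= 1, fn_rate >= 0, fn_rate <= 1)
  structure(as.list(environment()), class = "sim_config")
}

.rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

# quadratic GC bias factor, renormalized to mean 1 over the supplied gc values
.gc_bias_factor <- function(gc, amplitude) {
  g <- pmax(0.02, 1 - amplitude * ((gc - 0.45) / 0.25)^2)
  g / mean(g)
}

#' Simulate a synthetic capture panel with reference sequences
#'
#' Builds a multi-gene exon panel on synthetic chromosomes, one gene per
#' chromosome region, with per-gene GC content spread over a range so GC-bias
#' behaviour is observable. Optionally adds an X-chromosome gene for
#' sex-handling tests.
#'
#' @param n_genes Number of autosomal genes (default 8).
#' @param exons_per_gene Exon count range, inclusive (default 2..8).
#' @param exon_bp Exon length range (default 80..400).
#' @param include_x Add one gene on chromosome X (default FALSE).
#' @param gc_range Range of per-gene GC content (default 0.30..0.72).
#' @param seed Seed.
#' @return list: `panel` (a `panel_target`), `sequences` (named character
#'   vector of full chromosome sequences).
#' @export
simulate_panel <- function(n_genes = 8L, exons_per_gene = c(2L, 8L),
                           exon_bp = c(80L, 400L), include_x = FALSE,
                           gc_range = c(0.30, 0.72), seed = 1L) {
  .with_seed(seed, {
    genes <- sprintf("GENE%02d", seq_len(n_genes))
    chroms <- sprintf("chr%d", seq_len(n_genes))
    if (include_x) { genes <- c(genes, "GENEX"); chroms <- c(chroms, "chrX") }
    gcs <- seq(gc_range[1], gc_range[2], length.out = length(genes))
    rows <- list(); seqs <- list()
    for (i in seq_along(genes)) {
      n_ex <- sample(seq(exons_per_gene[1], exons_per_gene[2]), 1)
      widths <- sample(seq(exon_bp[1], exon_bp[2]), n_ex, replace = TRUE)
      gaps <- sample(200:1500, n_ex, replace = TRUE)
      starts <- 1000L + cumsum(gaps) + c(0L, cumsum(widths[-n_ex]))
      rows[[i]] <- genomic_intervals(chroms[i], starts, starts + widths,
                                     sprintf("%s|ex%d", genes[i], seq_len(n_ex)))
      chrom_len <- max(starts + widths) + 2000L
      p_gc <- gcs[i]
      seqs[[chroms[i]]] <- paste(sample(c("A", "T", "G", "C"), chrom_len, replace = TRUE,
                                        prob = c((1 - p_gc) / 2, (1 - p_gc) / 2,
                                                 p_gc / 2, p_gc / 2)),
                                 collapse = "")
    }
    list(panel = panel_target(do.call(rbind, rows)),
         sequences = unlist(seqs))
  })
}

.bin_gc <- function(bins, sequences) {
  if (is.null(sequences)) return(runif(nrow(bins), 0.35, 0.65))
  vapply(seq_len(nrow(bins)), function(i) {
    seqc <- sequences[[bins$chrom[i]]]
    if (is.null(seqc)) 0.5 else gc_fraction(substr(seqc, bins$start[i] + 1L, bins$end[i]))
  }, numeric(1))
}

#' Simulate a cohort depth matrix over panel bins
#'
#' Per-bin total read-base counts are drawn negative-binomially with mean
#' `lambda_s * g_b * width_b`, where `lambda_s` is a lognormal per-sample
#' scale around `mean_coverage` and `g_b` a smooth quadratic GC-bias factor,
#' then divided by bin width to give mean per-base depth.
#'
#' @param panel A `panel_target` (bins built with [build_bins()]) or a
#'   prebuilt `bin_spec`.
#' @param cfg A `sim_config`.
#' @param sequences Optional chromosome sequences for real bin GC; without
#'   them bin GC is drawn uniformly in 0.35..0.65.
#' @param groups Group label(s) for the sample sheet (recycled).
#' @param sexes Sex label(s) (recycled; default "female").
#' @return A depth-kind `bin_matrix`.
#' @export
simulate_cohort_depth <- function(panel, cfg = sim_config(), sequences = NULL,
                                  groups = "cohort", sexes = "female") {
  bins <- if (inherits(panel, "panel_target")) build_bins(panel) else panel
  .with_seed(cfg$seed, {
    n <- cfg$n_samples
    gc <- .bin_gc(bins, sequences)
    g <- .gc_bias_factor(gc, cfg$gc_bias_amplitude)
    lambda <- cfg$mean_coverage *
      exp(rnorm(n, -cfg$sample_scale_sd^2 / 2, cfg$sample_scale_sd))
    w <- bins$end - bins$start
    male <- rep_len(sexes, n) == "male"
    xbin <- .is_x_chrom(bins$chrom)
    vals <- matrix(0, nrow = n, ncol = nrow(bins))
    for (s in seq_len(n)) {
      mu <- lambda[s] * g * w
      if (male[s]) mu[xbin] <- mu[xbin] / 2
      vals[s, ] <- .rnb(nrow(bins), mu, cfg$nb_dispersion) / w
    }
    samples <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                          group = rep_len(groups, n),
                          sex = rep_len(sexes, n), stringsAsFactors = FALSE)
    bin_matrix(vals, bins, samples, kind = "depth")
  })
}

#' Simulate a per-base depth profile over the panel target
#'
#' @param panel A `panel_target`.
#' @param cfg A `sim_config`.
#' @param sequences Optional chromosome sequences: per-interval GC then drives
#'   the bias factor.
#' @param sample_id Sample identifier.
#' @return A `depth_profile`.
#' @export
simulate_depth_profile <- function(panel, cfg = sim_config(), sequences = NULL,
                                   sample_id = "sim") {
  .with_seed(cfg$seed, {
    tg <- panel$target
    gc <- .bin_gc(tg, sequences)
    g <- .gc_bias_factor(gc, cfg$gc_bias_amplitude)
    lambda <- cfg$mean_coverage *
      exp(rnorm(1, -cfg$sample_scale_sd^2 / 2, cfg$sample_scale_sd))
    depth <- unlist(lapply(seq_len(nrow(tg)), function(i) {
      w <- tg$end[i] - tg$start[i]
      .rnb(w, lambda * g[i], cfg$base_dispersion)
    }), use.names = FALSE)
    depth_profile(panel, sample_id = sample_id, depth = depth)
  })
}

#' Plant a CNV into a simulated depth matrix
#'
#' Multiplies the affected depths by `copies / 2` against the diploid
#' baseline, preserving the sampled noise.
#'
#' @param depths A depth `bin_matrix`.
#' @param sample Sample id (or row index).
#' @param bin_range Contiguous bin indices or bin ids.
#' @param copies Integer copy number 0..4 (2 = no change).
#' @return The modified `bin_matrix`.
#' @export
spike_cnv <- function(depths, sample, bin_range, copies) {
  if (!copies %in% 0:4) stop("copies must be an integer in 0..4")
  s <- if (is.character(sample)) match(sample, depths$samples$sample_id) else sample
  if (is.na(s) || s < 1 || s > nrow(depths$values)) stop("unknown sample")
  b <- if (is.character(bin_range)) match(bin_range, depths$bins$bin_id) else bin_range
  if (anyNA(b) || any(b < 1) || any(b > ncol(depths$values))) stop("bin_range outside matrix")
  depths$values[s, b] <- depths$values[s, b] * (copies / 2)
  depths
}

#' Simulate replicate call sets with dropout and quality failures
#'
#' A master variant list is placed at distinct panel-target positions; each
#' replicate keeps a variant with probability `1 - dropout` and draws its
#' caller quality so a fraction `q_fail_rate` falls at or below 100 (and is
#' later removed by the standard quality filter).
#'
#' @param panel A `panel_target`.
#' @param n_variants Master list size.
#' @param k_replicates Number of replicates.
#' @param cfg A `sim_config`.
#' @return list of `call_set`s labelled `rep1..repK`.
#' @export
simulate_callset_replicates <- function(panel, n_variants, k_replicates,
                                        cfg = sim_config()) {
  stopifnot(n_variants >= 1, k_replicates >= 1)
  .with_seed(cfg$seed, {
    master <- .random_snvs(panel, n_variants)
    lapply(seq_len(k_replicates), function(k) {
      keep <- runif(n_variants) >= cfg$dropout
      v <- master[keep, , drop = FALSE]
      nk <- nrow(v)
      fail <- runif(nk) < cfg$q_fail_rate
      v$quality <- ifelse(fail, runif(nk, 20, 100), runif(nk, 101, 2000))
      v$coverage <- pmax(1L, round(rnorm(nk, cfg$mean_coverage, cfg$mean_coverage * 0.15)))
      call_set(v, sample_id = "simsample", replicate_label = sprintf("rep%d", k))
    })
  })
}

# distinct random SNVs inside the merged panel target
.random_snvs <- function(panel, n, exclude_pos = NULL) {
  tp <- target_positions(panel)
  pool <- seq_len(nrow(tp))
  if (!is.null(exclude_pos)) pool <- setdiff(pool, exclude_pos)
  if (n > length(pool)) stop("more variants requested than available target bases")
  pick <- sort(sample(pool, n))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  df <- data.frame(chrom = tp$chrom[pick], pos = tp$pos[pick] + 1L,
                   ref = ref, alt = alt, stringsAsFactors = FALSE)
  attr(df, "slot") <- pick
  df
}

#' Simulate a truth set and a caller's output over it
#'
#' Calls are the truth minus false-negative draws plus false positives at
#' unused target positions. Optionally a number of truth variants are called
#' with a low allelic fraction so the standard AF filter removes them
#' (turning them into filtering-induced false negatives).
#'
#' @param panel A `panel_target`.
#' @param n_variants Truth-set size.
#' @param cfg A `sim_config` (`fp_rate`, `fn_rate`).
#' @param n_low_af Number of truth variants emitted with allelic fraction
#'   below 0.15 (default 0).
#' @return list(truth = `call_set`, calls = `call_set`).
#' @export
simulate_truth_and_calls <- function(panel, n_variants, cfg = sim_config(),
                                     n_low_af = 0L) {
  if (n_variants > panel_size(panel)) stop("n_variants exceeds target size")
  .with_seed(cfg$seed, {
    truth <- .random_snvs(panel, n_variants)
    truth$genotype <- sample(c("het", "hom"), n_variants, replace = TRUE, prob = c(0.8, 0.2))
    truth$allelic_fraction <- ifelse(truth$genotype == "hom", 1,
                                     pmin(0.95, pmax(0.2, rnorm(n_variants, 0.5, 0.05))))
    truth$quality <- 5000
    miss <- runif(n_variants) < cfg$fn_rate
    calls <- truth[!miss, , drop = FALSE]
    if (n_low_af > 0) {
      lowidx <- sample(seq_len(nrow(calls)), min(n_low_af, nrow(calls)))
      calls$allelic_fraction[lowidx] <- runif(length(lowidx), 0.05, 0.14)
    }
    n_fp <- rbinom(1, n_variants, cfg$fp_rate)
    if (n_fp > 0) {
      fp <- .random_snvs(panel, n_fp, exclude_pos = attr(truth, "slot"))
      fp$genotype <- "het"
      fp$allelic_fraction <- runif(n_fp, 0.2, 0.6)
      fp$quality <- 5000
      calls <- rbind(calls, fp)
    }
    calls$quality <- runif(nrow(calls), 101, 2000)
    list(truth = call_set(truth, sample_id = "truth"),
         calls = call_set(calls, sample_id = "calls"))
  })
}

#' Simulate fragment end positions over a region
#'
#' Cut positions are drawn from the mixture
#' `(1 - beta) * uniform + beta * motif-preference`, where the preferred
#' positions are those immediately following a fixed dinucleotide (an
#' idealized nicking-enzyme preference). `beta = 0` models unbiased
#' ultrasound-like shearing.
#'
#' @param region_seq Region reference sequence (length >= 2).
#' @param n Number of end observations.
#' @param beta Motif-preference mixture weight in 0..1.
#' @param seed Seed.
#' @param motif Preferred dinucleotide (default `"TA"`).
#' @return data.frame with columns `pos` (1-based) and `kind`
#'   (`start`/`stop`), suitable for [terminal_composition()].
#' @export
simulate_read_ends <- function(region_seq, n, beta, seed = 1L, motif = "TA") {
  region_seq <- toupper(region_seq)
  len <- nchar(region_seq)
  if (len < 2) stop("region shorter than 2 bases")
  stopifnot(beta >= 0, beta <= 1)
  .with_seed(seed, {
    # cut lands on the motif's first base, so biased ends over-represent it
    hot <- as.integer(gregexpr(motif, region_seq, fixed = TRUE)[[1]])
    hot <- hot[hot > 0 & hot <= len]
    p <- rep((1 - beta) / len, len)
    if (length(hot) > 0) p[hot] <- p[hot] + beta / length(hot)
    else p <- rep(1 / len, len)
    p <- p / sum(p)
    data.frame(pos = sample.int(len, n, replace = TRUE, prob = p),
               kind = sample(c("start", "stop"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

#' Simulate read positions with a planted off-target fraction
#'
#' On-target reads start uniformly inside baits; off-target reads are placed
#' 251..5000 bases beyond the last bait of their chromosome, so they are
#' guaranteed to exceed the distance cutoff from every bait.
#'
#' @param panel A `panel_target`.
#' @param n Number of reads.
#' @param offtarget_rate Expected off-target fraction.
#' @param seed Seed.
#' @return data.frame with columns `chrom`, `pos` (0-based).
#' @export
simulate_read_positions <- function(panel, n, offtarget_rate = 0.1, seed = 1L) {
  .with_seed(seed, {
    baits <- panel$baits
    chrom_last <- tapply(baits$end, baits$chrom, max)
    off <- runif(n) < offtarget_rate
    row <- sample.int(nrow(baits), n, replace = TRUE)
    pos <- integer(n)
    for (i in seq_len(n)) {
      b <- baits[row[i], ]
      pos[i] <- if (off[i]) chrom_last[[b$chrom]] + sample(251:5000, 1)
      else sample(seq.int(b$start, b$end - 1L), 1)
    }
    data.frame(chrom = baits$chrom[row], pos = pos, stringsAsFactors = FALSE)
  })
}

#' Write a depth profile as a samtools-depth style TSV (1-based positions)
#' @param profile A `depth_profile`.
#' @param path Output path.
#' @param omit_zero Drop zero-depth rows (sparse file; default TRUE).
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(profile, path, omit_zero = TRUE) {
  tp <- target_positions(profile$panel)
  keep <- if (omit_zero) profile$depth > 0 else rep(TRUE, length(profile$depth))
  writeLines(sprintf("%s\t%d\t%d", tp$chrom[keep], tp$pos[keep] + 1L,
                     profile$depth[keep]), path)
  invisible(path)
}

#' Write a sample sheet TSV
#' @param samples data.frame with sample_id, group, sex.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
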