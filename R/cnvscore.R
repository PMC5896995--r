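# Cohort read-depth CNV scoring.
#
# Depth per bin is turned into a log2 ratio against a cohort reference
# (median-of-samples after within-sample median scaling), group-median
# normalized, then thresholded: bins below the deletion threshold or above
# the duplication threshold mark suspected samples. Non-informative bins
# (X-chromosome bins in mixed-sex cohorts, low-coverage bins, bins calling an
# improbable fraction of the cohort) are masked before calling.

#' CNV calling configuration
#'
#' @param del_threshold Normalized score strictly below which a bin indicates
#'   a deletion (default -0.6).
#' @param dup_threshold Score strictly above which a bin indicates a
#'   duplication (default 0.45; 0.5 is a published alternative and can be
#'   passed here).
#' @param max_call_fraction A bin calling more than this fraction of a sample
#'   group is non-informative (default 0.04, strict inequality).
#' @param min_run Consecutive-bin run length upgrading call confidence
#'   (default 2).
#' @param min_ref_depth Bins whose cohort median depth falls below this are
#'   non-informative (default 20).
#' @param pseudocount Added to depths before ratio computation (default 0.5).
#' @param sex_aware When TRUE, male X-bin depths are doubled before scoring
#'   instead of masking X bins (default FALSE: masking).
#' @return list of class `cnv_config`.
#' @export
cnv_config <- function(del_threshold = -0.6, dup_threshold = 0.45,
                       max_call_fraction = 0.04, min_run = 2L,
                       min_ref_depth = 20, pseudocount = 0.5,
                       sex_aware = FALSE) {
  stopifnot(del_threshold < 0, dup_threshold > 0,
            max_call_fraction > 0, max_call_fraction < 1)
  structure(list(del_threshold = del_threshold, dup_threshold = dup_threshold,
                 max_call_fraction = max_call_fraction, min_run = as.integer(min_run),
                 min_ref_depth = min_ref_depth, pseudocount = pseudocount,
                 sex_aware = sex_aware),
            class = "cnv_config")
}

#' Split a panel target into CNV scoring bins
#'
#' Each merged target interval is cut into `ceiling(width / max_bin_bp)`
#' near-equal pieces, so bins partition the target exactly (every base in
#' exactly one bin).
#'
#' @param panel A `panel_target`.
#' @param max_bin_bp Maximum bin width (default 120).
#' @return A `bin_spec` data.frame: bin_id (`gene_chrom_start_end`), gene,
#'   chrom, start, end, sorted by (chrom, start).
#' @export
build_bins <- function(panel, max_bin_bp = 120L) {
  if (panel_size(panel) == 0) stop("empty panel")
  rows <- list()
  for (g in names(panel$genes)) {
    gi <- panel$genes[[g]]
    for (i in seq_len(nrow(gi))) {
      w <- gi$end[i] - gi$start[i]
      k <- ceiling(w / max_bin_bp)
      cuts <- round(seq(0, w, length.out = k + 1))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, chrom = gi$chrom[i],
        start = gi$start[i] + as.integer(cuts[-(k + 1)]),
        end = gi$start[i] + as.integer(cuts[-1]),
        stringsAsFactors = FALSE
      )
    }
  }
  bins <- do.call(rbind, rows)
  bins <- bins[order(bins$chrom, bins$start), , drop = FALSE]
  bins <- data.frame(bin_id = sprintf("%s_%s_%d_%d", bins$gene, bins$chrom, bins$start, bins$end),
                     bins, stringsAsFactors = FALSE)
  if (anyDuplicated(bins$bin_id)) stop("non-unique bin identifiers")
  rownames(bins) <- NULL
  bins
}

#' Construct a bins-by-samples matrix with sample metadata
#'
#' @param values Numeric matrix, samples in rows, bins in columns.
#' @param bins A `bin_spec` (see [build_bins()]) matching the columns.
#' @param samples data.frame with columns `sample_id`, optional `group`
#'   (default "cohort") and `sex` (male/female/unknown; default unknown),
#'   matching the rows.
#' @param kind `"depth"`, `"raw_score"` or `"normalized_score"`.
#' @return A `bin_matrix` object.
#' @export
bin_matrix <- function(values, bins, samples, kind = c("depth", "raw_score", "normalized_score")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.character(samples)) samples <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  if (!"group" %in% names(samples)) samples$group <- "cohort"
  if (!"sex" %in% names(samples)) samples$sex <- "unknown"
  if (nrow(values) != nrow(samples)) stop("row count must match the sample sheet")
  if (ncol(values) != nrow(bins)) stop("column count must match the bin spec")
  if (kind == "depth" && any(values < 0, na.rm = TRUE)) stop("depths must be non-negative")
  dimnames(values) <- list(samples$sample_id, bins$bin_id)
  structure(list(values = values, bins = bins, samples = samples, kind = kind),
            class = "bin_matrix")
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat(sprintf("bin_matrix [%s]: %d samples x %d bins (%d genes)\n",
              x$kind, nrow(x$values), ncol(x$values), length(unique(x$bins$gene))))
  invisible(x)
}

#' Log2 bin ratio scores against the cohort reference
#'
#' Per sample, depths are scaled by the sample's median bin depth
#' (after adding `pseudocount`); the per-bin reference is the median of these
#' scaled values across samples; the score is the log2 ratio to that
#' reference. A diploid bin scores about 0, a heterozygous deletion about -1,
#' a three-copy duplication about +0.585.
#'
#' @param depths A depth-kind `bin_matrix` with at least 3 samples.
#' @param cfg A `cnv_config` (for `pseudocount`).
#' @return A raw_score `bin_matrix`; bins whose reference is 0 are recorded in
#'   its `unusable_bins` element (their scores are NA) for downstream masking.
#' @export
raw_bin_scores <- function(depths, cfg = cnv_config()) {
  if (depths$kind != "depth") stop("raw_bin_scores expects a depth matrix")
  if (nrow(depths$values) < 3) stop("at least 3 samples are required for a cohort reference")
  d <- depths$values
  if (cfg$sex_aware) {
    xbin <- .is_x_chrom(depths$bins$chrom)
    male <- depths$samples$sex == "male"
    if (any(xbin) && any(male)) d[male, xbin] <- 2 * d[male, xbin]
  }
  med_s <- apply(d, 1, median)
  if (any(med_s <= 0)) stop("sample with non-positive median depth")
  x <- (d + cfg$pseudocount) / med_s
  ref <- apply(x, 2, median)
  unusable <- ref <= 0
  score <- log2(sweep(x, 2, ifelse(unusable, NA_real_, ref), "/"))
  out <- bin_matrix(score, depths$bins, depths$samples, kind = "raw_score")
  out$unusable_bins <- depths$bins$bin_id[unusable]
  out
}

#' Subtract the per-bin median of each sample group
#'
#' Centers every bin on its group's median score so batch-level depth
#' structure cancels; within each group the per-bin median of the output is 0
#' (exactly, for odd group sizes).
#'
#' @param scores A raw_score `bin_matrix`; every sample needs a group label
#'   and every group at least 3 samples.
#' @return A normalized_score `bin_matrix`.
#' @export
group_median_normalize <- function(scores) {
  if (scores$kind == "depth") stop("group_median_normalize expects scores, not depths")
  groups <- scores$samples$group
  sizes <- table(groups)
  if (any(sizes < 3)) stop(sprintf("sample group smaller than 3: %s",
                                   paste(names(sizes)[sizes < 3], collapse = ", ")))
  v <- scores$values
  for (g in unique(groups)) {
    rows <- groups == g
    med <- apply(v[rows, , drop = FALSE], 2, median, na.rm = TRUE)
    v[rows, ] <- sweep(v[rows, , drop = FALSE], 2, med, "-")
  }
  out <- bin_matrix(v, scores$bins, scores$samples, kind = "normalized_score")
  out$unusable_bins <- scores$unusable_bins
  out
}

.is_x_chrom <- function(chrom) toupper(sub("^chr", "", chrom)) == "X"

#' Identify non-informative bins
#'
#' A bin is masked when (a) it lies on the X chromosome and the cohort
#' contains males (deletion-like male signal; skipped in sex-aware mode),
#' (b) its cohort reference depth is insufficient, or (c) the fraction of
#' samples it calls beyond the thresholds strictly exceeds
#' `max_call_fraction` in some sample group (an improbable event rate that
#' marks recurrent artifacts, e.g. pseudogene cross-mapping).
#'
#' @param scores A normalized_score (or raw_score) `bin_matrix`.
#' @param cfg A `cnv_config`.
#' @param depths Optional matching depth `bin_matrix` for the
#'   low-reference-depth rule.
#' @return data.frame: bin_id, masked (logical), reason
#'   (`x_in_males` / `low_reference_depth` / `excess_calls`, comma-joined).
#' @export
mask_noninformative <- function(scores, cfg = cnv_config(), depths = NULL) {
  bins <- scores$bins
  n_bins <- nrow(bins)
  reasons <- vector("list", n_bins)

  if (!cfg$sex_aware && any(scores$samples$sex == "male")) {
    for (b in which(.is_x_chrom(bins$chrom))) reasons[[b]] <- c(reasons[[b]], "x_in_males")
  }
  if (!is.null(depths)) {
    ref_depth <- apply(depths$values, 2, median)
    for (b in which(ref_depth < cfg$min_ref_depth))
      reasons[[b]] <- c(reasons[[b]], "low_reference_depth")
  }
  if (!is.null(scores$unusable_bins)) {
    for (b in which(bins$bin_id %in% scores$unusable_bins))
      reasons[[b]] <- c(reasons[[b]], "low_reference_depth")
  }
  v <- scores$values
  hit <- v < cfg$del_threshold | v > cfg$dup_threshold
  for (g in unique(scores$samples$group)) {
    rows <- scores$samples$group == g
    frac <- colSums(hit[rows, , drop = FALSE], na.rm = TRUE) / sum(rows)
    for (b in which(frac > cfg$max_call_fraction))
      reasons[[b]] <- c(reasons[[b]], "excess_calls")
  }
  data.frame(
    bin_id = bins$bin_id,
    masked = lengths(reasons) > 0,
    reason = vapply(reasons, function(r) paste(unique(r), collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Call CNVs from normalized bin scores
#'
#' Per sample and gene, masked bins are dropped and maximal runs of remaining
#' consecutive bins all strictly below the deletion threshold (or all
#' strictly above the duplication threshold) become calls. A run of at least
#' `min_run` bins gets `consecutive_run` confidence, single crossings
#' `single_bin`; run length upgrades confidence but a single bin already
#' makes the sample suspected.
#'
#' @param normalized A normalized_score `bin_matrix`.
#' @param mask Optional mask data.frame from [mask_noninformative()].
#' @param cfg A `cnv_config`.
#' @return data.frame of calls: sample_id, gene, direction, first_bin,
#'   last_bin, run_length, min_score, max_score, confidence.
#' @export
call_cnvs <- function(normalized, mask = NULL, cfg = cnv_config()) {
  if (normalized$kind != "normalized_score") stop("call_cnvs expects normalized scores")
  keep <- rep(TRUE, nrow(normalized$bins))
  if (!is.null(mask)) keep <- !mask$masked[match(normalized$bins$bin_id, mask$bin_id)]
  calls <- list()
  for (s in seq_len(nrow(normalized$values))) {
    for (g in unique(normalized$bins$gene)) {
      idx <- which(normalized$bins$gene == g & keep)
      if (length(idx) == 0) next
      sc <- normalized$values[s, idx]
      state <- ifelse(is.na(sc), "none",
                      ifelse(sc < cfg$del_threshold, "deletion",
                             ifelse(sc > cfg$dup_threshold, "duplication", "none")))
      r <- rle(state)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in which(r$values != "none")) {
        span <- idx[starts[k]:ends[k]]
        calls[[length(calls) + 1L]] <- data.frame(
          sample_id = normalized$samples$sample_id[s],
          gene = g,
          direction = r$values[k],
          first_bin = normalized$bins$bin_id[span[1]],
          last_bin = normalized$bins$bin_id[span[length(span)]],
          run_length = length(span),
          min_score = min(normalized$values[s, span]),
          max_score = max(normalized$values[s, span]),
          confidence = if (length(span) >= cfg$min_run) "consecutive_run" else "single_bin",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(calls) == 0) {
    return(data.frame(sample_id = character(), gene = character(),
                      direction = character(), first_bin = character(),
                      last_bin = character(), run_length = integer(),
                      min_score = numeric(), max_score = numeric(),
                      confidence = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Samples suspected of carrying a CNV in a gene
#'
#' A sample is suspected as soon as it has one unmasked call in the gene;
#' run length affects confidence, not suspicion.
#'
#' @param calls Call table from [call_cnvs()].
#' @param gene Gene symbol.
#' @return data.frame: sample_id, direction summary, best (longest) run and
#'   top confidence per sample.
#' @export
suspected_samples <- function(calls, gene) {
  sub <- calls[calls$gene == gene, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(data.frame(sample_id = character(), directions = character(),
                      max_run = integer(), confidence = character(),
                      stringsAsFactors = FALSE))
  }
  ids <- unique(sub$sample_id)
  do.call(rbind, lapply(ids, function(sid) {
    rows <- sub[sub$sample_id == sid, , drop = FALSE]
    data.frame(sample_id = sid,
               directions = paste(sort(unique(rows$direction)), collapse = "+"),
               max_run = max(rows$run_length),
               confidence = if (any(rows$confidence == "consecutive_run"))
                 "consecutive_run" else "single_bin",
               stringsAsFactors = FALSE)
  }))
}

#' Plot normalized bin scores along a gene with calling thresholds
#'
#' @param normalized A normalized_score `bin_matrix`.
#' @param gene Gene symbol.
#' @param cfg A `cnv_config` (threshold lines).
#' @param out_path PNG output path.
#' @param highlight Optional sample ids drawn in colour above the grey cohort.
#' @return `out_path`, invisibly.
#' @export
plot_gene_scores <- function(normalized, gene, cfg = cnv_config(), out_path,
                             highlight = NULL) {
  idx <- which(normalized$bins$gene == gene)
  if (length(idx) == 0) stop(sprintf("no bins for gene %s", gene))
  v <- normalized$values[, idx, drop = FALSE]
  grDevices::png(out_path, width = 900, height = 420)
  on.exit(grDevices::dev.off(), add = TRUE)
  ylim <- range(c(v, cfg$del_threshold, cfg$dup_threshold), na.rm = TRUE) + c(-0.2, 0.2)
  plot(NA, xlim = c(1, length(idx)), ylim = ylim, bty = "l",
       xlab = sprintf("%s bins (5' to 3')", gene), ylab = "normalized log2 score",
       main = sprintf("%s bin scores, %d samples", gene, nrow(v)))
  for (s in seq_len(nrow(v))) lines(seq_along(idx), v[s, ], col = "grey75")
  abline(h = c(cfg$del_threshold, cfg$dup_threshold), col = "red", lty = 3, lwd = 2)
  if (!is.null(highlight)) {
    cols <- grDevices::rainbow(length(highlight))
    for (i in seq_along(highlight)) {
      s <- match(highlight[i], normalized$samples$sample_id)
      if (!is.na(s)) lines(seq_along(idx), v[s, ], col = cols[i], lwd = 2)
    }
    legend("topright", legend = highlight, col = cols, lwd = 2, bty = "n", cex = 0.8)
  }
  invisible(out_path)
}

# ---- IO ---------------------------------------------------------------------

#' Write a bin matrix as TSV (bins as rows, samples as columns)
#' @param bm A `bin_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bin_matrix <- function(bm, path) {
  df <- data.frame(bin_id = bm$bins$bin_id, t(bm$values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bin matrix TSV written in bins-as-rows layout
#'
#' Bin ids must follow `gene_chrom_start_end`; remaining columns are samples.
#'
#' @param path TSV path with header.
#' @param samples Optional sample sheet data.frame (`sample_id`, `group`,
#'   `sex`); defaults to one cohort of unknown sex.
#' @param kind Matrix kind (default `"depth"`).
#' @return A `bin_matrix`.
#' @export
read_bin_matrix_tsv <- function(path, samples = NULL, kind = "depth") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  parts <- regmatches(ids, regexec("^(.*)_([^_]+)_([0-9]+)_([0-9]+)$", ids))
  bad <- which(vapply(parts, length, integer(1)) != 5)
  if (length(bad)) stop(sprintf("bin id not in gene_chrom_start_end form: %s", ids[bad[1]]))
  bins <- data.frame(
    bin_id = ids,
    gene = vapply(parts, `[`, character(1), 2),
    chrom = vapply(parts, `[`, character(1), 3),
    start = as.integer(vapply(parts, `[`, character(1), 4)),
    end = as.integer(vapply(parts, `[`, character(1), 5)),
    stringsAsFactors = FALSE
  )
  values <- t(as.matrix(df[, -1, drop = FALSE]))
  if (is.null(samples)) samples <- data.frame(sample_id = rownames(values),
                                              stringsAsFactors = FALSE)
  bin_matrix(values, bins, samples, kind = kind)
}

#' Read a sample sheet TSV (sample, group, sex)
#' @param path TSV path with header columns `sample_id`, `group`, `sex`.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("sample sheet needs a sample_id column")
  if (!"group" %in% names(df)) df$group <- "cohort"
  if (!"sex" %in% names(df)) df$sex <- "unknown"
  df
}
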