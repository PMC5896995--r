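# Truth-set benchmarking over a defined target.
#
# Variant matching is allele-exact on normalized (chrom, pos, ref, alt) keys;
# genotype is not required for a true positive, but zygosity discordances are
# reported. True negatives are counted at base level: every target base not
# occupied by a classified variant site, which is what makes specificity
# meaningful over a multi-hundred-kilobase panel.

#' Classify calls against a truth set
#'
#' Restricts both sets to `confident_region` (when given), then matches on
#' normalized allele keys: TP = call present in truth, FP = call absent from
#' truth, FN = truth variant not called. Each variant lands in exactly one
#' class.
#'
#' @param calls A `call_set`.
#' @param truth A `call_set` of truth genotypes.
#' @param confident_region Optional interval data.frame; variants outside it
#'   are excluded from every class.
#' @return data.frame with columns key, class (TP/FP/FN), genotype_call,
#'   genotype_truth, genotype_match, af_called, af_truth.
#' @export
classify_calls <- function(calls, truth, confident_region = NULL) {
  restrict <- function(v) {
    if (is.null(confident_region) || nrow(v) == 0) return(v)
    v[points_within(v$chrom, v$pos - 1L, confident_region), , drop = FALSE]
  }
  cv <- restrict(calls$variants)
  tv <- restrict(truth$variants)
  ck <- variant_key(cv); tk <- variant_key(tv)
  if (anyDuplicated(ck) || anyDuplicated(tk)) stop("duplicate variant keys within a set")
  m_call <- match(ck, tk)
  out_calls <- data.frame(
    key = ck,
    class = ifelse(is.na(m_call), "FP", "TP"),
    genotype_call = cv$genotype,
    genotype_truth = tv$genotype[m_call],
    af_called = cv$allelic_fraction,
    af_truth = tv$allelic_fraction[m_call],
    stringsAsFactors = FALSE
  )
  fn_idx <- which(!tk %in% ck)
  out_fn <- data.frame(
    key = tk[fn_idx], class = rep("FN", length(fn_idx)),
    genotype_call = rep(NA_character_, length(fn_idx)),
    genotype_truth = tv$genotype[fn_idx],
    af_called = rep(NA_real_, length(fn_idx)),
    af_truth = tv$allelic_fraction[fn_idx],
    stringsAsFactors = FALSE
  )
  out <- rbind(out_calls, out_fn)
  out$genotype_match <- out$class == "TP" &
    !is.na(out$genotype_call) & !is.na(out$genotype_truth) &
    out$genotype_call == out$genotype_truth
  rownames(out) <- NULL
  out
}

#' Benchmark metrics from classified counts
#'
#' True negatives are the target bases left over once every classified
#' variant site is accounted for: `tn = target_bases - tp - fp - fn`.
#'
#' @param tp,fp,fn Class counts.
#' @param target_bases Total bases of the benchmarked target.
#' @return A `benchmark_result`: list with the four counts, `target_bases`,
#'   `sensitivity` = tp/(tp+fn), `specificity` = tn/(tn+fp), `accuracy` =
#'   (tp+tn)/target_bases. Sensitivity is NA (with a warning) when tp+fn = 0.
#' @export
benchmark_metrics <- function(tp, fp, fn, target_bases) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (target_bases < tp + fp + fn) stop("target_bases smaller than classified variant count")
  tn <- target_bases - tp - fp - fn
  sens <- if (tp + fn == 0) {
    warning("no truth variants: sensitivity undefined")
    NA_real_
  } else tp / (tp + fn)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, target_bases = target_bases,
                 sensitivity = sens,
                 specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / target_bases),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark: TP=%d FP=%d FN=%d TN=%d over %d bases\n",
              x$tp, x$fp, x$fn, x$tn, x$target_bases))
  cat(sprintf("  sensitivity %.4f  specificity %.6f  accuracy %.6f\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Benchmark a call set against a truth set in one step
#'
#' @param calls,truth `call_set`s.
#' @param target_bases Size of the benchmarked target in bases.
#' @param confident_region Optional interval restriction.
#' @return A `benchmark_result` with the per-variant table attached as
#'   `$per_variant`.
#' @export
benchmark_callset <- function(calls, truth, target_bases, confident_region = NULL) {
  pv <- classify_calls(calls, truth, confident_region)
  res <- benchmark_metrics(sum(pv$class == "TP"), sum(pv$class == "FP"),
                           sum(pv$class == "FN"), target_bases)
  res$per_variant <- pv
  res
}

#' Pool benchmark results across samples
#'
#' Counts and target sizes are summed and the metrics recomputed from the
#' pooled counts (pooling, not averaging, so large samples weigh more).
#'
#' @param results Non-empty list of `benchmark_result`s.
#' @return A pooled `benchmark_result`.
#' @export
aggregate_benchmarks <- function(results) {
  if (length(results) == 0) stop("no benchmark results to aggregate")
  benchmark_metrics(
    tp = sum(vapply(results, `[[`, numeric(1), "tp")),
    fp = sum(vapply(results, `[[`, numeric(1), "fp")),
    fn = sum(vapply(results, `[[`, numeric(1), "fn")),
    target_bases = sum(vapply(results, `[[`, numeric(1), "target_bases"))
  )
}

#' Split multi-allelic rows into biallelic records
#'
#' @param variants data.frame whose `alt` may contain comma-separated alleles.
#' @return data.frame with one row per (ref, alt) pair.
#' @export
split_multiallelic <- function(variants) {
  alts <- strsplit(as.character(variants$alt), ",", fixed = TRUE)
  n <- lengths(alts)
  out <- variants[rep(seq_len(nrow(variants)), n), , drop = FALSE]
  out$alt <- unlist(alts)
  rownames(out) <- NULL
  out
}

#' Write benchmark outputs
#'
#' @param result A `benchmark_result` from [benchmark_callset()].
#' @param out_dir Output directory; writes `benchmark.json` and
#'   `per_variant.tsv`.
#' @return Paths, invisibly.
#' @export
write_benchmark <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(out_dir, "benchmark.json")
  jsonlite::write_json(result[c("tp", "fp", "fn", "tn", "target_bases",
                                "sensitivity", "specificity", "accuracy")],
                       f1, auto_unbox = TRUE, digits = NA)
  f2 <- file.path(out_dir, "per_variant.tsv")
  if (!is.null(result$per_variant)) {
    write.table(result$per_variant, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(benchmark = f1, per_variant = f2))
}
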