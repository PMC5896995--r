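# ---- call sets --------------------------------------------------------------
#
# A call_set is a data.frame of variant records plus sample/replicate labels.
# Variant identity throughout the package is (chrom, pos, ref, alt) after
# normalization; genotype never enters identity (replicate comparisons count
# "variants identified", zygosity discordances are reported separately).

.variant_cols <- c("chrom", "pos", "ref", "alt", "quality", "coverage",
                   "allelic_fraction", "genotype")

#' Construct a variant call set
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; optional `quality`, `coverage`, `allelic_fraction`, `genotype`
#'   (het/hom/missing) and any annotation columns (population frequencies,
#'   predictor verdicts).
#' @param sample_id Sample identifier.
#' @param replicate_label Replicate/run/laboratory label.
#' @param normalize Normalize alleles on construction (default TRUE).
#' @return A `call_set` object.
#' @export
call_set <- function(variants, sample_id = "sample", replicate_label = sample_id,
                     normalize = TRUE) {
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants))) stop("variants need chrom, pos, ref, alt columns")
  for (col in c("quality", "coverage", "allelic_fraction")) {
    if (!col %in% names(variants)) variants[[col]] <- NA_real_
  }
  if (!"genotype" %in% names(variants)) variants$genotype <- "missing"
  variants$pos <- as.integer(variants$pos)
  variants$ref <- toupper(as.character(variants$ref))
  variants$alt <- toupper(as.character(variants$alt))
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  if (any(!grepl("^[ACGT]+$", variants$ref)) || any(!grepl("^[ACGT]+$", variants$alt)))
    stop("alleles must be non-empty strings over A/C/G/T")
  if (normalize && nrow(variants) > 0) {
    norm <- t(vapply(seq_len(nrow(variants)), function(i) {
      v <- normalize_variant(variants$pos[i], variants$ref[i], variants$alt[i])
      c(as.character(v$pos), v$ref, v$alt)
    }, character(3)))
    variants$pos <- as.integer(norm[, 1])
    variants$ref <- norm[, 2]
    variants$alt <- norm[, 3]
  }
  key <- variant_key(variants)
  if (anyDuplicated(key)) stop("duplicate variant keys after normalization")
  structure(list(sample_id = sample_id, replicate_label = replicate_label,
                 variants = variants),
            class = "call_set")
}

#' @export
print.call_set <- function(x, ...) {
  cat(sprintf("call_set '%s' (%s): %d variants\n",
              x$sample_id, x$replicate_label, nrow(x$variants)))
  invisible(x)
}

#' Canonical identity keys for variant rows
#' @param variants data.frame with chrom, pos, ref, alt.
#' @return Character vector `chrom:pos:ref>alt`.
#' @export
variant_key <- function(variants) {
  sprintf("%s:%d:%s>%s", variants$chrom, variants$pos, variants$ref, variants$alt)
}

#' Normalize a variant to its minimal trimmed representation
#'
#' Shared leading bases are trimmed first (advancing the position) while both
#' alleles retain at least one base, then shared trailing bases are trimmed
#' under the same guard. Idempotent; purely textual (no reference needed), so
#' identical variants written with different padding collapse to one key.
#'
#' @param pos 1-based position.
#' @param ref,alt Allele strings over A/C/G/T.
#' @return list(pos, ref, alt).
#' @export
normalize_variant <- function(pos, ref, alt) {
  if (ref == alt) stop("not a variant: ref equals alt")
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' Configuration for call filtering and concordance
#'
#' @param quality_min Caller quality a variant must strictly exceed
#'   (default 100).
#' @param region_flank_bp Intronic flank added to exon targets for the
#'   reporting window (default 12).
#' @param af_min Minimum allelic fraction; variants with known AF below this
#'   are removed, missing AF passes (default 0.15).
#' @param medium_indel_bp Inserted-sequence length above which an insertion or
#'   duplication is outside small-variant caller competence (default 35).
#' @return list of class `concord_config`.
#' @export
concord_config <- function(quality_min = 100, region_flank_bp = 12L,
                           af_min = 0.15, medium_indel_bp = 35L) {
  stopifnot(quality_min >= 0, region_flank_bp >= 0, af_min >= 0, medium_indel_bp >= 0)
  structure(list(quality_min = quality_min, region_flank_bp = region_flank_bp,
                 af_min = af_min, medium_indel_bp = medium_indel_bp),
            class = "concord_config")
}

#' Apply the reporting filters to a call set
#'
#' Keeps variants with quality strictly greater than `quality_min`, position
#' inside the exon targets flanked by `region_flank_bp` intronic bases, and
#' (when an allelic fraction is recorded) AF at or above `af_min`. Missing AF
#' passes: the AF rule belongs to callers that know read support, not to
#' tabular re-analysis. Idempotent.
#'
#' @param cs A `call_set`.
#' @param panel A `panel_target`.
#' @param cfg A `concord_config`.
#' @return Filtered `call_set`.
#' @export
filter_calls <- function(cs, panel, cfg = concord_config()) {
  v <- cs$variants
  if (nrow(v) == 0) return(cs)
  window <- flank_intervals(panel$target, cfg$region_flank_bp)
  inside <- points_within(v$chrom, v$pos - 1L, window)
  keep <- v$quality > cfg$quality_min & inside &
    (is.na(v$allelic_fraction) | v$allelic_fraction >= cfg$af_min)
  cs$variants <- v[keep, , drop = FALSE]
  rownames(cs$variants) <- NULL
  cs
}

#' Replicate concordance analysis
#'
#' Filters each call set, takes the union of normalized variant keys, and
#' reports per-variant presence and coverage per replicate together with
#' summary counts.
#'
#' @param callsets List of >= 2 `call_set`s.
#' @param panel A `panel_target` (filtering window).
#' @param cfg A `concord_config`. Pass `NULL` to skip filtering.
#' @return list of class `concordance` with `table` (one row per union
#'   variant: key, present.<label>, coverage.<label>, genotype.<label>,
#'   n_present) and `summary` (per-set counts, union and intersection sizes,
#'   percentages of the union).
#' @export
concordance <- function(callsets, panel = NULL, cfg = concord_config()) {
  if (length(callsets) < 2) stop("concordance requires at least two call sets")
  if (!is.null(cfg)) {
    if (is.null(panel)) stop("a panel is required when filtering is enabled")
    callsets <- lapply(callsets, filter_calls, panel = panel, cfg = cfg)
  }
  labels <- vapply(callsets, `[[`, character(1), "replicate_label")
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  keys <- lapply(callsets, function(cs) variant_key(cs$variants))
  union_keys <- sort(unique(unlist(keys)))
  tab <- data.frame(key = union_keys, stringsAsFactors = FALSE)
  for (i in seq_along(callsets)) {
    m <- match(union_keys, keys[[i]])
    tab[[paste0("present.", labels[i])]] <- !is.na(m)
    tab[[paste0("coverage.", labels[i])]] <- callsets[[i]]$variants$coverage[m]
    tab[[paste0("genotype.", labels[i])]] <- callsets[[i]]$variants$genotype[m]
  }
  pres <- as.matrix(tab[, paste0("present.", labels), drop = FALSE])
  tab$n_present <- rowSums(pres)
  n_union <- length(union_keys)
  per_set <- colSums(pres)
  summary <- list(
    labels = labels,
    per_set = setNames(as.integer(per_set), labels),
    union = n_union,
    intersection = sum(tab$n_present == length(callsets)),
    pct_of_union = setNames(if (n_union > 0) 100 * per_set / n_union else rep(NA_real_, length(labels)),
                            labels)
  )
  structure(list(table = tab, summary = summary), class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  s <- x$summary
  cat(sprintf("concordance over %d call sets: union %d, all-sets intersection %d (%.1f%%)\n",
              length(s$labels), s$union, s$intersection,
              if (s$union > 0) 100 * s$intersection / s$union else NA_real_))
  for (l in s$labels) {
    cat(sprintf("  %s: %d variants (%.1f%% of union)\n", l, s$per_set[[l]], s$pct_of_union[[l]]))
  }
  invisible(x)
}

#' Coverage normalization factor between two replicates
#'
#' Ratio of mean coverages over variants shared by two replicates, used to
#' put replicate coverage tracks on one scale for comparison plots.
#'
#' @param shared_cov_a,shared_cov_b Equal-length coverage vectors over the
#'   shared variants.
#' @param method `"mean"` (ratio of means, default) or `"median"` (median of
#'   per-variant ratios).
#' @return The scalar factor mean(a)/mean(b).
#' @export
coverage_factor <- function(shared_cov_a, shared_cov_b, method = c("mean", "median")) {
  method <- match.arg(method)
  if (length(shared_cov_a) != length(shared_cov_b) || length(shared_cov_a) < 1)
    stop("coverage vectors must have equal positive length")
  if (method == "mean") {
    mb <- mean(shared_cov_b)
    if (mean(shared_cov_a) == 0 || mb == 0) stop("zero mean coverage")
    mean(shared_cov_a) / mb
  } else {
    if (any(shared_cov_b == 0)) stop("zero coverage in denominator")
    median(shared_cov_a / shared_cov_b)
  }
}

#' Prioritize a variant of unknown significance
#'
#' A VUS is prioritized when every available population minor-allele
#' frequency is below `maf_max` (missing frequencies count as rare) and all
#' available in-silico predictor verdicts are concordantly `"deleterious"`.
#' With no predictor verdict available the variant is not prioritized:
#' concordant deleterious predictions cannot be established.
#'
#' @param annotations Named list/vector of annotation values for one variant.
#' @param maf_keys Names of population-frequency annotations.
#' @param predictor_keys Names of predictor-verdict annotations (values
#'   `"deleterious"`/`"benign"`/missing).
#' @param maf_max MAF cutoff (default 0.01).
#' @return TRUE/FALSE.
#' @export
prioritize_vus <- function(annotations, maf_keys, predictor_keys, maf_max = 0.01) {
  mafs <- suppressWarnings(as.numeric(unlist(annotations[maf_keys])))
  mafs <- mafs[!is.na(mafs)]
  if (any(mafs >= maf_max)) return(FALSE)
  verdicts <- as.character(unlist(annotations[predictor_keys]))
  verdicts <- verdicts[!is.na(verdicts) & nzchar(verdicts)]
  length(verdicts) > 0 && all(verdicts == "deleterious")
}

#' Flag insertions beyond small-variant caller competence
#'
#' Insertions or tandem duplications whose inserted sequence strictly exceeds
#' `medium_indel_bp` (default 35, about half a 75 bp read) are poorly
#' represented in gapped alignments and need a split-read tool; this flag
#' marks them.
#'
#' @param ref,alt Normalized allele strings.
#' @param cfg A `concord_config`.
#' @return TRUE iff `nchar(alt) - nchar(ref) > medium_indel_bp`.
#' @export
flag_medium_indel <- function(ref, alt, cfg = concord_config()) {
  (nchar(alt) - nchar(ref)) > cfg$medium_indel_bp
}

# ---- IO ---------------------------------------------------------------------

#' Read a single-sample VCF into a call set
#'
#' Uses the `QUAL` column as caller quality, `DP` (info or format) as
#' coverage, and `AF` info or `AD` format field for allelic fraction when
#' present; genotype from `GT` (het/hom).
#'
#' @param path VCF path (plain text or bgzipped).
#' @param sample_id Sample identifier (default: file basename).
#' @param replicate_label Replicate label (default `sample_id`).
#' @return A `call_set`.
#' @export
read_callset_vcf <- function(path, sample_id = basename(path), replicate_label = sample_id) {
  if (!requireNamespace("vcfR", quietly = TRUE)) stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no variant rows")
  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  gt <- tryCatch(vcfR::extract.gt(v, "GT")[, 1], error = function(e) rep(NA_character_, nrow(fix)))
  genotype <- ifelse(is.na(gt), "missing",
                     ifelse(gt %in% c("1/1", "1|1"), "hom", "het"))
  variants <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    quality = suppressWarnings(as.numeric(fix$QUAL)),
    coverage = dp, allelic_fraction = af, genotype = genotype,
    stringsAsFactors = FALSE
  )
  call_set(variants, sample_id = sample_id, replicate_label = replicate_label)
}

#' Read a replicate-comparison variant table
#'
#' Reads a TSV laid out like replicate comparison spreadsheets: columns
#' `chrom`, `pos`, `ref`, `alt`, then one `cov.<label>` and `q.<label>` pair
#' per replicate; an empty/NA quality cell means the replicate did not call
#' the variant.
#'
#' @param path TSV path with header.
#' @param sample_id Sample identifier applied to all replicates.
#' @return Named list of `call_set`s, one per replicate label.
#' @export
read_replicate_table <- function(path, sample_id = basename(path)) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  labels <- sub("^q\\.", "", grep("^q\\.", names(df), value = TRUE))
  if (length(labels) == 0) stop("no q.<label> quality columns found")
  out <- lapply(labels, function(l) {
    q <- suppressWarnings(as.numeric(df[[paste0("q.", l)]]))
    covcol <- paste0("cov.", l)
    cov <- if (covcol %in% names(df)) suppressWarnings(as.numeric(df[[covcol]])) else NA_real_
    keep <- !is.na(q)
    call_set(data.frame(chrom = df$chrom[keep], pos = df$pos[keep],
                        ref = df$ref[keep], alt = df$alt[keep],
                        quality = q[keep], coverage = cov[keep],
                        stringsAsFactors = FALSE),
             sample_id = sample_id, replicate_label = l)
  })
  setNames(out, labels)
}

#' Write a call set as a minimal VCFv4.2 file
#'
#' @param cs A `call_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_callset_vcf <- function(cs, path) {
  v <- cs$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=panelval",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allelic fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- vapply(seq_len(nrow(v)), function(i) {
    parts <- character()
    if (!is.na(v$coverage[i])) parts <- c(parts, sprintf("DP=%d", as.integer(v$coverage[i])))
    if (!is.na(v$allelic_fraction[i])) parts <- c(parts, sprintf("AF=%.4f", v$allelic_fraction[i]))
    if (length(parts) == 0) "." else paste(parts, collapse = ";")
  }, character(1))
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\t%s",
                  v$chrom, v$pos, v$ref, v$alt,
                  ifelse(is.na(v$quality), ".", format(v$quality, trim = TRUE)), info)
  writeLines(c(header, rows), path)
  invisible(path)
}
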