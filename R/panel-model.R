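#' @importFrom stats median rnorm runif rbinom rnbinom quantile setNames
#' @importFrom utils read.delim write.table head tail
NULL

# ---- interval representation ------------------------------------------------
#
# Genomic intervals are plain data.frames with columns chrom, start, end
# (0-based, half-open) and an optional label column. GRanges (1-based closed)
# is used internally for merge/flank/distance; conversion happens only in the
# two helpers below so the off-by-one boundary lives in one place.

.gi_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

.granges_to_gi <- function(gr, label = NA_character_) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    label = label,
    stringsAsFactors = FALSE
  )
}

#' Construct a set of genomic intervals
#'
#' Intervals use BED conventions: 0-based starts, exclusive ends.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector of 0-based start offsets.
#' @param end Integer vector of exclusive end offsets; must exceed `start`.
#' @param label Optional character labels (e.g. `"BRCA1|ex24"`).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `label`.
#' @export
genomic_intervals <- function(chrom, start, end, label = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end))) stop("non-integer interval coordinates")
  if (any(end <= start)) stop("interval end must exceed start")
  if (any(!nzchar(chrom))) stop("chromosome names must be non-empty")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             label = rep_len(as.character(label), length(chrom)),
             stringsAsFactors = FALSE)
}

#' Merge overlapping or bookended intervals
#'
#' Returns the minimal sorted set of disjoint intervals covering the same
#' bases. Idempotent; the total merged size is invariant under permutation of
#' the input rows.
#'
#' @param intervals Interval data.frame (see [genomic_intervals()]).
#' @return Merged interval data.frame, sorted by (chrom, start). Labels are
#'   dropped (a merged interval may span several labelled inputs).
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) return(genomic_intervals(character(), integer(), integer())[0, ])
  gr <- GenomicRanges::reduce(GenomicRanges::sort(.gi_to_granges(intervals)))
  .granges_to_gi(gr)
}

#' Total number of unique bases covered by a set of intervals
#' @param intervals Interval data.frame.
#' @return Integer count of unique covered bases.
#' @export
intervals_size <- function(intervals) {
  m <- merge_intervals(intervals)
  sum(m$end - m$start)
}

#' Extend intervals symmetrically and merge
#'
#' Each interval is widened by `bp` bases on both sides (clamped at the
#' chromosome origin), then overlapping results are merged. Used with
#' `bp = 12` to form the reporting window of exons plus adjacent intronic
#' bases.
#'
#' @param intervals Interval data.frame.
#' @param bp Non-negative number of bases to add on each side.
#' @return Merged, flanked interval data.frame.
#' @export
flank_intervals <- function(intervals, bp) {
  if (length(bp) != 1 || is.na(bp) || bp < 0) stop("flank bp must be a single value >= 0")
  if (nrow(intervals) == 0) return(merge_intervals(intervals))
  out <- intervals
  out$start <- pmax(0L, out$start - as.integer(bp))
  out$end <- out$end + as.integer(bp)
  merge_intervals(out)
}

#' Distance from a point to the nearest bait interval
#'
#' Returns 0 when the point lies inside a bait and otherwise the number of
#' bases strictly between the point and the closest bait edge. When the
#' chromosome carries no baits the point is unreachable and `NA_integer_`
#' is returned.
#'
#' @param chrom Chromosome of the query point (scalar or vector).
#' @param pos 0-based position(s), parallel to `chrom`.
#' @param baits Interval data.frame of bait/probe positions.
#' @return Integer vector of gap sizes; `NA` for unreachable points.
#' @export
distance_to_nearest <- function(chrom, pos, baits) {
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  out <- rep(NA_integer_, n)
  reachable <- which(chrom %in% baits$chrom)  # other chroms stay NA
  if (nrow(baits) == 0 || length(reachable) == 0) return(out)
  q <- GenomicRanges::GRanges(chrom[reachable],
                              IRanges::IRanges(pos[reachable] + 1L, width = 1L))
  subj <- .gi_to_granges(baits)
  hits <- GenomicRanges::distanceToNearest(q, subj)
  out[reachable[S4Vectors::queryHits(hits)]] <- as.integer(S4Vectors::mcols(hits)$distance)
  out
}

#' Test points for containment in a set of intervals
#'
#' Unlike a zero [distance_to_nearest()], which also holds for points merely
#' adjacent to an interval, this is strict membership.
#'
#' @param chrom Chromosome name(s).
#' @param pos 0-based position(s).
#' @param intervals Interval data.frame.
#' @return Logical vector.
#' @export
points_within <- function(chrom, pos, intervals) {
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  if (nrow(intervals) == 0) return(rep(FALSE, n))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  IRanges::overlapsAny(q, .gi_to_granges(intervals))
}

# ---- panel target -----------------------------------------------------------

#' Build a panel target from gene-labelled intervals
#'
#' @param intervals Interval data.frame whose `label` column, when present,
#'   is either `"GENE"` or `"GENE|exon-tag"`. Unlabelled rows are kept under
#'   the pseudo-gene `"_unassigned"`: they count in panel-wide metrics but are
#'   excluded from per-gene reports.
#' @param baits Optional bait intervals; defaults to the target intervals
#'   themselves (capture probe coordinates are rarely published).
#' @param design_flank_bp Flank built into the capture design (default 10).
#' @param report_flank_bp Flank used for variant reporting windows
#'   (default 12).
#' @return A `panel_target` object: list with `genes` (named list of merged,
#'   sorted exon interval data.frames), `target` (merged union), `baits`, and
#'   the two flank widths.
#' @export
panel_target <- function(intervals, baits = NULL,
                         design_flank_bp = 10L, report_flank_bp = 12L) {
  gene <- ifelse(is.na(intervals$label) | !nzchar(intervals$label),
                 "_unassigned",
                 sub("\\|.*$", "", intervals$label))
  genes <- lapply(split(intervals, gene), merge_intervals)
  target <- merge_intervals(intervals)
  if (is.null(baits)) baits <- target
  structure(list(genes = genes, target = target, baits = merge_intervals(baits),
                 design_flank_bp = as.integer(design_flank_bp),
                 report_flank_bp = as.integer(report_flank_bp)),
            class = "panel_target")
}

#' @export
print.panel_target <- function(x, ...) {
  ngene <- sum(names(x$genes) != "_unassigned")
  cat(sprintf("panel_target: %d genes, %d merged target intervals, %d bases\n",
              ngene, nrow(x$target), panel_size(x)))
  invisible(x)
}

#' Total merged panel target size in bases
#' @param panel A `panel_target`.
#' @return Integer number of unique target bases.
#' @export
panel_size <- function(panel) intervals_size(panel$target)

#' Gene names of a panel (excluding the unassigned pseudo-gene)
#' @param panel A `panel_target`.
#' @export
panel_genes <- function(panel) setdiff(names(panel$genes), "_unassigned")

#' Read a panel target from a BED file
#'
#' Accepts BED3 or BED4 (tab-separated, no header). A 4th column of the form
#' `GENE|exon-tag` (or bare `GENE`) assigns intervals to genes; rows without
#' it become anonymous targets.
#'
#' @param path BED file path.
#' @param ... Passed to [panel_target()] (`baits`, flank widths).
#' @return A `panel_target`.
#' @export
parse_target_bed <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(panel_target(genomic_intervals(character(), integer(), integer())[0, ], ...))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_row <- function(i) {
    f <- fields[[i]]
    if (length(f) < 3) stop(sprintf("BED parse error at line %d: fewer than 3 columns", i))
    start <- suppressWarnings(as.integer(f[2])); end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) stop(sprintf("BED parse error at line %d: non-integer coordinates", i))
    if (end <= start) stop(sprintf("BED parse error at line %d: start >= end", i))
    data.frame(chrom = f[1], start = start, end = end,
               label = if (length(f) >= 4 && nzchar(f[4])) f[4] else NA_character_,
               stringsAsFactors = FALSE)
  }
  intervals <- do.call(rbind, lapply(seq_along(fields), parse_row))
  panel_target(intervals, ...)
}

#' Write a per-gene panel summary table
#'
#' @param panel A `panel_target`.
#' @param path Output TSV path; columns gene, n_exons, target_bp.
#' @return The summary data.frame, invisibly.
#' @export
write_panel_summary <- function(panel, path) {
  genes <- panel_genes(panel)
  df <- data.frame(
    gene = genes,
    n_exons = vapply(genes, function(g) nrow(panel$genes[[g]]), integer(1)),
    target_bp = vapply(genes, function(g) intervals_size(panel$genes[[g]]), integer(1)),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
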