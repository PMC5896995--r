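# ---- depth profiles ---------------------------------------------------------
#
# A depth_profile stores one integer depth per target base, in the fixed order
# defined by the merged panel target (sorted by chrom, start). Positions the
# input never mentions are depth 0: uncovered target bases are real data, not
# missing data.

#' Enumerate every base of the merged panel target
#'
#' @param panel A `panel_target`.
#' @return data.frame with columns `chrom`, `pos` (0-based), one row per
#'   target base, in canonical order.
#' @export
target_positions <- function(panel) {
  tg <- panel$target
  if (nrow(tg) == 0) return(data.frame(chrom = character(), pos = integer()))
  widths <- tg$end - tg$start
  data.frame(
    chrom = rep(tg$chrom, widths),
    pos = unlist(lapply(seq_len(nrow(tg)), function(i) seq.int(tg$start[i], tg$end[i] - 1L)),
                 use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

# Index of profile slots falling inside `intervals` (0-based half-open),
# computed by offset arithmetic against the merged target rows.
.profile_index <- function(panel, intervals) {
  tg <- panel$target
  if (nrow(tg) == 0 || nrow(intervals) == 0) return(integer())
  offsets <- c(0L, cumsum(tg$end - tg$start))
  idx <- vector("list", nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    q <- intervals[i, ]
    hit <- which(tg$chrom == q$chrom & tg$start < q$end & tg$end > q$start)
    idx[[i]] <- unlist(lapply(hit, function(j) {
      lo <- max(tg$start[j], q$start); hi <- min(tg$end[j], q$end)
      offsets[j] + (lo - tg$start[j]) + seq_len(hi - lo)
    }), use.names = FALSE)
  }
  sort(unique(unlist(idx, use.names = FALSE)))
}

#' Construct a depth profile over a panel target
#'
#' @param panel A `panel_target`.
#' @param sample_id Sample identifier.
#' @param depth Integer vector of per-base depths in [target_positions()]
#'   order, or a single value recycled to every target base (default 0).
#' @return A `depth_profile` object.
#' @export
depth_profile <- function(panel, sample_id = "sample", depth = 0L) {
  n <- panel_size(panel)
  depth <- rep_len(as.integer(depth), n)
  if (any(depth < 0, na.rm = TRUE)) stop("depths must be non-negative")
  structure(list(sample_id = sample_id, panel = panel, depth = depth,
                 ignored_offtarget = 0L),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("depth_profile '%s': %d target bases, mean depth %.1f\n",
              x$sample_id, length(x$depth), mean(x$depth)))
  invisible(x)
}

#' Load a samtools-depth style TSV into a depth profile
#'
#' Expects rows `chrom<TAB>pos<TAB>depth` with 1-based positions and no
#' header. Positions inside the panel target are stored (converted to
#' 0-based); target bases absent from the file get depth 0; rows outside the
#' target are ignored and counted in `$ignored_offtarget`.
#'
#' @param path TSV path.
#' @param panel A `panel_target`.
#' @param sample_id Sample identifier (default: file basename).
#' @return A `depth_profile`.
#' @export
load_depth_tsv <- function(path, panel, sample_id = basename(path)) {
  prof <- depth_profile(panel, sample_id = sample_id)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(prof)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3)
  if (length(bad)) stop(sprintf("depth TSV parse error at line %d: fewer than 3 columns", bad[1]))
  chrom <- vapply(parts, `[`, character(1), 1)
  pos1 <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2)))
  dep <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3)))
  if (anyNA(pos1)) stop("depth TSV parse error: non-integer position")
  if (anyNA(dep)) stop("depth TSV parse error: non-integer depth")
  tp <- target_positions(panel)
  slot <- match(paste(chrom, pos1 - 1L), paste(tp$chrom, tp$pos))
  inside <- !is.na(slot)
  prof$depth[slot[inside]] <- dep[inside]
  prof$ignored_offtarget <- sum(!inside)
  prof
}

# ---- uniformity metrics -----------------------------------------------------

#' Fraction of target bases covered at or above a depth threshold
#'
#' "Covered at T" means depth >= T (inclusive boundary).
#'
#' @param profile A `depth_profile`.
#' @param threshold Depth threshold, >= 1.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_at_threshold <- function(profile, threshold) {
  if (threshold < 1) stop("threshold must be >= 1")
  if (length(profile$depth) == 0) stop("empty target: coverage fraction undefined")
  mean(profile$depth >= threshold)
}

#' Classify each gene by the highest threshold its whole target clears
#'
#' A gene is in class T when the minimum depth across its merged target is at
#' least T; genes whose minimum falls below every threshold are
#' `"below_all"`.
#'
#' @param profile A `depth_profile`.
#' @param panel A `panel_target`.
#' @param thresholds Strictly increasing depth thresholds (default 20/50/100).
#' @return Named character vector gene -> class (`"100"`, `"50"`, `"20"` or
#'   `"below_all"`).
#' @export
per_gene_coverage_class <- function(profile, panel, thresholds = c(20L, 50L, 100L)) {
  if (is.unsorted(thresholds, strictly = TRUE)) stop("thresholds must be strictly increasing")
  genes <- panel_genes(panel)
  vapply(genes, function(g) {
    idx <- .profile_index(panel, panel$genes[[g]])
    if (length(idx) == 0) stop(sprintf("gene %s has no target bases", g))
    mind <- min(profile$depth[idx])
    ok <- thresholds[thresholds <= mind]
    if (length(ok) == 0) "below_all" else as.character(max(ok))
  }, character(1))
}

#' Find maximal low-covered regions of the target
#'
#' Scans the target for maximal runs of contiguous bases with depth strictly
#' below `low_cutoff`. Runs never cross a gap in the target. Each region is
#' annotated with the gene owning most of it, its mean depth, and (when a
#' reference is supplied) its GC fraction.
#'
#' @param profile A `depth_profile`.
#' @param panel A `panel_target`.
#' @param low_cutoff Depth below which a base counts as low (default 20).
#' @param sequences Optional named character vector (or list) of full
#'   chromosome sequences used to compute GC content.
#' @return data.frame with columns chrom, start, end, gene, mean_depth,
#'   gc_fraction (NA without sequences).
#' @export
low_covered_regions <- function(profile, panel, low_cutoff = 20L, sequences = NULL) {
  tg <- panel$target
  out <- list()
  offset <- 0L
  for (i in seq_len(nrow(tg))) {
    w <- tg$end[i] - tg$start[i]
    d <- profile$depth[offset + seq_len(w)]
    r <- rle(d < low_cutoff)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      s0 <- tg$start[i] + starts[k] - 1L
      e0 <- tg$start[i] + ends[k]
      out[[length(out) + 1L]] <- data.frame(
        chrom = tg$chrom[i], start = s0, end = e0,
        mean_depth = mean(d[starts[k]:ends[k]]),
        stringsAsFactors = FALSE
      )
    }
    offset <- offset + w
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      gene = character(), mean_depth = numeric(),
                      gc_fraction = numeric()))
  }
  regions <- do.call(rbind, out)
  regions$gene <- vapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    best <- "_unassigned"; best_ov <- 0L
    for (g in panel_genes(panel)) {
      gi <- panel$genes[[g]]
      ov <- sum(pmax(0L, pmin(gi$end, r$end) - pmax(gi$start, r$start)) *
                  (gi$chrom == r$chrom))
      if (ov > best_ov) { best <- g; best_ov <- ov }
    }
    best
  }, character(1))
  regions$gc_fraction <- NA_real_
  if (!is.null(sequences)) {
    for (i in seq_len(nrow(regions))) {
      seqc <- sequences[[regions$chrom[i]]]
      if (!is.null(seqc)) {
        regions$gc_fraction[i] <-
          gc_fraction(substr(as.character(seqc), regions$start[i] + 1L, regions$end[i]))
      }
    }
  }
  regions[, c("chrom", "start", "end", "gene", "mean_depth", "gc_fraction")]
}

#' GC fraction of a nucleotide sequence
#'
#' `N` bases are excluded from the denominator.
#'
#' @param seq Character scalar over A/C/G/T/N (case-insensitive).
#' @return `(G + C) / (A + C + G + T)`.
#' @export
gc_fraction <- function(seq) {
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(toupper(seq)),
                                        letters = c("A", "C", "G", "T"))
  denom <- sum(counts)
  if (denom == 0) stop("gc_fraction undefined: no unambiguous bases")
  unname((counts[["C"]] + counts[["G"]]) / denom)
}

#' Fraction of reads mapping far from any capture bait
#'
#' A read is off-target when the gap between its position and the nearest
#' bait strictly exceeds `offtarget_bp`; reads on chromosomes without baits
#' count as off-target.
#'
#' @param read_positions data.frame with columns `chrom`, `pos` (0-based
#'   leftmost aligned position; a midpoint works equally if preferred).
#' @param baits Bait interval data.frame.
#' @param offtarget_bp Distance cutoff in bases (default 250).
#' @return Fraction in `[0, 1]`.
#' @export
off_target_fraction <- function(read_positions, baits, offtarget_bp = 250L) {
  if (nrow(read_positions) == 0) stop("off-target fraction undefined for empty read list")
  d <- distance_to_nearest(read_positions$chrom, read_positions$pos, baits)
  mean(is.na(d) | d > offtarget_bp)
}

# ---- rendering & reports ----------------------------------------------------

#' Plot per-base coverage along a gene's concatenated exons
#'
#' Depth is drawn along the gene's merged target with vertical marks at exon
#' boundaries; a green bar under the profile marks bases at or above
#' `low_cutoff` and a red bar marks bases below it, in the style of in-house
#' panel-coverage review scripts.
#'
#' @param profile A `depth_profile`.
#' @param panel A `panel_target`.
#' @param gene Gene symbol present in the panel.
#' @param low_cutoff Depth cutoff for the red/green bars (default 20).
#' @param out_path PNG output path.
#' @return `out_path`, invisibly.
#' @export
render_gene_coverage <- function(profile, panel, gene, low_cutoff = 20L, out_path) {
  if (!gene %in% panel_genes(panel)) stop(sprintf("unknown gene: %s", gene))
  exons <- panel$genes[[gene]]
  idx <- .profile_index(panel, exons)
  d <- profile$depth[idx]
  bounds <- cumsum(exons$end - exons$start)
  grDevices::png(out_path, width = 900, height = 380)
  on.exit(grDevices::dev.off(), add = TRUE)
  ymax <- max(d, low_cutoff) * 1.05
  plot(seq_along(d), d, type = "l", col = "grey25",
       xlab = sprintf("%s coding positions (exons concatenated)", gene),
       ylab = "depth", ylim = c(-0.08 * ymax, ymax), yaxs = "i", bty = "l",
       main = sprintf("%s coverage, sample %s", gene, profile$sample_id))
  abline(v = bounds[-length(bounds)] + 0.5, col = "grey70", lty = 3)
  abline(h = low_cutoff, col = "red", lty = 2)
  ok <- d >= low_cutoff
  bar_y <- -0.04 * ymax
  segments(seq_along(d) - 0.5, bar_y, seq_along(d) + 0.5, bar_y,
           col = ifelse(ok, "forestgreen", "red"), lwd = 6, lend = 1)
  invisible(out_path)
}

#' Write the three standard coverage QC reports
#'
#' @param profile A `depth_profile`.
#' @param panel A `panel_target`.
#' @param out_dir Output directory (created if needed).
#' @param thresholds Depth thresholds for the panel summary.
#' @param low_cutoff Cutoff for the low-region report.
#' @param sequences Optional chromosome sequences for GC annotation.
#' @return Named list of the written file paths, invisibly.
#' @export
write_coverage_reports <- function(profile, panel, out_dir,
                                   thresholds = c(20L, 50L, 100L),
                                   low_cutoff = 20L, sequences = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summ <- data.frame(threshold = thresholds,
                     fraction = vapply(thresholds, function(t)
                       fraction_at_threshold(profile, t), numeric(1)))
  f1 <- file.path(out_dir, "panel_summary.tsv")
  write.table(summ, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  cls <- per_gene_coverage_class(profile, panel, thresholds)
  f2 <- file.path(out_dir, "gene_classes.tsv")
  write.table(data.frame(gene = names(cls), class = unname(cls)),
              f2, sep = "\t", quote = FALSE, row.names = FALSE)
  low <- low_covered_regions(profile, panel, low_cutoff, sequences)
  f3 <- file.path(out_dir, "low_regions.tsv")
  write.table(low, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(panel_summary = f1, gene_classes = f2, low_regions = f3))
}
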