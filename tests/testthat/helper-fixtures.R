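# Shared fixtures, built in code.

# two-gene toy panel: GENEA on chr1 (two exons), GENEB on chr2 (one exon)
tiny_panel <- function() {
  panel_target(genomic_intervals(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(100L, 300L, 50L),
    end = c(200L, 360L, 150L),
    label = c("GENEA|ex1", "GENEA|ex2", "GENEB|ex1")
  ))
}

# single-gene panel with one 10-base exon at chr1:[0,10), for hand-sized
# depth examples
ten_base_panel <- function() {
  panel_target(genomic_intervals("chr1", 0L, 10L, "G1|ex1"))
}

write_bed <- function(rows) {
  path <- tempfile(fileext = ".bed")
  writeLines(rows, path)
  path
}

# brute-force oracles -----------------------------------------------------

# merged size by base enumeration
oracle_merged_size <- function(intervals) {
  length(unique(paste(
    rep(intervals$chrom, intervals$end - intervals$start),
    unlist(mapply(function(s, e) seq.int(s, e - 1L), intervals$start,
                  intervals$end, SIMPLIFY = FALSE))
  )))
}

# gap (bases strictly between) from a point to the nearest bait
oracle_distance <- function(chrom, pos, baits) {
  b <- baits[baits$chrom == chrom, , drop = FALSE]
  if (nrow(b) == 0) return(NA_integer_)
  min(vapply(seq_len(nrow(b)), function(i) {
    if (pos >= b$start[i] && pos < b$end[i]) 0L
    else if (pos < b$start[i]) b$start[i] - pos - 1L
    else pos - b$end[i]
  }, integer(1)))
}

# maximal low runs by per-base scan (depth vector over one contiguous block)
oracle_low_runs <- function(depth, cutoff) {
  low <- depth < cutoff
  runs <- list()
  i <- 1
  while (i <= length(low)) {
    if (low[i]) {
      j <- i
      while (j < length(low) && low[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i - 1L, j)  # 0-based [start, end)
      i <- j + 1
    } else i <- i + 1
  }
  runs
}

# random panel over one chromosome with contiguous blocks for oracle tests
random_block_panel <- function(n_blocks, block_bp, gap_bp = 50L) {
  starts <- cumsum(rep(block_bp + gap_bp, n_blocks)) - block_bp
  panel_target(genomic_intervals("chr1", starts, starts + block_bp,
                                 sprintf("G%d|ex1", seq_len(n_blocks))))
}

# call_set from bare position vectors (SNVs A>G on chr1), quality 500
snv_set <- function(pos, label = "rep", quality = 500, coverage = 100) {
  call_set(data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "G",
                      quality = quality, coverage = coverage,
                      stringsAsFactors = FALSE),
           sample_id = "s", replicate_label = label)
}
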