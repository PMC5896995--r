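# Fragmentation-randomness statistic.
#
# Random (ultrasound-like) shearing cuts DNA without sequence preference, so
# the bases observed at fragment ends should match the base composition of the
# region; enzymatic digestion prefers motifs and skews them. Each class k gets
# a relativized frequency r_k = observed fraction / regional composition
# fraction, so r_k = 1 means "ends look like the region". The scalar summary
# is the composition-weighted RMS deviation of the mononucleotide r_k from 1.

.composition <- function(region_seq, width) {
  s <- Biostrings::DNAString(toupper(region_seq))
  counts <- Biostrings::oligonucleotideFrequency(s, width = width)
  counts <- counts[!grepl("N", names(counts))]
  counts / sum(counts)
}

#' Terminal (di)nucleotide composition of fragment ends
#'
#' Each observation is one fragment end: the reference base at the terminal
#' aligned position (mononucleotide class) and the 2-mer spanning that
#' position and its inward neighbour (dinucleotide class: positions (p, p+1)
#' for a start end, (q-1, q) for a stop end). Reference bases are used rather
#' than read bases so sequencing errors do not contaminate the statistic.
#' Observed class fractions are relativized by the regional composition
#' (overlapping 2-mers for dinucleotides).
#'
#' @param ends data.frame with columns `pos` (1-based position within the
#'   region) and `kind` (`"start"` or `"stop"`).
#' @param region_seq Character scalar: the region's reference sequence
#'   (length >= 2).
#' @param region_label Label carried into the profile.
#' @param sample_id Sample identifier for ranking tables.
#' @return A `shear_profile`: list with `mono` and `di` relativized frequency
#'   vectors, `n_ends`, and `uniformity` (weighted RMS deviation of mono
#'   classes from 1; 0 means perfectly composition-like ends).
#' @export
terminal_composition <- function(ends, region_seq, region_label = "region",
                                 sample_id = "sample") {
  region_seq <- toupper(region_seq)
  len <- nchar(region_seq)
  if (len < 2) stop("region sequence must be at least 2 bases")
  if (any(ends$pos < 1 | ends$pos > len)) stop("end positions must lie inside the region")
  kind <- as.character(ends$kind)
  if (!all(kind %in% c("start", "stop"))) stop("end kind must be 'start' or 'stop'")

  bases <- strsplit(region_seq, "", fixed = TRUE)[[1]]
  mono_obs <- table(factor(bases[ends$pos], levels = c("A", "C", "G", "T")))

  # dinucleotide spans the terminal base and its inward neighbour; ends whose
  # neighbour would fall outside the region contribute no di observation
  di_start <- ends$pos[kind == "start" & ends$pos < len]
  di_stop <- ends$pos[kind == "stop" & ends$pos > 1]
  di_str <- c(paste0(bases[di_start], bases[di_start + 1L]),
              paste0(bases[di_stop - 1L], bases[di_stop]))
  di_levels <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  di_obs <- table(factor(di_str, levels = sort(di_levels)))

  relativize <- function(obs, comp) {
    obs_frac <- as.numeric(obs) / max(1, sum(obs))
    names(obs_frac) <- names(obs)
    comp <- comp[names(obs_frac)]
    comp[is.na(comp)] <- 0
    r <- ifelse(comp > 0, obs_frac / comp, ifelse(obs_frac > 0, Inf, NA_real_))
    if (any(is.infinite(r))) {
      warning("observed ends in classes absent from the region composition; reported as Inf and excluded from uniformity")
    }
    setNames(r, names(obs_frac))
  }

  mono_comp <- .composition(region_seq, 1L)
  di_comp <- .composition(region_seq, 2L)
  mono_comp <- setNames(as.numeric(mono_comp[c("A", "C", "G", "T")]), c("A", "C", "G", "T"))
  mono_comp[is.na(mono_comp)] <- 0
  mono_r <- relativize(mono_obs, mono_comp)
  di_r <- relativize(di_obs, setNames(as.numeric(di_comp), names(di_comp)))

  usable <- mono_comp > 0 & is.finite(mono_r)
  uniformity <- sqrt(sum(mono_comp[usable] * (mono_r[usable] - 1)^2))

  structure(list(region_label = region_label, sample_id = sample_id,
                 mono = mono_r, di = di_r, n_ends = nrow(ends),
                 uniformity = uniformity),
            class = "shear_profile")
}

#' @export
print.shear_profile <- function(x, ...) {
  cat(sprintf("shear_profile '%s' over %s: %d ends, uniformity %.4f\n",
              x$sample_id, x$region_label, x$n_ends, x$uniformity))
  print(round(x$mono, 3))
  invisible(x)
}

#' Compare fragmentation profiles over one region
#'
#' @param profiles List of `shear_profile`s computed over the same region.
#' @return data.frame with one row per profile (sample, n_ends, uniformity and
#'   the per-base relativized frequencies), ranked by uniformity ascending
#'   (most composition-like shearing first); ties broken by sample id.
#' @export
compare_shear <- function(profiles) {
  if (length(profiles) < 2) stop("at least two shear profiles are required")
  labels <- vapply(profiles, `[[`, character(1), "region_label")
  if (length(unique(labels)) != 1) stop("shear profiles cover different regions")
  df <- do.call(rbind, lapply(profiles, function(p) {
    cbind(data.frame(sample_id = p$sample_id, n_ends = p$n_ends,
                     uniformity = p$uniformity, stringsAsFactors = FALSE),
          as.data.frame(as.list(p$mono)))
  }))
  df[order(df$uniformity, df$sample_id), , drop = FALSE]
}

#' Read fragment end positions from a two-column TSV
#'
#' @param path TSV with columns `pos` (1-based within the region) and `kind`
#'   (`start`/`stop`); header optional.
#' @return data.frame with columns `pos`, `kind`.
#' @export
read_ends_tsv <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("pos", first, ignore.case = TRUE)
  df <- read.delim(path, header = has_header,
                   col.names = if (has_header) NULL else c("pos", "kind"))
  names(df) <- c("pos", "kind")
  df$pos <- as.integer(df$pos)
  df
}
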