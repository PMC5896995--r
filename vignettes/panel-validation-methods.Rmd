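---
title: "Validation analytics for targeted gene panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validation analytics for targeted gene panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelval)
```

# Scope

`panelval` implements the analytics a diagnostic laboratory runs when it
validates a hybridization-capture gene panel for germline testing: coverage
uniformity, fragmentation randomness, replicate concordance, truth-set
benchmarking, and cohort read-depth copy-number scoring. Everything operates
on plain-text inputs (BED targets, samtools-depth TSVs, VCFs, bin-score
tables) or on cohorts produced by the built-in simulator, so the entire
pipeline is testable without sequencing data.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the simulator does and does not
emulate.

# Coordinates and interval arithmetic

All intervals are BED-style: 0-based starts, exclusive ends. One-based
inputs (VCF positions, depth TSVs) are converted at the parsing boundary and
nowhere else, which keeps off-by-one errors out of the analysis code.
Merging, flanking and nearest-distance queries are delegated to
`IRanges`/`GenomicRanges`; the test suite checks them against brute-force
base enumeration.

Two distance notions coexist and are deliberately distinct:

* `distance_to_nearest()` returns the number of bases *strictly between* a
  point and the closest bait (0 both inside and immediately adjacent). This
  is the convention under which "off-target" means a gap strictly exceeding
  250 bases.
* `points_within()` is strict containment, used by the variant-filtering
  window and the confident-region restriction, where adjacency must not
  count.

A panel's exons can be flanked by a configurable number of intronic bases:
10 bp is the capture-design convention, 12 bp the variant-reporting window.
Unlabelled BED rows are kept under a `_unassigned` pseudo-gene: they count
in panel-wide fractions but are excluded from per-gene reports, since a
per-gene statement about an interval with no gene is meaningless.

# Coverage QC

Coverage metrics are per-base over the merged target. "Covered at T" means
depth ≥ T; "low" means depth strictly below the cutoff (default 20, the
depth generally regarded as the minimum for reliable heterozygote
detection). The two conventions are complementary by construction, and the
suite asserts the identity

    (low-region bases) / target + fraction_at_threshold(cutoff) = 1

exactly. Target bases absent from a depth file are depth 0, not missing:
an uncovered exon is a finding, and it surfaces as a maximal low region.
A per-region variant of the threshold fractions (counting whole regions
instead of bases) would be possible; the per-base definition was chosen
because it is insensitive to how targets are split into rows.

Per-gene classes are set by the *minimum* depth across the gene's merged
target: a single dropped base demotes the gene, which matches how a
reviewing analyst treats "fully covered". GC content of low regions is
computed on the reference sequence of the region exactly as delimited,
without padding, with `N` excluded from the denominator.

`render_gene_coverage()` draws depth along concatenated exons with a
green/red bar at the cutoff, the style used for per-gene coverage review
plots.

# Fragmentation randomness

Random (acoustic) shearing cuts DNA with little sequence preference;
enzymatic fragmentation prefers motifs. The statistic compares the bases
observed at fragment ends with the base composition of the region: for each
class *k* (4 mononucleotides, 16 dinucleotides),

    r_k = observed fraction of ends in class k / composition fraction of k,

so r_k = 1 means ends look like the region. The dinucleotide at a start end
spans the terminal base and its inward neighbour (p, p+1); at a stop end,
(q−1, q). Reference bases are counted rather than read bases, so sequencing
errors cannot masquerade as cut-site preference. Both ends of a fully
mapped read contribute one observation each (a fragment has a breakpoint at
each end); a 5′-only mode would halve the data without changing the
expectation. Strand collapsing is off by default.

The scalar summary is the composition-weighted RMS deviation of the
mononucleotide classes from 1:

    uniformity = sqrt( Σ_k f_k (r_k − 1)² ),   f_k = composition fraction.

It is 0 iff all observed classes sit at 1, invariant to the number of ends,
and in simulations its expectation grows monotonically with the cut-bias
mixture weight. Classes absent from the region but observed in the data are
reported as infinite deviations and excluded from the summary with a
warning. This scalar is this package's own definition — fragmentation
randomness is usually shown as curves — and it exists so that protocols can
be ranked and regression-tested.

# Variant normalization, filtering and concordance

Variant identity everywhere is `(chrom, pos, ref, alt)` after trimming:
shared leading bases first (advancing the position, while both alleles keep
at least one base), then shared trailing bases. The operation is idempotent
and purely textual; the suite verifies that the trimmed representation
edits a haplotype identically to the raw one. Genotype never enters
identity — replicate comparisons count variants identified, and zygosity
discordances are reported in their own column.

The reporting filter keeps variants with caller quality **strictly** above
100 inside the exon targets flanked by 12 intronic bases, and drops
variants with a recorded allelic fraction below 15%. A missing allelic
fraction passes: the AF rule belongs to pipelines that know read support,
and applying it to tabular re-analyses would silently delete data.
Insertions whose inserted sequence exceeds 35 bp (about half a 75 bp read)
are flagged as beyond small-variant caller competence; the flag marks them
for split-read follow-up, it does not remove them.

Concordance over k call sets reports, per variant of the union, presence
and coverage per set, plus per-set totals, union, intersection and percent
of union. With independent per-replicate dropout d the expected
all-replicates fraction is (1−d)^k, and the simulator-based tests hold the
implementation to that closed form.

The coverage factor between two replicates is the ratio of mean coverages
over the variants they share (a median-of-ratios alternative is available);
it is a display normalization, not a calling parameter.

VUS prioritization is a conjunction: every available population frequency
below 1% (missing frequencies count as rare — absence from a population
database is evidence of rarity) *and* at least one in-silico verdict, all
concordantly deleterious. With no verdict available the variant is not
prioritized, because concordance of predictions cannot be established from
nothing.

# Truth-set benchmarking

Calls are matched to truth allele-exactly on normalized keys within an
optional confident region. True negatives are counted at base level:
`tn = target_bases − tp − fp − fn`. Over a multi-hundred-kilobase target
this is what makes specificity meaningful at all; variant-level specificity
over a truth set of a few hundred sites would be a different (and much
weaker) statement. Multi-allelic truth rows are split into biallelic
records before matching. Aggregation across reference standards sums counts
and recomputes metrics from the pooled counts, so a sample with more
variants weighs more, as it should.

Zygosity disagreement on a matched site is reported but not penalized:
allele detection and genotype assignment are different failure modes, and
conflating them hides both.

# Cohort CNV scoring

Bin scores follow the standard read-depth recipe, reimplemented here so its
constants are explicit:

1. per sample s: `x_{s,b} = (d_{s,b} + 0.5) / median_b(d_{s,·})` — the
   pseudocount keeps homozygous-deletion bins finite, the within-sample
   median removes library size;
2. per bin b: reference `ref_b = median_s x_{s,b}` — the cohort median is
   robust to a few true CNV carriers;
3. `score_{s,b} = log2(x_{s,b} / ref_b)`.

A diploid bin scores ≈ 0, a heterozygous deletion ≈ −1, three copies
≈ +0.585. Because the within-sample median anchors each sample, whole-sample
depth rescaling (library size) leaves threshold crossings unchanged — the
suite verifies this by scaling a sample's depth row and asserting identical
calls. This anchoring assumes the diploid autosomal target dominates the
panel; a panel that were mostly X-chromosomal would contaminate the median
in male samples.

Group median normalization then subtracts, per bin, the median score of the
sample's group (laboratory/protocol batch), removing batch-level structure.
Groups must have at least 3 samples (a median of fewer is the sample
itself); even-sized groups use the mean of the two central values, R's
`median()` convention.

Calling thresholds are strict: deletion when the normalized score is
< −0.6, duplication when > 0.45. Two duplication cutoffs are in practical
circulation for this kind of score (0.45 and 0.5); 0.45 is the default
here and 0.5 is available via `cnv_config(dup_threshold = 0.5)` rather
than picking one silently. A sample is *suspected*
in a gene as soon as one unmasked bin crosses a threshold; a run of ≥ 2
consecutive unmasked bins upgrades confidence to `consecutive_run` but is
not required for suspicion (requiring it would miss single-exon events and
would not reproduce realistic suspect rates).

Non-informative bins are masked before calling, for three reasons:

* `x_in_males` — X-chromosome bins in cohorts containing males read as
  deletions in every male; default is to mask them. The sex-aware
  alternative doubles male X depth before scoring instead, turning male X
  bins back into diploid-like signal.
* `low_reference_depth` — cohort median depth below 20: ratios on a few
  reads are noise.
* `excess_calls` — bins whose deletion+duplication count strictly exceeds
  4% of some sample group. A real CNV is rare; a bin that calls 5% of a
  cohort is an artifact (pseudogene cross-mapping, capture instability),
  and masking it is what keeps the suspect rate interpretable.

Masked bins are removed before run-finding; remaining bins of a gene are
treated as consecutive, so a single masked artifact bin does not split an
otherwise contiguous event.

# The simulator

The simulator produces data with the statistical structure the analyses
assume — it is a test harness, not a sequencing emulator.

* **Depth.** Per-bin totals are negative-binomial with mean
  `λ_s · g_b · width_b`, divided by width. `λ_s` is lognormal around the
  100× target (SD 0.1, mean-corrected); `g_b` is a quadratic function of
  bin GC renormalized to mean 1 (amplitude 0.3 by default; raised in tests
  that need GC-starved regions). The per-bin dispersion default (1/150)
  puts the bin log2-ratio SD at ≈ 0.12, the regime in which −0.6/0.45
  thresholds cleanly separate 1-, 2- and 3-copy states. A single
  negative-binomial draw at a mean of 100 cannot get below the Poisson
  log2-SD floor of ≈ 0.14, which is why bins are modelled as width-summed
  counts. Per-base profiles use a larger dispersion (0.05) to mimic the
  raggedness of real per-base tracks.
* **Cohorts and spike-ins.** Default 30 samples per run (a pooled,
  barcoded enrichment batch); CNVs are planted by multiplying affected
  depths by copies/2, preserving the sampled noise.
* **Replicates.** A master variant list inside the target; each replicate
  drops variants independently (default 1%) and can draw a configurable
  fraction of qualities at or below 100, so the quality filter has
  something to do.
* **Truth/call pairs.** Calls are truth minus binomial false-negative draws
  plus false positives at unused target positions; optionally some calls
  carry allelic fractions below 15% to exercise the AF filter.
* **Cut sites.** A mixture `(1−β)·uniform + β·motif` with cuts landing on
  occurrences of a fixed dinucleotide. β = 0 models acoustic shearing;
  β ≈ 0.5 produces the strong terminal-base skew characteristic of
  enzymatic digestion.

Every generator takes a seed, is bit-reproducible under it, and restores
the caller's RNG state.

What the simulator does **not** emulate: read-level errors and qualities,
insert-size distributions, alignment artifacts, pseudogene cross-mapping,
PCR duplicates, or real enzyme motif spectra. Consequently, passing tests
demonstrate that the *analytics* are correct under the stated statistical
assumptions — not that any particular wet-lab protocol meets them. The
headline coverage percentages of a real validation depend on the realized
depth distribution of the instrument and cannot be reproduced from
simulation; the suite therefore treats them as sanity bands (e.g. ≥ 99% of
target bases at 20× for a 100× cohort with mild noise) rather than targets.

# Problem sizes used in tests

The shipped suite runs on desk-scale instances chosen to keep the
statistics stable: panels of 2–60 genes (up to ≈ 80 kb), cohorts of up to
241 samples by 80 bins, 10⁵ fragment ends for shear statistics, 10⁴
variants for benchmarking recovery, and 40–50 seed replicates for
Monte-Carlo means. These sizes make every documented expectation
measurable at the tolerances asserted; larger instances change runtime, not
conclusions.

# Known limitations

* Variant matching is exact after trimming; complex/adjacent indel
  representations that only haplotype-aware matching would reconcile are
  counted as discordant.
* The CNV scorer does not segment: it thresholds bins and reports runs.
  Breakpoints are resolved only to bin granularity.
* Masking is cohort-dependent: a bin informative in one batch may be
  masked in another, which is intended but means calls are not comparable
  across differently composed cohorts.
* `suspected_samples()` is deliberately sensitive (one bin suffices);
  its output is a review list, not a diagnosis.
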