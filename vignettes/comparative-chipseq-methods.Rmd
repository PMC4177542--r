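---
title: "Methods: comparative ChIP-seq analysis of two bHLH factors"
author: "eboxchip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative ChIP-seq analysis of two bHLH factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eboxchip)
```

# The problem

Basic helix-loop-helix (bHLH) transcription factors such as MyoD and MSC
(musculin) bind the E-box hexamer CANNTG as dimers.  Two factors can share
the same core E-box preference — typically a GC or GG central
dinucleotide — and still occupy partly different genomic sites because
they read the *flanking* bases differently: MyoD-class dimers prefer G or
A at the two positions before the E-box, while MSC-class dimers tolerate
more flank variation but are enriched for C immediately before and G
immediately after the core, the 8-mer CCAGCTGG.  `eboxchip` implements
the full comparative analysis that quantifies this: peak calling for two
ChIP-seq samples plus a no-antibody control, rank-based peak-overlap
statistics, classification of peaks into factor-specific and shared sets,
discriminative motif discovery between those sets, flanking-nucleotide
profiling, genomic-location annotation, and association of the peak
classes with open-chromatin signals (histone H4 acetylation and DNase
hypersensitivity).

Because the analysis is validated end-to-end on synthetic data, the
package also contains a first-class generator that plants all of this
structure into a toy genome.

# Peak calling

## Model

Tags (aligned reads) are deduplicated to at most one per (chromosome,
start, strand) to suppress PCR amplification artifacts, then extended in
their sequencing orientation to the expected fragment length $L = 200$
bases.  The genome is tiled into non-overlapping windows of $w = 200$ bp
and each window is scored by the number of extended tags overlapping it.
Background windows are modelled as negative binomial,
$X \sim \mathrm{NB}(\mu, r)$ with $\mathrm{Var}(X) = \mu + \mu^2/r$, and
each window receives the upper-tail probability $P(X \ge k)$.  Windows at
$P \le$ the cutoff are merged when separated by at most one window's gap,
each merged region is trimmed to its covered extent, and the peak reports
the minimum window $P$, the leftmost coverage-maximum as summit, the
maximum coverage as height, and its deduplicated tag count.  Matching the
window width to the extension length means one binding event saturates
roughly one to two windows.

Raw P-value cutoffs ($10^{-5}$, $10^{-7}$, $10^{-10}$) are reported
without multiple-testing correction; peak lists at several cutoffs are
the object of interest, not a single FDR-controlled set.  Peaks sharing
at least one base with a control-sample peak at $P \le 10^{-5}$ are
removed.

## The background fit

The NB parameters are estimated by the method of moments
($\hat\mu = \bar x$, $\hat r = \hat\mu^2/(s^2 - \hat\mu)$).  A naive fit
is unusable whenever a noticeable fraction of windows contains signal: on
the default synthetic conditions roughly one window in eight overlaps a
planted site, and a fixed upper-quantile trim (for example discarding the
top 1%) leaves the dispersion wildly inflated, to the point where no
window is ever significant.  `fit_background()` therefore re-trims
iteratively: the cap starts near the count median ($2\,\mathrm{median} +
5$), the NB is fitted to windows at or below the cap, the cap moves to
the fitted upper $10^{-4}$ quantile (never above the `trim_quantile`
empirical quantile of the raw counts), and the procedure repeats until
the cap stabilises.  Starting low keeps heavy contamination out of the
initial fit; on clean background the cap expands and effectively all
windows are retained, so the estimates stay close to the plain
method-of-moments values.  `trim_quantile = 1` disables the guard
entirely.  When the retained counts are underdispersed ($s^2 \le \bar x$)
the NB degenerates and the fit falls back to Poisson, which keeps the
tail probabilities valid (and slightly conservative).

Tail probabilities are clamped below at the smallest positive double so
that the peak invariant $0 < P \le 1$ survives underflow at extreme
planted-site counts.

# Comparing two peak lists

Peaks are ranked by $P$ value with ties broken by genomic order, and the
cumulative rank-bin overlap matrix reports, for bins of 3,000 ranks up to
30,000, the fraction of the top $x$ peaks of one sample overlapping any
of the top $y \ge x$ peaks of the other.  Overlap means at least one
shared base.  When a list is shorter than a nominal bin the bin truncates
at the list length and the denominator is $\min(x, \text{length})$.
Overlap is many-to-one, so both directions are computed and reported.

Classification uses the dual-cutoff rule: a peak is *specific* when it is
present at $P \le 10^{-10}$ and no overlapping partner-factor peak
reaches $P \le 10^{-4}$; a pair of overlapping peaks both at $P \le
10^{-10}$ is *shared*; everything else — including the genuinely
ambiguous case of a partner present at $10^{-4}$ but not at $10^{-10}$ —
is *unclassified*.  "Absent" is judged at the peak level against the
partner's loosely-called peak list, which is why the pipeline calls its
working lists at $10^{-4}$ and only then counts survivors at tighter
cutoffs.

# Motif analysis

## E-box scanning and flank profiles

`scan_eboxes()` reports forward-strand CANNTG matches; the pattern is its
own reverse complement, so a single forward scan covers both strands and
palindromic frames are reported once.  Ambiguous bases (`N`) in the
subject never match.  For flank profiling each peak contributes exactly
one E-box — the one nearest its summit within ±50 bp — so long peaks
cannot dominate the counts.  Because the core frame is strand-ambiguous,
profiles are built in two passes: an all-forward tally, then
re-orientation of every match toward the frame whose flanks score higher
under that first-pass profile, then a second tally.  Ties stay forward.

## Discriminative discovery

The discriminative score of a consensus $c$ is the pseudo-counted log
odds ratio of sequence-hit fractions,
$$ S(c) = \log\frac{(h_{fg}+\tfrac12)/(n_{fg}-h_{fg}+\tfrac12)}
                   {(h_{bg}+\tfrac12)/(n_{bg}-h_{bg}+\tfrac12)}, $$
where $h$ counts sequences with at least one match on either strand.  A
Wald standard error for $S$ follows from the 2×2 table, and a motif is
reported only when $S$ exceeds twice that standard error.

Seeds are exhaustive k-mers (k = 6..10, strand-collapsed), but ranked by
the z-statistic $S/\mathrm{SE}(S)$ rather than by $S$ itself: the raw
score rewards rare words with an empty background cell out of all
proportion to the evidence (a word hitting 18 foreground sequences and no
background sequence outscores one hitting 120 versus 9).  Greedy
refinement then tries, at each step, replacing one position with an IUPAC
superset code or extending by one position on either side, and accepts
the change that most improves $S$ *provided the z-statistic also
improves*.  The two objectives fail in opposite directions when used
alone — the raw score climbs into over-specific zero-background words,
the z-statistic relaxes into near-vacuous degenerate codes — and
requiring joint improvement pins the climb to changes supported by both
effect size and evidence.  Reported motifs are masked out of the
foreground (with a character that cannot match any code) and the search
repeats up to `max_motifs`.

In the pipeline the foreground is the B-specific peak set and the
background is the union of shared and A-specific peaks, sequences taken
±100 bp around summits; this is the contrast that isolates what
distinguishes the B factor's private sites from sites it shares.

# Chromatin context

The per-peak acetylation statistic defaults to the mean track value over
the peak interval (maximum available by flag), displayed and tested on
the square-root scale.  Between-class location shifts are tested with the
two-sided Mann–Whitney U test: enrichment values are heavily skewed, a
rank test needs no distributional assumption, and the square-root
transform (which leaves ranks unchanged) exists only for interpretability
of the reported medians.  TSS distance is measured from the peak summit
to the nearest TSS, unsigned, and stratified into half-open bins
([0, 2 kb), [2 kb, 10 kb), [10 kb, 100 kb), [100 kb, ∞) by default).

DNase hypersensitivity is summarised per peak as the maximum HSS score
over the interval.  The overlap fraction is the fraction of peaks with a
nonzero score — equivalently $1 - \mathrm{CDF}(0)$ of the per-peak score
distribution — and therefore depends only on the zero/nonzero pattern of
the track, not its scale.  The full empirical CDF is also reported.

# Genomic-location annotation

A peak receives every category whose region it overlaps by at least one
base: promoter (TSS ± 2 kb), proximal promoter (TSS ± 10 kb), 3′ (TES ±
2 kb), exon and intron (block overlap), and strand-aware upstream /
downstream flanks (100 kb beyond the gene span).  Labels are *not*
exclusive — a peak in a first exon near the TSS is simultaneously
promoter, proximal promoter and exon, so category fractions may sum well
above 1 — with the single exception of intergenic, which is assigned
exactly when nothing else is.  The distance parameters are printed into
every output header so tables are self-describing.

Note the scale caveat: the up/downstream default of 100 kb is a
real-genome convention.  On the 1 Mb toy genome with 40 genes the flanks
tile everything and the intergenic fraction is structurally zero; tests
that exercise intergenic recovery use a sparse gene layout and
scaled-down flanks instead.

# The synthetic-data generator

The generator's defaults are the package's standard study conditions:

| parameter | default | meaning |
|---|---|---|
| genome | 1 Mb, 2 chromosomes, GC 0.41 | i.i.d. bases at human-like GC |
| sites | 100 A-specific, 100 B-specific, 100 shared | planted 10-mers (E-box ± 2 flanks) |
| occupancy | 10, at 20 tags per unit | ≈ 200 site tags ~ Poisson |
| background | NB(μ = 5, r = 2) per 200 bp window | tag count model |
| tags | 36 bp, extension L = 200 | platform-era read length |
| AcH4 | class amplitudes (A 2, B 2, shared 8), ×4 within 2 kb of a TSS, log-normal noise (sd 0.5) | triangular bumps, half-width 300 bp |
| HSS | fraction 0.7 of sites nonzero | constant score over site ± 50 bp |

A-specific and shared sites draw their E-box from the tolerant G/A-flank
model; B-specific sites draw from the C(−1)/G(+1) model with a
GC-dominant core, so the B-specific class carries the discriminative
8-mer signal against the shared background, mirroring the contrast the
motif stage tests.  Site tags are placed so that the L-extended fragment
always covers the whole planted site (uniform offset within the feasible
range per strand), which concentrates coverage summits at site centers.
The control sample has zero occupancy everywhere and is pure background.

Site centers sit on a jittered 3 kb grid.  The hard constraint is only
that sites be at least $2L$ apart, but at densities near that bound the
fragment pileups of neighbouring sites merge into single peaks and a
"missed" site is an artifact of crowding rather than of the caller; the
3 kb spacing keeps planted peaks resolvable while still being far denser
than real binding-site density per megabase.

One master seed fans out deterministically to per-stage child seeds
(`derive_seed()`), so any stage can be regenerated alone and the whole
simulation — and every downstream pipeline output file — is byte-for-byte
reproducible from the configuration.

What the generator does **not** emulate: sequencing errors, mappability
and repeat structure, GC bias, fragment-length variability (extension is
exactly L), duplicate-rate structure, diploidy, and co-factor or
nucleosome effects on occupancy.  Passing tests therefore demonstrate
that the implementation recovers planted structure under its own model
assumptions — calibration of the NB tail, recovery of sites, classes,
flank preferences, and context contrasts — not that those assumptions
describe any particular real dataset.

# Numerical and interface choices

* In memory the package uses the Bioconductor containers — `GRanges`
  (1-based, closed) for tags, peaks, sites and genes; `DNAStringSet` for
  genomes; `RleList` for signal tracks.  All emitted and consumed files
  (BED, bedGraph) are 0-based half-open; conversion happens only at the
  parse/serialize boundary, in `R/io.R`.
* Peak files are BED6+ with a −log10 P score column plus exact-precision
  columns (summit offset, height, tag count, P value printed with 17
  significant digits) so write → read is lossless.
* Ranking ties on identical P values are broken by genomic order;
  coverage-maximum ties by the leftmost base.  Both rules exist for
  reproducibility, not statistics.
* Degenerate inputs are first-class: empty tag files warn and return
  empty sets, empty peak lists propagate, all-zero backgrounds error,
  constant window counts trip the Poisson fallback.
* Test and validation problem sizes (a 1 Mb default genome, a 2 Mb
  background-only calibration genome, 10^5 windows for moment-fit
  recovery, 200-sequence motif sets, a 300 kb determinism run) were
  chosen so the whole suite exercises every stage at well-powered sizes
  while remaining quick on a laptop.

# Limitations

The caller has no local (sliding) background, no input-normalised
fold-enrichment score and no broad-peak mode; the motif stage matches
IUPAC consensus strings rather than scored position-weight matrices and
does not compare against motif databases; annotation is gene-span based
without transcript isoforms.  The between-class AcH4 statistic and test
are configuration choices (mean + Mann–Whitney) rather than attempts to
reproduce any particular published statistic, and the HSS analysis
reduces the track to its zero/nonzero pattern plus the per-peak maximum.
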