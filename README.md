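# eboxchip

Comparative ChIP-seq analysis of two basic helix-loop-helix (bHLH)
transcription factors that bind the same E-box core (CANNTG) but read its
flanking bases differently — the MyoD/MSC situation, where one factor
prefers G/A at the −1/−2 positions while the other is flank-tolerant but
enriched for the 8-mer CCAGCTGG (C at −1, G at +1).

The package is for computational biologists who have aligned ChIP-seq
tags for two factors plus a no-antibody control and want the complete
comparative analysis as reusable, tested R functions:

* **Peak calling** — deduplication, directional extension of each tag to
  L = 200 bases, 200 bp window counts, a negative-binomial background
  `X ~ NB(μ, r)` fitted by an iteratively re-trimmed method of moments,
  upper-tail window P values `P(X ≥ k)`, merging into peaks with summit,
  height and tag count, and control-peak subtraction at P ≤ 1e−5.
* **Peak comparison** — the cumulative rank-bin overlap matrix (fraction
  of the top *x* peaks of one factor overlapping the top *y ≥ x* of the
  other, bins of 3,000 up to 30,000) and the dual-cutoff classifier:
  *specific* = present at P ≤ 1e−10 with no partner peak at P ≤ 1e−4;
  *shared* = both present at P ≤ 1e−10.
* **Motif analysis** — E-box scanning with central-dinucleotide and
  flanking-position profiles, and discriminative de novo discovery of
  IUPAC consensus motifs scored by the log odds ratio of sequence-hit
  fractions (with fg.frac, bg.frac and enrichment ratio reported).
* **Chromatin context** — per-peak acetylated-H4 statistics on the
  square-root scale, TSS-distance stratification, Mann–Whitney
  between-class tests, and DNase-hypersensitivity overlap fractions and
  CDFs (overlap = 1 − fraction of peaks at HSS score 0).
* **Annotation** — multi-label genomic-location fractions (promoter,
  proximal promoter, 3′, exon, intron, upstream, downstream, intergenic).
* **Synthetic data** — a deterministic generator that plants all of this
  structure (factor-specific E-box flank models, NB tag background,
  gene models, AcH4/HSS tracks) into a toy genome, so the entire pipeline
  is testable without any external download.

Everything runs from one configuration through `run_pipeline()`, which
writes every intermediate file, a summary report and a checksum manifest;
reruns with the same seed are byte-identical.

## Worked example

Scan a gel-shift probe for its E-box:

```r
library(eboxchip)
scan_eboxes(emsa_probes()["msc_specific"])
#>   position   core central flank_m2 flank_m1 flank_p1 flank_p2 orientation
#> 1        8 CAGCTG      GC        A        C        G        A           +
```

One E-box at 0-based position 8 with a GC central dinucleotide; reading
the −1 and +1 flanks around the core gives CCAGCTGG, the flank-preferred
8-mer.

Run the full synthetic experiment (1 Mb genome, 300 planted sites in
three classes, occupancy 10, NB(5, 2) background):

```r
cfg <- pipeline_config(simulate = sim_config(seed = 5), max_motifs = 2)
res <- run_pipeline(cfg, "run_seed5")
cat(readLines("run_seed5/report.txt"), sep = "\n")
#> comparative ChIP-seq pipeline report
#>
#> peaks A (post-control): 200; peaks B: 200; control peaks at 1e-05: 0
#> peak counts per cutoff [A]: 1e-05=200, 1e-07=200, 1e-10=200
#> peak counts per cutoff [B]: 1e-05=200, 1e-07=200, 1e-10=200
#> class counts: A_specific=100, B_specific=100, shared=100, unclassified=0
#> top motif: CCMGCTS (fg.frac 0.800, bg.frac 0.170, ratio 18.95)
#> AcH4 shared vs A_specific: P = 2.74e-26
#> AcH4 shared vs B_specific: P = 6.2e-25
#> AcH4 A_specific vs B_specific: P = 0.77
#> HSS overlap fractions: A_specific=0.670, B_specific=0.680, shared=0.710
#> truth recovery recall: A=1.000, B=1.000, shared=1.000
```

Reading the report: each factor binds 200 of the 300 planted sites (its
100 specific plus the 100 shared), every planted site survives all three
P-value cutoffs, and the dual-cutoff classifier recovers all three
planted classes exactly.  Discriminative search of B-specific against
shared ∪ A-specific peaks recovers a GC-core E-box consensus with C
before and S(=C/G) after the core at 80% of foreground peaks.  The
planted 4× acetylation contrast of shared over specific sites is detected
at P ≈ 1e−26 in both comparisons (and, as planted, there is no A vs B
difference), and the HSS overlap fractions recover the planted 0.7.

The output directory also contains the peak BEDs, both overlap matrices,
the class BED, the E-box position profile, per-peak context records and
the annotation table.

## Layout

```
R/              io, synthetic data, peak calling, comparison, motifs,
                context, annotation, pipeline
tests/testthat/ unit + property tests per module, end-to-end acceptance
scripts/        acceptance.R
vignettes/      methods vignette (model, parameters, design choices)
inst/scripts/   thin command-line wrapper over run_pipeline()
```
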