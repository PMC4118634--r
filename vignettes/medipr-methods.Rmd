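---
title: "Methods: comparative MeDIP-Seq methylome analysis of parent-hybrid panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative MeDIP-Seq methylome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipr)
```

## The measurement and its statistics

MeDIP-Seq enriches methylated DNA fragments with a 5-methylcytosine
antibody and sequences them; read density is therefore a *regional*
proxy for methylation level, at roughly fragment-scale (hundreds of bp)
resolution. Nothing in this package pretends to per-cytosine
methylation levels (that would need bisulfite data); every statistic is
a function of read positions over regions.

The package follows the analysis chain used in comparative poplar
parent-hybrid methylome studies:

1. **Mapping summaries.** Mapped and uniquely-mapped rates are
   `100 · count / total_reads`. Rates are held at full precision and
   rounded only for presentation (1 decimal), matching how such tables
   are printed.
2. **Window tracks.** Each chromosome is tiled with 100-kb windows; a
   read belongs to the window containing its *start* coordinate (the
   track is a read count, not base coverage, so reads are not split
   across windows). Counts are scaled to
   `raw × 10⁶ / uniquely_mapped_total`.
3. **Context coverage.** Every cytosine on both strands is classified
   by its two downstream bases into CG, CHG or CHH (H = A, T or C);
   the statistic is the fraction of context sites whose cytosine
   position is covered by at least `d` reads (`d = 1` default). Sites
   whose 2-base downstream context runs off the chromosome end, or
   contains an `N`, are dropped and counted in a diagnostics field.
4. **Feature fractions.** An item (read or peak) is counted for every
   feature class it overlaps by ≥ 1 bp; an item spanning two classes
   counts in both, so per-class percentages deliberately do not sum
   to 100 (published peak-per-feature tables behave the same way).
   Promoters are exactly 2 kb upstream of the annotated TSS,
   strand-aware, clipped at chromosome ends.
5. **Metaprofiles.** The 20/40/20 layout: 2-kb flanks in 20 fixed
   100-bp bins each, the interval body in 40 equal *fractions* of its
   length. Fractional bin boundaries attribute bases proportionally,
   which makes the body profile invariant to interval length in
   expectation. Stranded intervals are oriented 5'→3'; CpG islands are
   unstranded and profiled left-to-right.
6. **Differential methylation.** The two samples' peak intervals are
   merged (union, with overlapping or book-ended pieces coalesced) into
   disjoint regions. Although peak *summits* are what an external
   caller emits, regions must have width to hold reads, so the merge
   operates on peak intervals — the only reading under which
   region-level read counting is possible. Per region, raw counts
   `a, b` against library totals `N₁, N₂` enter the Pearson chi-square
   on `[[a, N₁−a], [b, N₂−b]]` with df = 1 and no continuity
   correction (MeDIP peak counts are large; Yates would only make the
   test conservative). The 2×2 layout and the use of *raw* counts for
   the test are this package's interpretation: a chi-square needs
   counts, while direction and fold use the per-million *normalized*
   values. A gene overlapping a region is called hypermethylated when
   sample 2's normalized count is higher and hypomethylated in the
   opposite case, subject to p < 0.01, normalized ratio strictly > 2,
   and both samples having ≥ 1 read in the overlapped feature of that
   gene. A zero-count side gives an infinite ratio and passes the fold
   criterion if p passes. One gene can be called in several feature
   classes, and (via different regions) in both directions; gene-level
   totals then count it once per direction. No multiple-testing
   correction is applied inside this filter — correction belongs to the
   enrichment stage — though `p.adjust` can trivially be applied to the
   region table by the user.
7. **Enrichment.** Exact upper-tail hypergeometric p per term
   (`P(X ≥ k)` with `phyper`), population = all genes of the supplied
   annotation map (the "whole genome"), Benjamini–Hochberg adjustment
   across tested terms. BH was chosen because FDR-style q-values are
   the norm for pathway enrichment; parent-child term propagation is
   off by default (annotation files are often pre-propagated).
8. **Heterosis.** Better-parent heterosis
   `H = (F1 − Ps)/Ps × 100` with `Ps` the higher *parental mean*,
   re-identified per trait and age; the mid-parent value is
   `(P1 + P2)/2`. One-way ANOVA (`aov`) across lines; a within-group
   mean square at machine-noise scale flags the F ratio as degenerate
   rather than reporting a spurious value.

### Coordinate convention

All intervals inside the package are `GRanges` in the Bioconductor
1-based closed convention — the single internal convention that kills
off-by-one drift in this ecosystem. Conversions happen only at file
boundaries: BED is 0-based half-open, GFF3 and MACS-style peak tables
are 1-based. Uniqueness of mapping cannot be derived downstream of an
aligner, so it enters as a per-read dialect: SAM `MAPQ > 0` (and not
secondary), or the score column of BED6.

## The simulator: what it emulates

The generator produces the study conditions end to end: genome,
annotation, per-line methylomes, reads, truth peaks, and a trait table.
Defaults (all in `simulation_config()`):

| knob | default | why |
|---|---|---|
| genome | 2 × 1.5 Mb, GC 0.34 | poplar-like GC; large enough that ~100 planted genes occupy a modest fraction of tiles |
| tile | 500 bp | MeDIP resolution is fragment-scale; methylation is modelled per tile, not per cytosine |
| reads | 49-bp single-end, 10⁵ per line, 90% unique | panel-scale library shape; depth that leaves context coverage unsaturated |
| enrichment | weight `β + λ·m`, λ = 10, β = 0.05 | strong antibody enrichment over a small unmethylated background; the study itself gives no quantitative efficiency, so these are calibration knobs of the simulator, not claims |
| parents | mean methylation 0.60 (P1) vs 0.30 (P2) | parents of similar genetic background but distinct methylome level |
| hybrids | `non_additive_up` δ = 0.05; `below_both` margin = 0.1 | a better-parent hybrid above the MPV and a lower-parent hybrid below both parents |
| truth peaks | tiles with m ≥ the 0.9 methylome quantile, coalesced | stands in for an external peak caller |
| planted genes | 50 hyper + 50 hypo at m 0.95/0.05 over the gene's footprint | recoverable truth for the differential caller |

Per-line methylomes share one uniform random field `u` over tiles and
set `m = u^γ` with `γ = 1/level − 1`, so `E[m] = level`. This makes a
higher-level line tile-wise above a lower-level one with *nested*
quantiles — the same regions are methylable in both parents, the
overall level differs. That is what makes the context-coverage
comparison behave like the real panel: the lower parent concentrates
its reads into fewer heavily methylated tiles, covers less of the
genome, and an additive hybrid lands between the parents while a
`non_additive_up` hybrid exceeds the parental average.

Planted differential genes overwrite the tiles of a gene's whole
annotated footprint (promoter included) so that every feature-level
call reflects the planted difference, and chosen footprints keep at
least 1 kb (two tiles) of separation so two planted genes of opposite
direction cannot book-end into a single merged region — without this,
region-level counts genuinely mix two opposite signals and the
"recovered direction" of one gene is undefined.

What the simulator does **not** emulate: sequencing errors and base
qualities, fragment-length variation, PCR duplicates, mappability
structure (unique/multi status is an i.i.d. flag), CpG-density-dependent
antibody affinity, and biological replicate variance. Passing the
recovery tests therefore shows the *pipeline arithmetic* is right under
the stated generative model; it does not validate the model against
real MeDIP libraries.

## Numerical and design choices

* **Chi-square:** closed form `N(ad − bc)² / ((a+b)(c+d)(a+c)(b+d))`
  with `p = pchisq(stat, 1, lower.tail = FALSE)`; regions with
  `a = b = 0` are undefined, flagged `no_coverage`, and excluded from
  calls. The implementation is tested to ≤ 10⁻⁹ relative error against
  `chisq.test(correct = FALSE)` and the hypergeometric to ≤ 10⁻¹²
  against an exact log-binomial sum.
* **Null calibration** uses a *flat* methylome (constant m = 0.5) with
  two independent read draws over 250-bp tiles, taking every other
  tile as a region (6000 regions, 5 × 10⁵ reads per draw) so all
  regions have comparable expected counts (~42); with heterogeneous
  counts the small-count regions make the chi-square approximation
  discretely conservative and the calibration check would measure that
  artefact instead.
* **Ties and edges:** fold exactly 2 is excluded (strict inequality);
  book-ended peaks merge (gap 0); the last genome tile and window may
  be short; metaprofile flanks running off a chromosome contribute
  zero depth; intervals shorter than the body bin count are skipped
  with a message.
* **Window counting and normalization denominators** default to
  uniquely mapped reads (consistent with the per-million denominator);
  context depth defaults to all mapped reads. Both are flags, since
  published methods rarely state the choice.
* **Determinism:** every generator seeds its own derived RNG stream
  from `config$seed` and restores the caller's RNG state, so identical
  configurations give byte-identical output regardless of call order.
* **Presentation rounding** mirrors printed tables (rates to 1
  decimal, averages to 2); one published mapped rate is reproducibly a
  truncation rather than a rounding of the underlying counts, and the
  bundled reference table records the printed value alongside the
  counts.

## Problem sizes

The test suite and the acceptance script run the default 3-Mb panel
(four lines × 10⁵ reads), a 6000-region null calibration at 5 × 10⁵
reads per draw, 1000-instance oracle sweeps, and a 60-CGI metaprofile
panel; module tests use a 0.4-Mb configuration. These sizes were chosen
so the full chain demonstrates its statistical properties (recovery,
calibration, monotonicity) at comfortable margins while remaining
quick to run on a laptop.

## Known limitations

* MeDIP read density confounds methylation level with CpG density;
  without a density correction (e.g. Bayesian deconvolution), between-
  line comparisons are safest at matched loci — which is all this
  package does, but absolute "coverage" percentages should not be read
  as methylation levels.
* The chi-square filter tests each merged region independently with no
  FDR control, by design; interpret per-region p-values as a filter,
  not as calibrated genome-wide inference.
* The uniqueness flag is trusted from the aligner dialect; no
  mappability model is applied.
* Heterosis uncertainties (the ± on H) are not computed: they require
  block-level resampling schemes that published tables do not specify.
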