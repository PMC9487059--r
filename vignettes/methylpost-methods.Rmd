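---
title: "methylpost: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methylpost: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

methylpost covers the downstream, post-alignment half of a whole-genome
bisulfite sequencing (WGBS) study. Its input is the per-cytosine output
of a methylation caller — a Bismark-style CX cytosine report (one row
per cytosine: chromosome, 1-based position, strand, methylated count,
unmethylated count, CX context, trinucleotide) or a BS-Seeker2 CGmap
file, which is converted to the same representation on ingest. From
there it produces methylation profiles, hypomethylated segments,
differential methylation calls and promoter-associated gene lists.
Read trimming, alignment and methylation calling are out of scope, as
are enrichment analysis itself (a gene list is exported as the hand-off
point) and figure rendering (tabular bedGraph/TSV equivalents are
written instead).

## The quantities being estimated

At every cytosine the data are a pair of counts $(m, u)$ of methylated
and unmethylated calls. The methylation level is the binomial point
estimate

$$\hat\beta = \frac{m}{m + u},$$

undefined (reported as missing, never imputed) when $m + u = 0$.
Replicates of one sample are merged by summing counts per (chromosome,
position, strand), which is the maximum-likelihood pooling under the
binomial model and mirrors how multi-replicate WGBS samples are
conventionally combined. For CpG-context analyses the two strands of a
symmetric CpG dinucleotide are pooled the same way ("destranding"),
anchoring the unit at the '+' strand cytosine; CpG methylation is
symmetric in mammalian somatic cells, so this doubles the effective
coverage per unit without changing the estimand.

## Profiles

* **Context summaries.** Mean level and a 10-bin histogram per CX
  context (CpG, CHG, CHH) over covered sites. Histogram bins are
  left-closed and right-open except the last, which is closed at 1.0,
  so a fully methylated site is counted once, in the top bin.
* **Genome bins.** Chromosomes are tiled with fixed 100-kb bins (the
  last bin truncated); each bin reports the mean level over covered
  sites of the chosen context, or missing when empty. Missing bins are
  omitted from the bedGraph — absence of data is encoded as absence of
  a line. The coverage-weighted mean of bin means equals the
  genome-wide mean exactly, which the tests assert to $10^{-12}$.
* **Genomic contexts.** A promoter is the 1-kb region immediately
  upstream of a gene's TSS, strand-aware and clamped at chromosome
  edges. The gene body is the min-to-max span of all transcripts
  sharing a gene id; merged exons are the union of all transcripts'
  exons; introns are the gene span minus the merged exons; intergenic
  is the genome minus all transcript spans. The classes are
  deliberately non-exclusive except intergenic: a site in an exon also
  contributes to the gene-body mean, while intergenic sites contribute
  nowhere else. Note that promoters usually lie in intergenic space —
  the partition constraint applies to transcribed regions, not to
  promoters.
* **TSS metaprofiles.** Windows of 500 bp sliding by 100 bp across
  1500 bp on each side of the TSS give
  $\lfloor(2 \cdot 1500 - 500)/100\rfloor + 1 = 26$ windows per gene.
  Windows are strand-oriented: window 1 is the most upstream window for
  genes on either strand, so a '-' gene's profile equals the
  coordinate-mirrored '+' computation. Whether such profiles should be
  strand-oriented at all is a genuine design choice; we orient by
  strand because a metagene average is only interpretable when
  "upstream" means the same thing for every gene. CpG is the default
  context profiled, as the dominant methylation context around
  mammalian promoters; other contexts can be selected. Windows that
  run past a chromosome edge, or contain no covered site, are missing
  for that gene and are ignored by the across-gene mean.

Multi-transcript genes raise a definitional question for promoters:
we anchor the promoter at the 5'-most TSS of the gene's transcript
union ('+' strand; 3'-most on '-'), treating "the gene" as one unit
rather than emitting one promoter per transcript.

## Hypomethylated segmentation (UMRs and LMRs)

Hypomethylated regions are contiguous stretches of CpGs with markedly
lower methylation than the surrounding background. The canonical
treatment distinguishes unmethylated regions (UMRs; CpG-island-like,
near-zero methylation, typically promoters) from low-methylated
regions (LMRs; CpG-poor distal elements around 30% methylation).
methylpost uses a deliberately transparent threshold-run procedure
rather than a hidden-Markov segmentation:

1. keep destranded CpG units with coverage ≥ `minCoverage` (default 5);
2. smooth each unit's level with a centered running mean over
   `segSmoothK` = 3 consecutive CpGs per chromosome (truncated at the
   ends);
3. mark units with smoothed level < `lmrMaxLevel` = 0.50;
4. maximal runs of ≥ `segMinCpgs` = 4 marked units become segments
   spanning the first to the last unit;
5. classify by the mean *raw* level inside: < `umrMaxLevel` = 0.10 is a
   UMR, otherwise an LMR.

The class boundaries encode the verbal definitions ("almost zero" for
UMRs, "around 30%" for LMRs, i.e. anything below 50% but above 10%).
They are this package's own operational definitions; classification is
by level only, not by CpG density — density enters descriptively via
the reported `n_cpg`. All five constants live in `AnalysisParams`. The
procedure's behavior is fully characterized by an exhaustive
brute-force oracle in the tests, and its recovery properties (planted
features of ≥ 10 CpGs recovered with ≤ 2 CpG boundary error at 30×
coverage; no calls in long background stretches) are asserted on
simulated data. A 3-unit running mean costs at most
$\lfloor k/2 \rfloor = 1$ CpG of boundary blur, which is where the
2-CpG tolerance comes from (1 from smoothing, 1 from sampling noise).

## Differential methylation

Comparisons are pairwise (case vs control), on replicate-merged,
destranded CpG tracks, so DMC coordinates coincide with segmentation
coordinates. Per site, only positions present in both samples with
coverage ≥ `minCoverage` in each are tested.

**Per-site test.** With replicates pre-merged, per-site differential
testing reduces to a 2×2 contingency table
$[[m_1, u_1], [m_2, u_2]]$. methylpost implements the two-sided exact
(hypergeometric / Fisher) test directly: the p-value is the sum of the
probabilities of all tables with the same margins that are no more
likely than the observed one. The implementation is validated to
$10^{-12}$ against a full enumeration oracle and cross-checked against
`stats::fisher.test`. The exact test is conservative on discrete
tables; on 10,000 simulated null CpGs at 30× per group the observed
fraction with $p < 0.05$ is about 0.03.

**Multiple testing.** Benjamini–Hochberg step-up q-values via
`stats::p.adjust(method = "BH")` — standard, monotone and reproducible.
Methods that re-estimate the null proportion (e.g. SLIM) are
intentionally not reproduced.

**DMC filter.** A site is a DMC when $q \le$ `qCutoff` *and*
$|\Delta| \ge$ `minDiffPp` percentage points. Defaults are
`qCutoff` = 0.5 and `minDiffPp` = 25, mirroring the common
application-style settings (`-c 5 -q 0.5`, with 25 pp the conventional
default difference threshold). The direction is *hypo* when the case
level is below the control level, *hyper* otherwise.

**DMR rules.** Two rule sets are implemented, reflecting the two
definitions in common use:

* *gap_cluster*: per chromosome and per direction, maximal chains of
  DMCs with adjacent gaps ≤ `dmrMaxGap` = 500 bp (inclusive — a gap of
  exactly 500 bp clusters; the gap is measured between DMC base
  positions) containing ≥ `dmrMinDmcs` = 2 DMCs. Hypo- and
  hypermethylated DMCs never share a region.
* *smooth_like*: gap-cluster candidates additionally requiring ≥ 3
  DMCs, mean $|\Delta| \ge 10$ pp, ≥ 70 destranded CpG units in the
  span, and length ≥ 1 kb. This is a filter over candidates in the
  spirit of smoothing-based DMR callers, not a re-implementation of a
  local-likelihood smoother; "70 CpGs" counts all destranded units in
  the span, covered or not.

**Summaries and gene association.** DMC counts per direction (overall
and within promoters), distances between consecutive DMCs, and each
DMC's signed distance to its nearest TSS (negative = upstream in gene
orientation; equidistant ties break to the lower coordinate) are
reported. Genes whose promoter contains a DMC (or overlaps a DMR by
≥ 1 bp) are exported one id per line, ready for a functional-enrichment
tool.

## The simulator

The synthetic methylome generator exists so that every stage is
testable with no external data, and its defaults *are* the conditions
under which the package's statistical claims are made:

| parameter | default | rationale |
|---|---|---|
| CpG background level | 0.80 | within the 70–90% of CpGs methylated in normal somatic cells |
| CHG/CHH level | 0.01 | non-CpG contexts are hardly methylated in mammalian somatic tissue |
| UMR level / placement | 0.02, at promoters with prob. 0.5 | promoter CpG islands are typically unmethylated |
| LMR level / count | 0.30, 5 per genome | the "around 30%" low-methylated class |
| DMR difference / width / count | 40 pp, 10 CpG units, 20 | strong, desk-scale differential signal |
| coverage | Poisson, mean 30 per replicate | typical WGBS depth; Poisson so coverage filters are exercised |
| genome | 2 chromosomes × 200 kb, 20 genes, 2 replicates | desk-scale: ~160k cytosines, ~16k destranded CpG units |

The genome is random sequence with CpG-enriched promoters (25% of
promoter dinucleotides set to CG, mimicking CpG islands); genes are
non-overlapping with 2–5 exons. True methylation probabilities are
*assigned* (the background mean is exactly 0.80), and only the counts
are sampled: coverage is Poisson, methylated counts binomial, sites
independent. Planted DMRs shift the case condition by exactly
`dmrDiffPp`/100 with the sign chosen to stay inside [0, 1] (at the
defaults, all planted DMRs are hypomethylated in the case); everywhere
else the two conditions are identical. Feature placements that would
collide are re-drawn up to a retry cap and then fail loudly. Every
random stream is derived deterministically from (seed, condition,
replicate), so any single replicate is reproducible in isolation and a
fixed seed reproduces every output file byte for byte.

What the simulator does *not* model — and what passing tests therefore
do not show about real data: read-level artifacts (incomplete bisulfite
conversion, mapping bias, M-bias), spatial autocorrelation of
methylation beyond the planted blocks, biological replicate-level
dispersion (replicates are resampled from identical true
probabilities), and realistic genome composition. The simulation
validates the counting, testing, clustering and segmentation machinery,
not the biology.

## Numerical and interface choices

* Internal containers are `GRanges` in the native 1-based closed
  convention; 0-based half-open coordinates appear only in BED and
  bedGraph files, 1-based only in cytosine reports and CGmap, each
  converted at the file boundary. Tests assert the file-level
  conventions byte for byte.
* Zero-coverage cytosines are kept on ingest and excluded at analysis
  time, so the coverage filter is applied once, visibly, with one
  parameter.
* Gzip input is detected by magic bytes, not file extension.
* Context `"CG"` in files maps to `"CpG"` internally (file dialects
  write CG; the literature says CpG).
* A chromosome present in the annotation but absent from chrom.sizes
  is a hard error, never a silent skip — silently partial analyses are
  the classic WGBS failure mode. Likewise a cytosine beyond the
  declared chromosome end.
* CGmap rows carry only a dinucleotide, so the stored trinucleotide is
  padded with `N`; the context/trinucleotide consistency check applies
  only to N-free trinucleotides. Zero-coverage CGmap rows are
  preserved, consistent with the cytosine-report reader.
* Degenerate inputs: an empty call set round-trips as an empty file; a
  chromosome with fewer covered CpGs than the smoothing width is
  skipped by segmentation with a warning; a comparison with no shared
  qualifying sites returns an empty result with a warning rather than
  an error.
* Deterministic ordering everywhere: records sort by (chromosome,
  position, strand), regions by (chromosome, start, direction), and
  identical inputs plus an identical seed give byte-identical output
  directories (timestamps appear only in log files; the run config
  written by the simulator uses paths relative to itself so bundles
  are relocatable).

The pipeline stages (`simulate`, `profile`, `hmr`, `dmr`) are
independently runnable over a declarative YAML config rather than
chained through a monolithic state, which is what makes each stage
testable in isolation; a thin command-line wrapper over the same
functions ships in `inst/scripts/methylpost`.

## Problem sizes used in the validation suite

The test suite works at desk scale by design: the default simulated
genome (2 × 200 kb, ~16k CpG units) for the recovery and determinism
checks; 10,000 sites for null calibration; 1,000 random annotations
for the context-partition invariants; 1,000 random DMC configurations
(up to 200 sites each) for the clustering oracle; and exhaustive
brute-force oracles on inputs of up to ~120 CpGs for segmentation.
These sizes were chosen as the smallest at which the statistical
claims are meaningful; all scale linearly if increased.

## Known limitations

* The per-site exact test ignores replicate-level dispersion: merging
  replicates before testing treats biological replicates as technical.
  Covariate-adjusted or beta-binomial models are out of scope.
* The segmentation is a threshold-run procedure with fixed level
  cutoffs, not an HMM with FDR-calibrated cutoff selection; partially
  methylated domains (PMDs) are not modeled.
* UMR/LMR classification uses mean level only; a CpG-density-based
  classifier would be a reasonable alternative definition.
* The "filter out positions with q-value less than the cutoff"
  phrasing found in pipeline documentation is ambiguous; methylpost
  implements the conventional reading — *retain* sites with
  $q \le$ cutoff.
* Whether DMC counting should be per-strand rather than destranded is
  configurable (`context = NULL` tests all contexts per strand), but
  destranded CpG units are the default and the only path exercised by
  the acceptance checks.
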