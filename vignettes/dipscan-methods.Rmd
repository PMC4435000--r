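---
title: "dipscan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dipscan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models inside dipscan, the
parameters that matter, the design choices made where several defensible
options existed, and — because the whole test suite runs on simulated
data — exactly what the simulator does and does not emulate.

# The measurement problem

5-hydroxymethylcytosine is rare (0.1–7% of modified cytosines outside the
CNS), so genome-wide profiles are obtained by enriching fragmented DNA
with a modification-specific antibody and sequencing the enriched (IP)
pool next to a 10% input aliquot.  The sequencing readout per genomic
window is therefore not coverage of the mark itself but the *relative
enrichment* of IP over input.  All of dipscan's quantification is built
on that ratio.

# Windowed quantification

Reads are assigned to fixed windows (200 bp default — fine enough to
resolve promoter-scale features, coarse enough to smooth sampling noise).
Each mapped read contributes to exactly one window, the one containing
the midpoint of its aligned span.  Midpoint assignment, rather than
overlap counting, keeps total counts conserved (`sum(counts) + skipped ==
mapped reads`), which makes the counting stage exactly testable against a
brute-force oracle; with ~150 bp reads in 200 bp windows the practical
difference from overlap counting is marginal.  With sliding windows
(`step < windowSize`) the window with the largest start not exceeding the
midpoint is used, so the assignment stays unique.

Depth normalization is counts per million.  The enrichment track is

$$\log_2\frac{\mathrm{CPM}_{IP,i} + c}{\mathrm{CPM}_{input,i} + c}$$

with pseudocount $c = 0.5$ CPM.  The pseudocount keeps sparse windows
finite and forces windows empty in both samples to exactly 0, so grids
remain comparable across samples.  Note that $c$ is on the CPM scale: at
very low library sizes one CPM unit corresponds to much less than one
read and the ratio becomes noisy in near-empty windows; for shallow
libraries a pseudocount near the CPM value of a single read
($10^6/N$) is the more stable choice.

## Duplicates

Ten cycles of whole-genome amplification mean that the same original
fragment is frequently sequenced many times.  Counting those repeats
would make window counts strongly overdispersed relative to any Poisson
model, so records flagged as duplicates are excluded by default
(`readAlignments(keepDuplicates = FALSE)`), collapsing each fragment to
one observation.  The simulator flags repeated draws of a fragment with
SAM flag 1024 for the same reason.

# Peak calling

Window $i$ of the IP track is tested against the expectation

$$\lambda_i = \max\!\big(s \cdot \max(x_i, \bar{x}_i),\ f \cdot N_{IP}/W\big),
\qquad s = N_{IP}/N_{input}$$

where $x_i$ is the input count, $\bar{x}_i$ a running mean of the input
over ±`smoothWindows` windows (default 25, i.e. ±5 kb at 200 bp), $f$
the floor fraction (default 0.1) and $W$ the window count.  The
one-sided Poisson p-value $P(X \ge \mathrm{IP}_i \mid \lambda_i)$ is
Benjamini–Hochberg adjusted across all windows; windows with
$q \le \alpha$ (default 0.05) *and* log2 CPM enrichment ≥ `minLog2`
(default 1) are significant, and runs of adjacent significant windows
merge into peaks (chromosome boundaries always split).

Two aspects deserve comment:

* **Input smoothing.**  A matched input sequenced at practical depth has
  only a handful of reads per 200 bp window, so the naive expectation
  $s \cdot x_i$ is an extremely noisy, anti-conservative null: windows
  where the input happens to be 0 would be tested against only the
  floor, and Poisson sampling alone then produces hundreds of false
  positives genome-wide.  Taking the maximum of the observed window and
  its local neighbourhood mean — the same idea as the local-lambda
  background of general-purpose ChIP-seq callers — restores a
  conservative null while preserving sensitivity to real copy-number or
  accessibility structure in the input.  `smoothWindows = 0` disables
  the refinement.
* **The floor** prevents unbounded significance in regions where even
  the smoothed input is empty; 0.1× the genome-mean IP rate is low
  enough never to mask real signal.

Because the null is (conservatively) correct, BH control of the FDR at
$\alpha$ directly bounds the expected fraction of false peaks — this is
what the recovery tests verify empirically.

# Compartment annotation

Peak midpoints are classified with strict precedence promoter core
(TSS ± 500 bp) → promoter proximal (± 2 kb) → promoter distal (± 10 kb)
→ intragenic → intergenic.  Promoter zones are symmetric around every
TSS and evaluated before gene bodies, so a peak just downstream of a TSS
inside the gene is "promoter proximal", not "intragenic".  The radii are
package defaults, exposed in `compartmentScheme()`; midpoint
classification (rather than maximal overlap) guarantees exactly one
label per peak.  Gene models are per-gene unions of transcripts, with
the TSS at the 5' end of the unioned body.

# Metagene profiles

Each gene body is rescaled to 100 bins; flanks of 25% of the gene length
get 25 bins each, so bin width is uniform *within* a gene and the flank
occupies a quarter of the body's visual width.  A bin's value is the
length-weighted mean of the window step function it covers, computed
from an exact piecewise-linear integral — hence the profile is linear in
the track and constant tracks give exactly flat profiles (both are
asserted in the tests).  Minus-strand genes are reversed so bin 0 is
always 5'.  Bins that fall off a chromosome end are dropped for that
gene, with per-bin gene counts reported.

# Concordance

R² is reported as the square of Pearson r: it is symmetric in the two
tracks and avoids choosing a regression direction.  Correlation matrices
are clustered with average linkage on distance $1 - r$ (the linkage is a
configurable convention; average linkage is the common default for
correlation matrices).  Random-window subsampling is uniform without
replacement and deterministic given a seed.  Condition differences are
reported as descriptive per-window track differences without a
significance model.

# The simulator

`simulateRun()` executes the protocol generatively:

1. CpG sites placed by a Poisson process (default mean spacing 100 bp).
2. Each site marked with probability `hmcFraction` (default 0.01),
   multiplied inside planted regions (capped at 1).
3. `nFragments` fragments: uniform start, length ~ Normal(300, 75)
   clipped to [100, 500] bp.
4. 10% reserved as input.
5. Capture: a fragment with $k$ marked sites is retained with
   probability $1 - (1 - e)^k$ (default $e = 0.9$); unmarked fragments
   with probability `nonspecificRate` (default 0.1).  The independent
   per-site form is chosen for analytic tractability — it is a model,
   not a claim about antibody chemistry.
6. Amplification to an expected $2^{10}$ copies, with optional
   per-fragment log-normal efficiency (`wgaBiasSd`, default 0 =
   unbiased).
7. Size selection to [100, 250] bp.
8. Sequencing: `depth` reads drawn from the pool with
   amplification-weighted replacement; read length = min(fragment
   length, Normal(137, 15) truncated at 20 bp); repeats of a fragment
   flagged as duplicates.  Reads are emitted as already-aligned records
   (mapping is upstream of this toolkit); optional switches inject
   20–49 bp adapter artefacts and degrade the mapping of sub-50 bp
   reads for QC testing.

The amplify → size-select → sequence order follows the bench protocol
(library amplification precedes bead selection, and sequencing sampling
is necessarily last), and guarantees exactly `depth` reads per sample.

`captureEfficiency` and `nonspecificRate` have no measured wet-lab
values; they are free model parameters.  0.9 reflects a high-specificity
antibody; 0.1 nonspecific retention makes the deduplicated IP and input
pools comparably sized at equal aliquot proportions, which is also the
regime in which the IP-vs-input ratio is well behaved.

`expectedWindowEnrichment()` evaluates the capture stage in closed form:
for each window, the capture probability is averaged over the
post-selection fragment length distribution (integer-length weights from
the clipped normal, aggregated into integration nodes) and over midpoint
positions within the window, then normalized to a genome-wide mean of 1.
It shares no code path with the Monte-Carlo sampler, so agreement
between the two is a genuine cross-check of both.

## What the simulator does not emulate

No sequence content (reads are emitted as coordinates, not base
strings), no sequencing error or homopolymer model, no mappability or GC
structure, no chromatin or copy-number variation in the input, and no
real genome: CpG positions are a homogeneous Poisson process, whereas
real genomes have CpG islands and deserts.  Passing tests therefore
demonstrate the correctness and calibration of the *computational*
pipeline under its own generative assumptions — not robustness to the
biases of real libraries.

# Fixed study designs used by the tests

The statistical acceptance checks run on configurations fixed in advance
by power analysis (per-window expected counts large enough that the
assertion being tested is not noise-limited):

* **Null calibration** — defaults with `hmcFraction = 0`, 5M fragments,
  100k reads/sample on 2×1 Mb.  Five million fragments keep both
  deduplicated pools above the sequencing depth, so IP and input are
  comparably sparse and the genome-mean log2 ratio is testable against
  ±0.05.
* **Recovery** — `simConfigExample()`: 2×1 Mb, ten 2 kb regions at
  multiplier 50 (half the CpGs marked), 500k fragments, 200k
  reads/sample → ~10 deduplicated IP reads per enriched window, ample
  for the window test at FDR 0.05.
* **Model agreement** — 2×300 kb, ten 3 kb regions with multipliers
  graded 2–300, 500k fragments, 1 kb windows: the graded multipliers
  span the capture model's dynamic range and the window size keeps
  Poisson noise well below it.
* **Replicate concordance** — 2×5 Mb (50,000 windows), `hmcFraction =
  0.05`, twenty 2 kb regions at multiplier 20, 3M fragments, 200k
  reads/sample, two runs re-sequenced from one shared truth.

Precision in the recovery tests is measured against windows whose
closed-form expected enrichment is at least twice the genome median:
isolated marked CpGs outside the planted regions are genuine
modification signal, and peaks over them are correct detections, not
false positives.  Recall is measured against the planted regions only.

# Numerical and coordinate conventions

Internally all ranges are 1-based closed GRanges, the Bioconductor
convention; BED, bedGraph and SAM conversion happens only at the I/O
boundary, and all on-disk BED-family coordinates are 0-based half-open.
The final window of each chromosome is truncated at the chromosome end
rather than dropped, so no base is silently excluded.  bedGraph values
are written with six decimal places (round trips are exact to 1e-6);
SAM output is byte-deterministic for a given configuration and seed.
Tied hierarchical-clustering merges follow `hclust`'s deterministic
ordering.  All seeded operations restore the caller's RNG state.

# Known limitations

* The peak caller is single-resolution: no broad/narrow dual mode, no
  differential peak calling (condition differences are descriptive
  tracks).
* No GC/mappability correction is applied anywhere.
* Cross-platform comparisons (e.g. against microarray log ratios) are
  handled only by resampling both signals onto a shared grid; no
  probe-level processing is implemented.
* The metagene profiler requires a tiling grid (`step == windowSize`).
* `WindowTrack` stores the whole genome densely; at 200 bp windows this
  is ~15 MB per mammalian-genome track, acceptable but not sparse.
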