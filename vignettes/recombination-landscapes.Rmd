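---
title: "Methods: genetic maps, shuffling and recombination landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic maps, shuffling and recombination landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recland)
library(dplyr)
```

`recland` analyses meiotic recombination from two complementary sources:
crossovers (COs) observed segregating in a pedigree, which give unbiased,
sex-specific but broad-scale genetic maps; and per-bp population
recombination rate tracks inferred from linkage disequilibrium (LD), which
resolve kilobase-scale structure but estimate `rho = 4*Ne*r` and therefore
need calibration against the pedigree maps. This vignette describes the
models and conventions behind each stage, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the numerical
decisions taken where the methodology is genuinely open.

## Coordinates and data model

All interval data are 0-based, half-open (BED convention); marker and CO
positions are 0-based bp points. The genome is described by a
`genome_layout()` (linkage group, assembled length, autosome flag) and every
reader validates intervals against it. Rate tracks are tibbles
`lg, start, end, rate` with `rate` the per-bp, per-generation crossover
probability of a transmitted gamete — the semantics of LD-based estimators
after dividing out `4*Ne`.

## Map building from segregation data

For each pair of adjacent markers, the recombination fraction is estimated
as the proportion of meioses with an *odd* number of COs between the two
markers. Odd-counting is deliberate: an even number of crossovers between
two markers restores the parental phase and is invisible to segregation
analysis, so counting raw COs would inflate the map wherever marker spacing
is wide. Interval fractions are converted to distance either directly
(`100*c` cM, the default — at dense marker spacing the mapping-function
correction is negligible) or through Haldane's function
`d = -50*ln(1 - 2c)`, which assumes no crossover interference. Haldane mode
refuses `c >= 0.5` and suggests a denser grid rather than returning an
infinite distance.

A meiosis here is a *transmitted gamete*. A crossover on the bivalent
involves two of the four chromatids, so it appears in a transmitted gamete
with probability 1/2; this is why one obligate CO per chromosome per meiosis
corresponds to a ~50 cM map, not 100 cM, and why the simulator applies the
1/2 thinning by default (`transmit = TRUE` in `simulate_meioses()`).

The sex-averaged map is built from the pooled male + female meioses rather
than averaging the two sex maps. Pooling weights each sex by its observed
meioses and behaves sensibly when one sex contributes few events; it is the
natural estimator when families contribute both parents.

**End trimming.** Markers misplaced at linkage-group extremities show up as
implausible jumps in genetic position. `trim_map_ends()` scans the terminal
`window_markers` (default 100) markers at each end and removes everything
outside a neighbour separation larger than `max_jump` (default 2 cM),
repeating until the terminal window is clean. Interior jumps are never
touched — a real recombination desert boundary in the middle of a
chromosome is signal, not artefact. Cumulative positions are re-anchored to
0 afterwards.

## Pseudomarkers and intrachromosomal shuffling

Because real markers are irregular, pair statistics over markers would be
dominated by dense regions. `interpolate_pseudomarkers()` places a marker
every `spacing` bp (default 10 kb) from position 0, plus the sequence end,
and interpolates genetic positions linearly between flanking true markers.
Outside the marker span the terminal genetic position is clamped: no
segregation information exists there, and linear extrapolation would
fabricate map length.

`r_intra()` computes, per linkage group, the mean over all pseudomarker
pairs of their map separation, in two modes:

* `haldane_prob` (default): each separation `d` cM is converted to a
  recombination probability `(1 - exp(-d/50))/2` before averaging. This
  bounds every pair's contribution by 0.5, which is required for maps longer
  than 50 cM where raw distances exceed the probability scale.
* `morgan_linear`: the raw separation in Morgans. For a uniform map of total
  length `T` cM this has the closed form `T/300` (mean pairwise distance of
  a uniform variable is a third of its range), which the tests exploit.

Both modes are reported because the averaging scale is a genuine
methodological fork; results should be compared within one mode. The per-LG
mean is weighted by `(L_k / sum(L))^2` — the probability that two uniformly
drawn loci both land on LG `k` — using *assembled* lengths from the layout,
not marker spans, so unmapped sequence still counts as territory that could
be shuffled. The O(n²) pair sum is evaluated with O(n) prefix identities on
the sorted positions (for the Haldane mode via a prefix sum of
`exp(D/50)`, centred on the median to keep the exponentials small);
equality with the brute-force oracle to 1e-9 is asserted in the tests up to
n = 2000.

## Windowed landscapes and scaling

`windows_from_track()` converts a rate track into fixed-size windows. Each
track interval of length `len` carries probability `p = r*len`, translated
once through Haldane's function; its centimorgans are then split pro rata by
bp across the windows it overlaps. Applying Haldane per track interval —
the unit on which the rate was estimated — rather than per window makes
window maps *exactly* additive: the 1 Mb map is the sum of its thousand
1 kb windows and the genome total is invariant under window size, which the
tests assert to 1e-9. A trailing window shorter than the nominal size is
kept and its cM/Mb normalised by its true length, but flagged
`complete = FALSE` and excluded from Lorenz/Gini and RRR80 computations,
whose statistics assume equal support.

`scale_to_linkage()` removes the `4*Ne` confound of LD-based estimates by
multiplying each linkage group's centimorgans by
`f_k = (linkage cM) / (LD cM)` — separately per LG, since `Ne` varies along
the genome through selection and drift. Scaling a track (rather than a
window table) inverts Haldane per interval after scaling so that the
rescaled track reproduces the target lengths exactly when re-windowed.

The genome-average rate used by fold-based hotspot calls is total autosomal
cM over total autosomal assembled Mb, computed on the scaled landscape.

## Inequality, hotspots and element profiles

`lorenz_gini()` orders complete 10 kb windows by decreasing rate and
accumulates sequence fraction against cM fraction; the Gini coefficient is
twice the trapezoid area between the curve and the diagonal. An all-zero
linkage group has no meaningful inequality and is flagged `undefined` rather
than given 0. The statistic is invariant to uniform rescaling and strictly
increases under regressive transfers (both property-tested), and the
sequence fraction carrying 80% of recombination is reported alongside.

Broad-scale calls (`call_global()`) use the genome mean: hotspots are
windows with *more than* `hot_fold` (5) times the mean — strict inequality,
following the "more than" definition — while the stricter global set uses
*at least* `alt_hot_fold` (10) times — inclusive, following "at least".
Coldspots are windows below `mean/cold_fold`. The boundary semantics only
matter on measure-zero ties but are documented and tested.

Local calls (`rrr80()` + `call_local()`) work at 1 kb. RRR80 is the focal
window's rate over the mean of the 40 kb of windows on each side, focal
excluded. Near chromosome ends the statistic is computed when at least half
the full flank (40 of 80 windows) exists — enough support for a stable
mean — and is `NA` otherwise, as it is when the flank mean is 0 (a ratio to
zero is undefined, not infinite). Candidate hotspot windows need
`RRR80 >= 5` (a flag switches to strict `>`; the difference is measure-zero),
a rate between 1 and 10 cM/Mb (LD inference has poor power outside that
band), and at most 500 bp of annotated repeats (spurious rate peaks
concentrate in repeats). Only runs of at least two consecutive candidates
are called, and both window-level and merged-run-level sets are returned.

`element_profile()` generalises RRR80 into a distance profile: for windows
containing a TSS, or fully spanned by a CpG island, the rates at offsets up
to ±40 kb are divided by the element's own flank mean and averaged over
elements. In species without PRDM9, crossovers concentrate at accessible
chromatin, so a peak at offset 0 is the expected signature.

## Population comparison

`multiscale_correlation()` correlates `log10(cm_per_mb + 1e-6)` between
populations over identical window grids. The log transform reflects the
heavy-tailed rate distribution; the pseudocount (1e-6 cM/Mb, far below any
estimable rate) keeps zero-rate windows finite and is documented rather
than hidden. `hotspot_sharing()` evaluates each population's mean relative
rate at another population's hotspot windows, and `sharing_envelope()`
classifies a population as different when its offset-0 value falls outside
the min–max of the pseudoreplicate curves. With a handful of replicates a
min–max envelope is an honest heuristic; it is not a formal test and is
labelled as such.

## The synthetic generator

`sim_params()` + `simulate_landscape()` + `simulate_meioses()` +
`simulate_diversity()` + `perturb_track()` generate every input the
pipeline consumes, with recorded ground truth. Defaults sketch an
avian-like genome: 8 linkage groups of 5–90 Mb; log-normal background rates
drawn per 100 kb segment (`meanlog = log(1.6e-8)`, `sdlog = 0.6`, i.e.
~2 cM/Mb on average with several-fold segment-to-segment variation); 2 kb
hotspots at 0.5/Mb multiplying the local background 10–50×, 80% of them
centred on a TSS or CpG island; ~10 genes and CpG islands per Mb and 10%
repeats; diversity following
`log(pi) = a + b*log(rate) + noise` on 10 kb windows, giving pi near 0.004
at the average rate. Where no external constraint fixed a value, it was set
once at the start to a magnitude a population geneticist would call
realistic, and is documented here rather than tuned.

Crossovers are drawn per meiosis, sex and LG: one obligate CO (plus
Poisson extras at `extra_co_rate` per Morgan) placed according to a per-sex
mixture of a symmetric U-shaped Beta(0.5, 0.5) telomere-biased density and
a uniform density, multiplied by the truth track and renormalised — so the
pedigree COs and the LD landscape describe the same underlying landscape,
as the two real data types do. The default mixture weights (0.6 male, 0.3
female) are illustrative: they produce end-loaded placement and a
detectable between-sex difference, but are not calibrated to any particular
species. Replicate noise is multiplicative log-normal per 10 kb block,
mimicking locally correlated estimation error.

Deliberate simplifications, and what they imply about test coverage:

* **No crossover interference**: extra COs are independent, so map
  variances are slightly larger than in real meioses; nothing downstream
  consumes interference.
* **Hotspot starts are aligned to 1 kb boundaries**, matching the analysis
  grid. Real hotspots straddle window boundaries, which dilutes single-window
  rates; recovery statistics on synthetic data are therefore an upper bound
  on real-data sensitivity.
* **No coalescent noise model**: replicate noise is i.i.d. log-normal per
  block, not genealogy-driven, so it has no long-range correlation
  structure.
* **No genotype or VCF emission**: diversity is summarised as
  allele-frequency tables; genotype-level missingness and error are out of
  scope.

Passing recovery tests therefore demonstrate correctness of the estimators
under the stated generative model, not robustness to every artefact of real
sequencing data.

## Mappability

`exact_mappability_mask()` reimplements short-read mappability as exact
string matching: every 150-mer (one per bp) is looked up in the genome on
both strands via canonical k-mer counting, and 150 bp blocks where fewer
than 90% of overlapping reads are unique are masked. Exact counting is
deterministic, dependency-free and equivalent to aligner-based remapping
for synthetic genomes without sequencing error; reads containing ambiguous
bases are conservatively treated as never unique. The mask is invariant
under reverse-complementing the genome (tested), and nucleotide diversity
estimates are corrected by the unmasked denominator, with fully masked
windows flagged `NA` rather than reported as 0.

## Numerical conventions and degenerate inputs

* Haldane round-trips are exact to 12 digits over `p in [0, 0.49]`.
* Pseudomarker interpolation matches the direct formula to 1e-9 cM.
* Diversity uses the unbiased `2n/(2n-1)` heterozygosity correction.
* Ratios with zero denominators (female shuffling 0, zero flank mean, zero
  LD length against positive linkage length) are flagged or raised as
  errors, never silently coerced.
* Every generator is deterministic under `seed`; pseudoreplicate `i` uses
  `seed + i`.

## Problem sizes

The test suite exercises the pipeline at sizes chosen to make the
statistics sharp while keeping the suite quick to run: 10–50 Mb genomes for
landscape operations, 10⁴ meioses for map-recovery and obligate-CO checks
(binomial error ~0.5 cM on a 50 cM map), ~100 planted hotspots for
sensitivity/FDR estimates, and pseudomarker grids up to 5×10⁵ points for
the closed-form shuffling checks. These are the package's own choices of
precision, stated here so the tolerances in the tests can be read against
them.

## The interface

Functions take a data frame first and return tibbles, so stages chain with
the pipe: simulate (or read) → `build_map()` → `trim_map_ends()` →
`r_intra()` / `windows_from_track()` → `scale_to_linkage()` →
`lorenz_gini()` / `call_global()` / `rrr80()` / `call_local()` →
`multiscale_correlation()` / `hotspot_sharing()`. Fitted and composite
results (`length_regression()`, `lorenz_gini()`) provide `tidy()` and
`glance()`/`print()` methods, and each result type has a `plot_*()`
function returning a ggplot. File exchange uses the field's plain-text
formats: BED, FASTA, and 4-column rate-track TSV.
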