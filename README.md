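# recland

Sex-specific genetic maps and fine-scale recombination landscapes in R.

`recland` is for population and evolutionary geneticists who have two
complementary views of meiotic recombination in a species — crossover (CO)
events segregating in a pedigree, and per-bp population recombination rate
tracks inferred from linkage disequilibrium (LD) — and want to turn them into
a coherent, multi-scale description of the recombination landscape:
sex-specific linkage maps, allele-shuffling statistics, windowed cM/Mb maps,
landscape-inequality summaries, hotspot/coldspot annotation, and
cross-population comparisons. A first-class synthetic-data generator emulates
every input with known ground truth, so each stage of the pipeline is
testable end to end.

## The statistics at the core

* **Map building from segregation.** For adjacent markers, the recombination
  fraction is `c = (# meioses with an odd number of COs in the interval) / n`;
  interval distance is `100·c` cM or Haldane's `d = -50·ln(1 - 2c)`.
  Odd-counting means double COs within one interval cancel, matching what
  segregation data can detect. Because one obligate bivalent CO is
  transmitted to a gamete with probability 1/2, a chromosome with exactly one
  obligate CO per meiosis yields a ~50 cM map.
* **Pseudomarkers and intrachromosomal shuffling.** Maps are resampled at
  equidistant (default 10 kb) pseudomarkers by linear interpolation
  `D_b = [(s_{a+1} - s_b)·D_a + (s_b - s_a)·D_{a+1}] / (s_{a+1} - s_a)`.
  The shuffling rate of LG *k* is the mean over pseudomarker pairs of their
  map separation (as Haldane probabilities, or Morgans), weighted by
  `w_k = (L_k / ΣL)²`; summing over LGs gives `r̄_intra`, the probability
  that a random same-chromosome locus pair is shuffled by crossing over.
* **Windowed landscapes.** Each rate-track interval contributes
  `d = -50·ln(1 - 2·r·len)` cM, distributed pro rata by bp into 1 kb – 1 Mb
  windows, so window maps are exactly additive across scales. LD-derived
  lengths (confounded by `4·N_e`) are rescaled per LG to match the linkage
  map.
* **Inequality and hotspots.** Lorenz curves over windows ordered by
  decreasing rate give per-LG and genome-wide Gini coefficients. Broad-scale
  hotspots/coldspots are windows beyond fold thresholds of the genome-mean
  rate; local hotspots are runs of ≥ 2 consecutive 1 kb windows with
  `RRR80 ≥ 5` (rate over the mean of 40 kb each side), rate within
  1–10 cM/Mb and ≤ 500 bp of repeats. Profiles of RRR80 around TSSs and CpG
  islands quantify the concentration of recombination at accessible
  chromatin in PRDM9-lacking species.
* **Population comparison.** Pairwise correlations of `log10(rate + ε)` at
  several window sizes, subsampling pseudoreplicates as a noise envelope,
  and hotspot-sharing curves (mean relative rate of other populations at one
  population's hotspot windows).

## Worked example

```r
library(recland)
library(dplyr)

lay    <- genome_layout(c("lg1", "lg2", "lg3"), c(40e6, 20e6, 8e6))
params <- sim_params(seed = 1, layout = lay, n_meioses_per_sex = 2000,
                     hotspot_density = 2)
truth  <- simulate_landscape(params)
#> Synthetic landscape: 3 LGs, 68.0 Mb, 129 planted hotspots (seed 1)

cos <- simulate_meioses(truth, params)   # 7,476 observed crossovers
mk  <- bind_rows(lapply(1:3, \(i) tibble::tibble(
  lg = lay$lg[i], pos = round(seq(0, lay$length_bp[i], length.out = 200)))))
map <- build_map(cos, mk, n_meioses = c(M = 2000, F = 2000)) |>
  trim_map_ends()
map |> group_by(lg) |>
  summarise(male = max(cm_male), female = max(cm_female), avg = max(cm_avg))
#>   lg     male female   avg
#> 1 lg1    71     72.6  71.8
#> 2 lg2    62.8   59.8  61.3
#> 3 lg3    55.2   52.0  53.6
```

Every LG exceeds 50 cM, the floor set by the obligate crossover; the excess
grows with physical length. Shuffling and landscape summaries:

```r
ri <- r_intra(map, lay)
shuffling_total(ri)      # r_intra_total: avg 0.0689, female 0.0709, male 0.0669
shuffling_ratio(ri)      # male/female per LG: 0.93, 0.98, 1.00

w10k <- windows_from_track(truth$track, lay, 10000) |> scale_to_linkage(map)
lorenz_gini(w10k)
#> Lorenz/Gini summary over 3 linkage groups; pooled Gini 0.458
genome_mean_rate(w10k, lay)
#> [1] 2.746 (cM/Mb)
call_global(w10k, genome_mean_rate(w10k, lay)) |> count(kind)
#>   kind                   n
#> 1 coldspot             266
#> 2 global_hotspot_10x    19
#> 3 hotspot               88
```

Here about 1.3% of 10 kb windows exceed five times the genome-average rate
(`hotspot`), and the pooled Gini of 0.46 says recombination is moderately
concentrated: ~50% of the sequence carries 80% of the genetic length
(`frac_seq_80` in `tidy(lorenz_gini(w10k))`). Plot helpers
(`plot_lorenz()`, `plot_placement_density()`, `plot_sharing()`, ...) return
ggplots for each result type.

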