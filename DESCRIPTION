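Package: recland
Title: Sex-Specific Genetic Maps and Fine-Scale Recombination Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing meiotic recombination landscapes in species
    with pedigree and population sequencing data. Builds sex-specific genetic
    maps from crossover segregation events, trims unreliable map ends,
    interpolates equidistant pseudomarkers, and quantifies intrachromosomal
    allele shuffling with squared-length weighting. Converts per-basepair
    population (LD-based) recombination rate tracks into multi-scale windowed
    centimorgan maps via Haldane's mapping function, scales them to linkage
    maps per chromosome, and summarises landscape inequality with Lorenz
    curves and Gini coefficients. Annotates recombination hotspots and
    coldspots at broad (genome-mean fold) and local (relative rate in 80 kb,
    RRR80) scales, profiles recombination around transcription start sites
    and CpG islands, and compares landscapes across populations with
    multi-scale correlations, subsampling pseudoreplicates and
    hotspot-sharing curves. Includes a synthetic-data generator that emulates
    pedigree crossovers, piecewise-constant rate tracks with planted
    hotspots, diversity covariates and noisy population replicates, with
    ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
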