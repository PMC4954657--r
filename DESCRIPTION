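Package: nilmap
Title: Backcross Introgression Mapping and Variance Partitioning of
    Genotype-Environment Interaction in Yeast Crosses
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of a recurrent-backcross-with-selection
    quantitative genetics design in budding yeast. Provides a forward
    simulator of a biparental haploid cross (Poisson-crossover meiosis under
    the Haldane map function, phenotypic selection over backcross
    generations, condition-dependent locus effects, sequencing-read and
    plate-image observation models); a two-state hidden Markov model
    genotyper that calls parental origin from low-coverage per-SNP allele
    counts and extracts introgression segments, with aneuploidy and
    replicate-line screens; recurrence- and enrichment-based mapping of
    contributing loci using Fisher's exact tests and candidate-interval
    refinement; colony growth quantification from plate images by
    circular-ROI pixel intensity with background correction; and
    full-factorial sequential sums-of-squares ANOVA with per-term percent
    variance explained, genetic variance summaries, allele-dosage
    regressions, and cross-environment effect profiles.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
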