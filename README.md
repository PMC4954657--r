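# nilmap

Backcross introgression mapping and variance partitioning of a
genotype–environment interaction (GxE) in a budding-yeast cross.

Certain haploid segregants of a lab × clinical yeast cross grow very poorly
only when both carbon source and temperature are perturbed (ethanol at
37 °C, "E37"), while growing normally on glucose at 30 °C. `nilmap`
implements the complete genetic strategy for dissecting such a phenotype,
together with a calibrated synthetic-data generator standing in for the
wet-lab data sources:

- **Breeding simulation** — Poisson-crossover meiosis (Haldane map
  function) over a 16-chromosome yeast-like map with ~60,000 SNPs;
  recurrent backcrossing with phenotypic selection that concentrates
  stress-sensitive alleles as introgressions in nearly isogenic lines
  (NILs); condition-dependent additive phenotypes
  `y = μ_c − s_c Σ_ℓ β_ℓ [g_ℓ = 0] + N(0, σ_c²)` whose effects and severity
  multipliers are calibrated in closed form to the published E37 variance
  structure.
- **Introgression genotyping** — a two-state hidden Markov model decodes
  parental origin per chromosome from low-coverage per-SNP allele counts
  (Viterbi or posterior, log-space), extracts segment sets, and screens
  strains for aneuploidy (1.5× coverage rule) and replicated lineages
  (Jaccard overlap of introgressed bp).
- **Locus mapping** — recurrence of introgressed regions across
  independent NILs; allelic enrichment of selected poor growers versus
  random controls with a hypergeometric-mass Fisher's exact test at the
  maximally enriched site per locus; candidate-interval refinement by
  segment intersection.
- **Variance partitioning** — full-factorial sequential (Type I) ANOVA of
  growth on four locus genotypes per environment, per-term percent variance
  explained (PVE), genetic/additive summaries (R²_G, R²_A), allele-dosage
  regression, and the cross-environment additive effect profile
  (G30 < G37 < E30 < E37).
- **Colony quantification** — circular-ROI pixel intensity (radius 50 px,
  7845-pixel mask) with annulus background correction, plus a plate-image
  renderer that makes the render/measure round trip an exact oracle.

## Worked example

Simulate a panel of 192 final-round backcross segregants from a reference
NIL, phenotype them in the severe condition, and partition the variance:

```r
library(nilmap)
map   <- yeast_map()
model <- calibrate_phenotype_model(map)   # published-calibrated defaults

set.seed(1)
yjm  <- parental_genotype(map, 1L)
nil3 <- synthetic_nil_genotype(map)       # reference NIL with 8 introgressions
pop  <- simulate_f2b7_population(nil3, yjm, 192, map)

ids <- map$snp$id[vapply(1:4, function(i)
  snp_index(map, model$loci$chrom[i], model$loci$pos[i]), 1L)]
G <- pop$genotypes[, ids]; colnames(G) <- model$loci$name
y <- simulate_phenotype_at_loci(G, "E37", model)

tab <- full_factorial_anova(y, G)
tab
#>                 term  df  sumsq meansq  fvalue    pvalue  pve
#>                  L_I   1 3969.7 3969.7 117.034 3.095e-21 13.5
#>                L_VII   1 9768.0 9768.0 287.981 6.820e-39 33.2
#>                 L_X1   1  856.0  856.0  25.235 1.239e-06  2.9
#>                 L_X2   1 8614.2 8614.2 253.964 5.679e-36 29.2
#>            L_I:L_VII   1    3.2    3.2   0.093 7.607e-01  0.0
#>  ...                                                      ...
#>            Residuals 176 5969.8   33.9      NA        NA 20.3

genetic_variance_summary(tab)
#> R2_G = 79.7%, additive share = 98.8%
```

The four configured causal loci explain most of the variance, almost
entirely additively: the estimated per-locus PVEs scatter around the
calibration targets (11.1, 32.4, 7.0, 24.7%), and the genetic variance
(R²_G ≈ 80%) matches the regime the model was calibrated to. Repeating the
phenotype in the milder conditions (`"G30"`, `"G37"`, `"E30"`) and passing
the tables to `condition_effect_profile()` recovers the increasing severity
profile.

`run_demo(demo_config(seed = 1), out_dir)` chains the whole pipeline —
breeding, sequencing + HMM genotyping, recurrence mapping, the 864-strain
selection screen with Fisher enrichment (all four causal loci recovered,
no null locus), interval refinement, and per-condition ANOVA — writing
provenance-stamped TSV/BED/JSON outputs that are byte-identical across runs
with the same seed.

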