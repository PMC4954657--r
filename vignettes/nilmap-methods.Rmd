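---
title: "Methods: simulating and dissecting a genotype-environment interaction in a yeast cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and dissecting a genotype-environment interaction in a yeast cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nilmap)
```

# The problem

Some haploid segregants of a cross between a laboratory yeast strain and a
clinical isolate grow very poorly, but only when the environment is doubly
perturbed — ethanol as the carbon source *and* 37 °C ("E37"). `nilmap`
implements, end to end, the genetic strategy for dissecting such a
genotype-environment interaction (GxE):

1. **Breed nearly isogenic lines (NILs)** by recurrent backcrossing with
   phenotypic selection, so that the alleles responsible for poor growth are
   concentrated as small introgressions in the other parent's background.
2. **Genotype the NILs** from low-coverage sequencing summaries with a
   two-state hidden Markov model (HMM), screening for aneuploid and
   replicated lines.
3. **Map contributing loci** by recurrence across independent lineages and
   by allelic enrichment among phenotypically selected segregants versus
   random controls (Fisher's exact tests), refining loci to candidate
   intervals.
4. **Partition phenotypic variance** per environment with full-factorial
   sequential-sums-of-squares ANOVA, summarising additive versus epistatic
   contributions and the cross-environment effect profile.

Because the underlying study's raw data exist only as supplementary
spreadsheets, the package ships a first-class synthetic-data generator whose
defaults encode the study design itself; every analysis component is tested
against that generator and against independent oracles.

# The generative model

## Genome and meiosis

The default map (`yeast_map()`) has 16 chromosomes with physical lengths
from the S288c karyotype rounded to 10 kb, a uniform recombination rate of
0.4 cM/kb (the yeast genome-wide average), and one biparental SNP per 200 bp
— 60,350 SNPs, approximating the ~57,000 high-confidence SNPs that
distinguish the two parents. Alleles are coded 0 for the lab-strain (BY-type)
parent and 1 for the clinical (YJM-type) parent throughout.

`meiosis()` draws, per chromosome, a Poisson number of crossovers with mean
`length_cM / 100`, places them uniformly on the genetic map, and alternates
parental origin from a random starting phase. This is the Haldane
(no-interference) model, chosen for analytic testability: the recombinant
fraction between two markers `d` cM apart is `(1 - exp(-2d/100))/2`, which
the tests check directly. Crossover interference is a known omission.

## Phenotypes

Growth (in pixel-intensity units, matching plate-image quantification) of a
segregant in condition $c$ is

$$y = \mu_c - s_c \sum_\ell \beta_\ell\,[g_\ell = 0] + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma_c^2),$$

with optional severity-scaled epistatic products (zero by default, since the
published interaction terms each explain at most ~2% of variance). The
essential biology is in the severity multipliers $s_c$: the same
stress-sensitive alleles are nearly silent under permissive conditions and
strongly deleterious when carbon source and temperature are both perturbed,
which is what turns many individually modest gene-environment interactions
into one large genotype-environment interaction.

`calibrate_phenotype_model()` solves the model's closed form so that, in a
population with allele frequency 1/2 at each causal locus:

* per-locus expected PVE in E37 equals the published decomposition
  (11.1, 32.4, 7.0, 24.7% for the chromosome I, VII, X1 and X2 loci), with
  residual SD $\sigma = \sqrt{35}$ (the published residual mean square) and
  $s_{E37} = 1$;
* the mean additive PVE per condition equals the published profile
  (0.48, 5.4, 9.2, 18.8% in G30, G37, E30, E37), giving severities
  ($\approx$ 0.080, 0.301, 0.438, 1).

Given targets $p_\ell$, total variance is $V = \sigma^2/(1-\sum p_\ell)$ and
$\beta_\ell = 2\sqrt{p_\ell V}$; severities follow from the analogous
per-condition identity. `expected_pve()` exposes the closed form, and a test
verifies the calibration reproduces its targets to numerical precision.
Baselines (150, 120, 100, 80) encode the observed ordering of average growth
across conditions; they affect no variance quantity.

The calibrated $\sigma_c$ is the residual SD of the *analysed* phenotype,
i.e. the per-strain median of five replicate measurements. Where the demo
pipeline simulates individual replicates it therefore inflates per-replicate
noise by $1/\sqrt{0.2868}$ (the variance factor of the median of five
normals), so that medians land on the calibrated scale.

## Breeding design

`cross_program()` defaults are the study design: 112 F2 segregants screened,
at least 576 progeny per backcross, six backcross rounds, seven lineages per
recurrent parent, and selection of the poorest ~5% of growers in E37
(45/864 ≈ 5.2% in the published screen). The published account does not say
how the single F2 progenitor was picked among the five poor growers; the
simulator selects the poorest eligible individual (configurable). Selection
keeps a running pool of the poorest progeny, so memory stays flat in the
progeny count. Each NIL records its true introgression segments — the SNP
runs where it differs from the recurrent parent — as ground truth for the
genotyper.

One asymmetry of the additive model is worth stating: because only
sensitive (type-0) alleles lower growth, backcrossing into the type-0
background cannot be driven by phenotype, and type-0-background NILs carry
only drift introgressions. The real system shows background-dependent
effects that a strictly additive model cannot express; the analysis chain is
unaffected, since mapping operates on the segment sets themselves.

## Observation models

Sequencing is summarised per SNP as `reads_total ~ Poisson(depth)` and
`reads_A ~ Binomial(reads_total, 1 - e)` or `Binomial(reads_total, e)`
according to the true allele (`simulate_read_observations()`), with defaults
21X for NILs and 5X for segregant panels. `inject_aneuploidy()` rescales one
chromosome's depth by a copy ratio for testing the coverage screen. Plate
images render each colony as a Gaussian spot whose integrated intensity
equals its growth value on a noisy constant background (`render_plate()`),
making the render/measure round trip an exact linear oracle for the
quantification code.

# Analysis components and their numerical choices

## HMM genotyping

Two hidden states (parental origins), symmetric transitions with stay
probability 0.9999, uniform initial distribution, Viterbi decoding in log
space, per chromosome. The published parameterisation prints an emission
matrix of all 0.5, which is constant-likelihood and cannot produce
data-dependent genotypes; it is retained as `literal_uniform` for fidelity
experiments (it decodes to state 0 everywhere by tie-breaking). The default
`binarized_error` emission reduces each covered SNP to its majority allele,
emitted with error `epsilon = 0.05`; zero-coverage SNPs emit with probability
one from both states, preserving transition geometry rather than deleting
rows. Segment boundaries use the SNP-spanned convention (first to last SNP
of the run, 1-based inclusive): conservative and exactly round-trippable.
Ties in the Viterbi recursion break toward state 0; for exact score ties
reached along different floating-point accumulation orders either optimum
may be returned, so tests assert optimality against an enumeration oracle
rather than a specific path. Posterior (forward-backward) decoding is
available and agrees with Viterbi wherever the posterior is confident.

Aneuploidy is flagged when a chromosome's mean depth is ≥1.5× or ≤1/1.5× the
genome mean; replicated lineages are flagged at Jaccard overlap ≥0.9 of
introgressed base pairs.

## Locus mapping

`count_region_overlaps()` partitions the genome at all segment endpoints,
counts carriers per atomic interval, and merges adjacent intervals with
identical carrier sets; a conservation identity (sum of count × width equals
total introgressed width) and a per-bp brute-force oracle guard it.
Regions carried by ≥2 independent NILs are called loci, excluding windows
around the *MAT* and *CAN1* selection markers, whose retention reflects the
breeding protocol.

`fisher_exact_2x2()` is computed from the hypergeometric mass directly; the
two-sided p sums all tables with point probability not exceeding the
observed one (minimum-likelihood convention, matching the standard
statistical environments), with the sample odds ratio `ad/bc`. Enrichment at
a locus is reported at the SNP with minimal p (ties to the smallest
position), uncorrected for multiple testing — both choices mirror the
published analysis; a one-sided option exists. Interval refinement
intersects the sensitive-allele segments of selected segregants within the
locus; the exact rule used to delimit the published candidate intervals is
not described, so this intersection rule is the package's documented choice.
An empty intersection is treated as a phenotype/genotype inconsistency and
raises an error; the demo pipeline intersects over the strains that carry
the allele at the causal position, because under an additive architecture a
strain can be in the selected tail without carrying every sensitive allele.

## Variance partitioning

`full_factorial_anova()` fits `y ~ g1 * g2 * g3 * g4` and decomposes
variance with sequential (Type I) sums of squares in R-formula expansion
order — main effects in locus order, then interactions by degree — which is
the order of the published table and is required to reproduce its numbers on
unbalanced data. Type II/III decompositions are out of scope. PVE is a
term's SS over the total SS; $R^2_G$ sums all genetic terms, $R^2_A$ the
main effects. A test verifies that term order genuinely changes per-term SS
on confounded designs while conserving the total, and that PVE is invariant
to affine phenotype transforms. The allele-dosage regression
(`equal_effects_fit()`) uses the four mapped loci by default; the published
figure caption mentions five (including the chromosome XVI locus), so any
locus set can be supplied.

## Colony quantification

Circular-ROI total intensity at radius 50 px (7845 lattice pixels — exactly
the published divisor), background-corrected by the mean of a surrounding
10 px annulus from which other colonies' ROIs are excluded. The default
divides by the actual mask area; a compatibility flag forces the fixed
divisor 7845. Negative corrected averages are clamped to zero and flagged.
Saturated-pixel handling in the original imaging is unspecified and is not
corrected.

# Pipeline, scale and reproducibility

`run_demo()` chains breed → genotype → map → screen → enrich → refine →
anova on one seeded RNG stream and writes provenance-stamped outputs (tool
version, seed, configuration fingerprint); two runs with one seed are
byte-identical. The demo keeps the study-scale segregant numbers (864
screened, 45 selected, 192 controls, 5 replicates) but reduces the breeding
program to 3 lineages per parent and 96 progeny per round so the whole chain
runs in about half a minute; the full program defaults remain available on
`cross_program()`. The demo phenotypes strains directly from the model
rather than through rendered images; image quantification is validated
separately by the render/measure round trip. Intermediate writers/readers
(BED with 1-based-inclusive to 0-based-half-open conversion, TSV genotype
and observation tables, YAML configs) exist for all artefacts, but stages
within one run communicate in memory.

Test problem sizes are chosen to keep the routine suite fast: toy maps of a
few hundred SNPs wherever genome scale is irrelevant, the full default map
where calibration is the point (PVE recovery over 50 panels of 192, profile
ordering over panels seeded 1–20, 100 seeded enrichment screens of 864+192).

# What the synthetic data do and do not establish

The generator emulates the breeding design, linkage, condition-dependent
additive effects calibrated to the published variance structure, sequencing
noise and plate images. It does not emulate: crossover interference;
background-dependent (epistatic) allele effects, including any threshold
character of the real poor-growth phenotype; diploid-phase biology,
sporulation efficiency or mating-type genetics beyond marker bookkeeping;
read-level artefacts (mapping bias, duplicates); or plate spatial effects.
Consequently, passing tests show that the analysis chain recovers the
parameters of this generative model at the study's sample sizes — they do
not show that the real phenotype is additive, and they reproduce the
published enrichment p-values only in order of magnitude: under the
calibrated additive model the selected tail is a genotype mixture, so
exact-test power at the weakest locus is necessarily below what the
published, sharper phenotype yielded. The package reports this honestly
rather than sharpening the generator beyond its calibration.
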