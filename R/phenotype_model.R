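#' Condition-dependent additive phenotype model
#'
#' Generative model for colony growth (in pixel-intensity units) of a haploid
#' segregant across environments. Each causal locus carries a base effect
#' `beta` that is expressed when the strain carries the stress-sensitive
#' allele (allele 0, the lab-strain type), scaled by a per-condition severity
#' multiplier; Gaussian noise is added on top of a per-condition baseline:
#'
#' \deqn{y = baseline_c - s_c \sum_l \beta_l [g_l = 0] + s_c \sum_k
#'   \gamma_k \prod_{l \in k} [g_l = 0] + N(0, \sigma_c^2)}
#'
#' The severity multipliers encode the core biology being modelled: locus
#' effect magnitudes grow with the severity of the environmental
#' perturbation, so the same alleles that are nearly silent under permissive
#' conditions produce very poor growth when both carbon source and
#' temperature are stressful.
#'
#' @param baseline named numeric, mean growth per condition for a strain
#'   carrying no sensitive alleles.
#' @param loci data.frame with columns `name`, `chrom`, `pos`, `beta`
#'   (`beta >= 0`; allele 0 at the locus lowers growth).
#' @param severity named numeric `>= 0`, one multiplier per condition, same
#'   names as `baseline`.
#' @param noise_sd named numeric `> 0`, residual SD per condition.
#' @param epistasis optional list of interaction terms, each a list with
#'   elements `loci` (2+ locus names) and `coef` (a single numeric, applied
#'   on the severity scale like the main effects).
#' @return An object of class `phenotype_model`.
#' @seealso [calibrate_phenotype_model()] for the shipped default
#'   calibration, [simulate_phenotype()] to draw phenotypes.
#' @export
phenotype_model <- function(baseline, loci, severity, noise_sd,
                            epistasis = NULL) {
  conds <- names(baseline)
  stopifnot(!is.null(conds), length(conds) >= 1,
            identical(sort(conds), sort(names(severity))),
            identical(sort(conds), sort(names(noise_sd))))
  if (any(severity < 0)) stop("severity multipliers must be >= 0")
  if (any(noise_sd < 0)) stop("noise SDs must be >= 0")
  stopifnot(is.data.frame(loci),
            all(c("name", "chrom", "pos", "beta") %in% names(loci)))
  if (!is.null(epistasis)) {
    for (e in epistasis) {
      stopifnot(length(e$loci) >= 2, all(e$loci %in% loci$name),
                is.numeric(e$coef), length(e$coef) == 1)
    }
  }
  structure(list(baseline = baseline, loci = loci,
                 severity = severity[conds], noise_sd = noise_sd[conds],
                 epistasis = epistasis, conditions = conds),
            class = "phenotype_model")
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat("phenotype_model:", nrow(x$loci), "causal loci,",
      length(x$conditions), "conditions\n")
  cat("  loci:", paste0(x$loci$name, " (beta=", signif(x$loci$beta, 4), ")",
                        collapse = ", "), "\n")
  cat("  severity:", paste0(x$conditions, "=",
                            signif(x$severity, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Calibrate the default phenotype model from target variance fractions
#'
#' Solves the model's closed form for locus base effects and severity
#' multipliers so that, in a balanced backcross population (allele frequency
#' 1/2 at every causal locus, linkage ignored), the expected per-locus
#' percent variance explained (PVE) in the most severe condition and the
#' expected mean additive PVE in every condition hit the requested targets.
#'
#' With severity fixed at 1 in the reference condition, total phenotypic
#' variance there is \eqn{V = \sigma^2 / (1 - \sum_l pve_l)}, locus effects
#' are \eqn{\beta_l = 2\sqrt{pve_l V}}, and for any other condition with
#' mean additive PVE target \eqn{m_c} over L loci the severity is
#' \eqn{s_c^2 = L m_c \sigma_c^2 / (A (1 - L m_c))} where
#' \eqn{A = \sum_l \beta_l^2 / 4}.
#'
#' The default targets are per-locus E37 PVEs of 11.1, 32.4, 7.0 and 24.7
#' percent for L_I, L_VII, L_X1 and L_X2, mean additive PVEs of 0.48, 5.4,
#' 9.2 and 18.8 percent in G30, G37, E30 and E37, and residual SD
#' `sqrt(35)` in every condition.
#'
#' @param map a [genetic_map()] whose `role == "causal"` loci (in map order)
#'   receive the per-locus targets.
#' @param pve_reference per-locus PVE targets (fractions) in the reference
#'   condition, in causal-locus order.
#' @param mean_additive_pve named per-condition targets (fractions) for the
#'   mean additive PVE; the last condition is the reference and must equal
#'   `mean(pve_reference)`.
#' @param sigma residual SD, recycled over conditions.
#' @param baseline named per-condition baseline growth.
#' @param epistasis optional epistasis terms passed through.
#' @return A [phenotype_model()].
#' @export
calibrate_phenotype_model <- function(
    map = yeast_map(),
    pve_reference = c(0.111, 0.324, 0.070, 0.247),
    mean_additive_pve = c(G30 = 0.0048, G37 = 0.054, E30 = 0.092,
                          E37 = 0.188),
    sigma = sqrt(35),
    baseline = c(G30 = 150, G37 = 120, E30 = 100, E37 = 80),
    epistasis = NULL) {
  causal <- map$loci[map$loci$role == "causal", , drop = FALSE]
  L <- nrow(causal)
  stopifnot(L == length(pve_reference), sum(pve_reference) < 1)
  conds <- names(mean_additive_pve)
  ref <- conds[length(conds)]
  if (abs(mean(pve_reference) - mean_additive_pve[[ref]]) > 1e-6)
    stop("reference-condition mean additive PVE must equal mean(pve_reference)")
  sigma <- rep_len(sigma, length(conds))
  names(sigma) <- conds

  v_total <- sigma[[ref]]^2 / (1 - sum(pve_reference))
  beta <- 2 * sqrt(pve_reference * v_total)
  A <- sum(beta^2) / 4
  m <- unlist(mean_additive_pve)
  if (any(L * m >= 1)) stop("mean additive PVE targets too large")
  severity <- sqrt(L * m * sigma^2 / (A * (1 - L * m)))

  loci <- data.frame(name = causal$name, chrom = causal$chrom,
                     pos = causal$pos, beta = beta,
                     stringsAsFactors = FALSE)
  phenotype_model(baseline = baseline[conds], loci = loci,
                  severity = severity, noise_sd = sigma,
                  epistasis = epistasis)
}

#' Expected per-locus percent variance explained under the model
#'
#' Closed-form expectation in a population with independent allele frequency
#' 1/2 at every causal locus and no epistatic variance: locus variance is
#' \eqn{s_c^2 \beta_l^2 / 4} and total variance is the sum over loci plus
#' \eqn{\sigma_c^2}.
#'
#' @param model a [phenotype_model()].
#' @param condition condition name.
#' @return Named numeric vector of per-locus PVEs in percent, with attribute
#'   `"total"` giving total expected additive PVE (percent).
#' @export
expected_pve <- function(model, condition) {
  s <- severity_of(model, condition)
  sd <- model$noise_sd[[condition]]
  v_loc <- s^2 * model$loci$beta^2 / 4
  v_tot <- sum(v_loc) + sd^2
  out <- 100 * v_loc / v_tot
  names(out) <- model$loci$name
  attr(out, "total") <- sum(out)
  out
}

severity_of <- function(model, condition) {
  if (!condition %in% model$conditions)
    stop("unknown condition: ", condition)
  model$severity[[condition]]
}

#' Extract causal-locus genotypes from full haploid genotypes
#'
#' @param g a haploid genotype vector over all SNPs of `map`, or a matrix
#'   with one row per individual.
#' @param model a [phenotype_model()].
#' @param map the [genetic_map()] `g` is defined on.
#' @return Matrix (individuals x loci) of 0/1 alleles, columns named by
#'   locus.
#' @export
locus_genotypes <- function(g, model, map) {
  idx <- locus_snp_indices(map, model$loci)
  if (anyNA(idx)) stop("model loci must map to SNPs in the map")
  if (is.matrix(g)) G <- g[, idx, drop = FALSE]
  else G <- matrix(g[idx], nrow = 1)
  colnames(G) <- model$loci$name
  G
}

#' Simulate growth phenotypes
#'
#' Draws growth values under the phenotype model: baseline minus
#' severity-scaled effects of the sensitive (allele 0) causal alleles, plus
#' severity-scaled epistatic terms and Gaussian noise. Uses the R session
#' RNG; seed with [set.seed()] for reproducibility.
#'
#' @param g haploid genotype vector over all SNPs of `map` (or matrix, one
#'   row per individual).
#' @param condition condition name.
#' @param model a [phenotype_model()].
#' @param map the [genetic_map()] `g` is defined on.
#' @return Numeric vector of growth values, one per individual.
#' @export
simulate_phenotype <- function(g, condition, model, map) {
  simulate_phenotype_at_loci(locus_genotypes(g, model, map),
                             condition, model)
}

#' Simulate growth phenotypes from causal-locus genotypes
#'
#' Same model as [simulate_phenotype()], taking the (individuals x loci)
#' causal-locus genotype matrix directly. Columns must be in `model$loci`
#' order.
#'
#' @param G matrix of 0/1 alleles, individuals x causal loci.
#' @param condition condition name.
#' @param model a [phenotype_model()].
#' @return Numeric vector of growth values.
#' @export
simulate_phenotype_at_loci <- function(G, condition, model) {
  if (is.null(dim(G))) G <- matrix(G, nrow = 1)
  stopifnot(ncol(G) == nrow(model$loci), all(G %in% c(0L, 1L)))
  s <- severity_of(model, condition)
  by_carrier <- G == 0L
  mu <- model$baseline[[condition]] -
    s * as.numeric(by_carrier %*% model$loci$beta)
  if (!is.null(model$epistasis)) {
    for (e in model$epistasis) {
      j <- match(e$loci, model$loci$name)
      mu <- mu + s * e$coef *
        apply(by_carrier[, j, drop = FALSE], 1, all)
    }
  }
  mu + stats::rnorm(nrow(G), 0, model$noise_sd[[condition]])
}
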