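#' Median growth per strain and condition
#'
#' Collapses replicate measurements to the per-strain median within each
#' condition (the median of an even number of replicates is the midpoint of
#' the central pair). The median is used for robustness to single aberrant
#' replicate measurements.
#'
#' @param measurements data.frame with columns `strain`, `replicate`,
#'   `condition`, `intensity`.
#' @return Wide data.frame: `strain` plus one `<condition>_med` column per
#'   condition, strains in order of first appearance.
#' @export
aggregate_replicates <- function(measurements) {
  need <- c("strain", "replicate", "condition", "intensity")
  stopifnot(all(need %in% names(measurements)))
  strains <- unique(measurements$strain)
  conds <- unique(measurements$condition)
  out <- data.frame(strain = strains, stringsAsFactors = FALSE)
  for (cn in conds) {
    m <- measurements[measurements$condition == cn, , drop = FALSE]
    med <- vapply(strains, function(s) {
      v <- m$intensity[m$strain == s]
      v <- v[!is.na(v)]
      if (length(v) == 0L)
        stop("no replicate measurements for strain ", s,
             " in condition ", cn)
      stats::median(v)
    }, numeric(1))
    out[[paste0(cn, "_med")]] <- unname(med)
  }
  out
}

#' Full-factorial sequential-SS ANOVA of growth on locus genotypes
#'
#' Fits the saturated linear model of phenotype on all main effects and
#' interactions of the binary locus genotypes (`y ~ g1 * g2 * ... * gL`)
#' and decomposes the variance with sequential (Type I) sums of squares:
#' terms enter in locus order, then interactions grouped by degree in
#' R-formula expansion order; each term's SS is the reduction in residual
#' SS when it is added. Because the design is in general unbalanced, the
#' decomposition depends on this term order, which is recorded in the
#' result. Per-term percent variance explained (PVE) is the term's SS over
#' the total (including residual) SS.
#'
#' @param phenotype numeric vector of per-strain growth (one condition).
#' @param genotypes 0/1 matrix or data.frame, strains x loci.
#' @param loci locus names (default: column names of `genotypes`).
#' @return An object of class `pve_anova`: a data.frame with columns
#'   `term`, `df`, `sumsq`, `meansq`, `fvalue`, `pvalue`, `pve`, ending
#'   with the `Residuals` row.
#' @export
full_factorial_anova <- function(phenotype, genotypes,
                                 loci = colnames(genotypes)) {
  G <- as.matrix(genotypes)
  stopifnot(length(phenotype) == nrow(G), all(G %in% c(0, 1)))
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(G)))
  for (j in seq_len(ncol(G))) {
    if (length(unique(G[, j])) < 2)
      stop("locus ", loci[j], " is monomorphic: its term cannot be fit")
  }
  if (length(phenotype) <= 2^ncol(G))
    stop("need more strains than model terms for a residual df")
  dat <- as.data.frame(G)
  vars <- paste0("g", seq_len(ncol(G)))
  names(dat) <- vars
  dat$y <- phenotype
  fml <- stats::as.formula(paste("y ~", paste(vars, collapse = " * ")))
  fit <- stats::lm(fml, data = dat)
  a <- stats::anova(fit)
  term <- rownames(a)
  for (j in seq_along(vars))  # map internal names back to locus names
    term <- gsub(paste0("\\b", vars[j], "\\b"), loci[j], term)
  tab <- data.frame(term = term, df = a$Df, sumsq = a$`Sum Sq`,
                    meansq = a$`Mean Sq`, fvalue = a$`F value`,
                    pvalue = a$`Pr(>F)`, stringsAsFactors = FALSE)
  tab$pve <- 100 * tab$sumsq / sum(tab$sumsq)
  structure(tab, class = c("pve_anova", "data.frame"),
            loci = loci, n = length(phenotype))
}

#' Build a PVE ANOVA table from printed df and sums of squares
#'
#' Reconstructs the derived columns (mean squares, F statistics against the
#' residual mean square, p-values, and PVE) from a published table's `Df`
#' and `Sum Sq` columns. The last term must be `Residuals`.
#'
#' @param terms character vector of term labels ending in `"Residuals"`.
#' @param df integer degrees of freedom per term.
#' @param sumsq sums of squares per term.
#' @return A `pve_anova` object.
#' @export
anova_table <- function(terms, df, sumsq) {
  stopifnot(length(terms) == length(df), length(df) == length(sumsq),
            terms[length(terms)] == "Residuals", all(df >= 1),
            all(sumsq >= 0))
  n <- length(terms)
  ms <- sumsq / df
  fv <- c(ms[-n] / ms[n], NA)
  pv <- c(stats::pf(fv[-n], df[-n], df[n], lower.tail = FALSE), NA)
  tab <- data.frame(term = terms, df = df, sumsq = sumsq, meansq = ms,
                    fvalue = fv, pvalue = pv,
                    pve = 100 * sumsq / sum(sumsq),
                    stringsAsFactors = FALSE)
  structure(tab, class = c("pve_anova", "data.frame"))
}

#' @export
print.pve_anova <- function(x, ...) {
  df <- as.data.frame(x)
  df$sumsq <- round(df$sumsq, 1)
  df$meansq <- round(df$meansq, 1)
  df$fvalue <- round(df$fvalue, 3)
  df$pvalue <- signif(df$pvalue, 4)
  df$pve <- round(df$pve, 1)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Percent variance explained per term
#'
#' Each term's sum of squares divided by the total sum of squares
#' (including the residual), in percent.
#'
#' @param table a `pve_anova` object (see [full_factorial_anova()] and
#'   [anova_table()]).
#' @return Named numeric vector of PVEs (percent), including `Residuals`.
#' @export
pve <- function(table) {
  tot <- sum(table$sumsq)
  if (tot <= 0) stop("total sum of squares is zero")
  stats::setNames(100 * table$sumsq / tot, table$term)
}

is_main_term <- function(term) !grepl(":", term) & term != "Residuals"

#' Genetic and additive variance summaries of a PVE ANOVA table
#'
#' @param table a `pve_anova` object.
#' @return List with `r2_g` (percent variance explained by all genetic
#'   terms), `r2_a` (by main effects only), `additive_share` and
#'   `epistatic_share` (percent of the genetic contribution).
#' @export
genetic_variance_summary <- function(table) {
  p <- pve(table)
  main <- is_main_term(table$term)
  genetic <- table$term != "Residuals"
  r2_g <- sum(p[genetic])
  if (r2_g <= 0) stop("no genetic variance: shares undefined")
  r2_a <- sum(p[main])
  list(r2_g = r2_g, r2_a = r2_a,
       additive_share = 100 * r2_a / r2_g,
       epistatic_share = 100 * (1 - r2_a / r2_g))
}

#' Cross-condition additive effect profile
#'
#' Mean main-effect PVE per condition, with the observed rank order of
#' conditions. Under the severity model the profile should increase with
#' environmental perturbation (e.g. G30 < G37 < E30 < E37).
#'
#' @param tables named list of `pve_anova` objects, one per condition, all
#'   fitted on the same loci.
#' @return List with `mean_additive_pve` (named numeric, percent),
#'   `ordering` (condition names sorted by increasing profile) and
#'   `monotone` (logical: is the profile strictly increasing in the order
#'   the conditions were supplied?).
#' @export
condition_effect_profile <- function(tables) {
  stopifnot(length(tables) >= 1, !is.null(names(tables)))
  main_terms <- lapply(tables, function(t) t$term[is_main_term(t$term)])
  if (!all(vapply(main_terms, identical, logical(1), main_terms[[1]])))
    stop("conditions were fitted on different loci")
  prof <- vapply(tables, function(t) {
    p <- pve(t)
    mean(p[is_main_term(t$term)])
  }, numeric(1))
  list(mean_additive_pve = prof,
       ordering = names(sort(prof)),
       monotone = !is.unsorted(prof, strictly = TRUE))
}

#' Equal-effects allele-dosage regression
#'
#' Ordinary least squares of phenotype on the number of type-1 alleles a
#' strain carries across the loci: the completely additive, equal-effect
#' null model of the multi-locus architecture.
#'
#' @param phenotype numeric vector of per-strain growth.
#' @param genotypes 0/1 matrix, strains x loci.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value` (overall
#'   model F-test) and `n`.
#' @export
equal_effects_fit <- function(phenotype, genotypes) {
  G <- as.matrix(genotypes)
  stopifnot(length(phenotype) == nrow(G))
  dose <- rowSums(G)
  if (length(unique(dose)) < 2)
    stop("allele-dosage predictor is constant")
  fit <- stats::lm(phenotype ~ dose)
  s <- summary(fit)
  fstat <- s$fstatistic
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                  lower.tail = FALSE)),
       n = length(phenotype))
}
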