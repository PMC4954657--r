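#' Simulate per-SNP sequencing read counts
#'
#' Observation model for low-coverage whole-genome sequencing summarised as
#' per-SNP allele counts: total reads at a SNP are Poisson with the target
#' mean depth, and reads supporting the type-0 ("A") allele are binomial
#' with success probability `1 - base_error` when the strain carries allele
#' 0 and `base_error` otherwise. Zero-depth SNPs are retained with
#' `reads_total = 0`.
#'
#' @param g haploid genotype vector over all SNPs of `map` (values 0/1).
#' @param map a [genetic_map()].
#' @param mean_depth mean per-site coverage (e.g. 21 for the NILs, 5 for
#'   segregant panels).
#' @param base_error per-read miscall probability in `[0, 0.5)`.
#' @return data.frame `chrom`, `pos`, `reads_A`, `reads_total` (a
#'   SNP-observation table).
#' @export
simulate_read_observations <- function(g, map, mean_depth,
                                       base_error = 0.002) {
  stopifnot(length(g) == n_snps(map), mean_depth > 0,
            base_error >= 0, base_error < 0.5)
  n <- n_snps(map)
  tot <- stats::rpois(n, mean_depth)
  p_a <- ifelse(g == 0L, 1 - base_error, base_error)
  data.frame(chrom = map$snp$chrom, pos = map$snp$pos,
             reads_A = stats::rbinom(n, tot, p_a), reads_total = tot,
             stringsAsFactors = FALSE)
}

#' Inject an aneuploidy into a SNP-observation table
#'
#' Rescales read depth on one chromosome by a copy ratio, re-drawing totals
#' from a Poisson at `copy_ratio` times the chromosome's empirical mean
#' depth and re-drawing allele counts at each SNP's observed allele
#' fraction. Fixture generator for the coverage-based aneuploidy screen.
#'
#' @param obs a SNP-observation table.
#' @param chrom chromosome to rescale.
#' @param copy_ratio positive depth multiplier (2 for a disome gain in a
#'   haploid, 0.5 for a loss in a disomic region, 1 leaves the
#'   distribution unchanged).
#' @return The modified observation table.
#' @export
inject_aneuploidy <- function(obs, chrom, copy_ratio) {
  stopifnot(copy_ratio > 0)
  sel <- obs$chrom == chrom
  if (!any(sel)) stop("unknown chromosome: ", chrom)
  lambda <- mean(obs$reads_total[sel]) * copy_ratio
  frac <- ifelse(obs$reads_total[sel] > 0,
                 obs$reads_A[sel] / obs$reads_total[sel], 0.5)
  new_tot <- stats::rpois(sum(sel), lambda)
  obs$reads_total[sel] <- new_tot
  obs$reads_A[sel] <- stats::rbinom(sum(sel), new_tot, frac)
  obs
}

#' Per-chromosome coverage profile
#'
#' @param obs a SNP-observation table.
#' @return List with `per_chrom` (named mean depth per chromosome, in order
#'   of appearance) and `genome` (genome-wide mean depth).
#' @export
coverage_profile <- function(obs) {
  chroms <- unique(obs$chrom)
  per <- vapply(chroms,
                function(ch) mean(obs$reads_total[obs$chrom == ch]),
                numeric(1))
  list(per_chrom = per, genome = mean(obs$reads_total))
}
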