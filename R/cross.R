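#' Parental haploid genotype
#'
#' @param map a [genetic_map()].
#' @param allele 0 (lab-strain type, "BY-like") or 1 ("YJM-like").
#' @return Integer vector of length [n_snps()].
#' @export
parental_genotype <- function(map, allele) {
  stopifnot(allele %in% c(0L, 1L))
  rep(as.integer(allele), n_snps(map))
}

# Parental origin of a gamete along one chromosome: crossover count is
# Poisson(length_cM / 100), breakpoints uniform in cM (Haldane, no
# interference), starting phase random. Returns logical: TRUE = from mother.
gamete_phase <- function(snp_cM, length_cM) {
  k <- stats::rpois(1L, length_cM / 100)
  phase <- sample.int(2L, 1L) - 1L
  if (k == 0L) return(rep(phase == 0L, length(snp_cM)))
  br <- sort(stats::runif(k, 0, length_cM))
  ((findInterval(snp_cM, br) + phase) %% 2L) == 0L
}

#' Simulate one meiosis of a diploid
#'
#' Produces a haploid gamete of the diploid formed by two haploid parents.
#' Per chromosome, the crossover count is Poisson-distributed with mean
#' `length_cM / 100` and breakpoints fall uniformly on the genetic map
#' (Haldane map function, no interference); the gamete alternates parental
#' origin at each crossover, starting from a random phase.
#'
#' @param mother,father haploid genotype vectors over all SNPs of `map`.
#' @param map a [genetic_map()].
#' @return Integer gamete genotype of length [n_snps()].
#' @export
meiosis <- function(mother, father, map) {
  if (length(mother) != n_snps(map) || length(father) != n_snps(map))
    stop("parent genotypes must cover every SNP of the map")
  g <- integer(n_snps(map))
  for (i in seq_len(nrow(map$chrom))) {
    idx <- map$chrom_index[[i]]
    if (length(idx) == 0L) next
    fm <- gamete_phase(map$snp$cM[idx], map$chrom$length_cM[i])
    gi <- mother[idx]
    gi[!fm] <- father[idx][!fm]
    g[idx] <- gi
  }
  g
}

# Meiosis evaluated only at a subset of SNPs (exact: the chromosome-wide
# crossover process is simulated in full; parental origin is just not
# evaluated at SNPs where both parents agree). `sub` is a list per
# chromosome: list(rows = indices into the subset vector, cM = positions).
meiosis_subset <- function(mother_sub, father_sub, sub, chrom_lengths_cM) {
  g <- integer(length(mother_sub))
  for (i in seq_along(sub)) {
    s <- sub[[i]]
    if (length(s$rows) == 0L) next
    fm <- gamete_phase(s$cM, chrom_lengths_cM[i])
    gi <- mother_sub[s$rows]
    gi[!fm] <- father_sub[s$rows][!fm]
    g[s$rows] <- gi
  }
  g
}

#' Phenotypic selection rule
#'
#' @param condition condition in which selection is applied (default
#'   `"E37"`, the severe condition).
#' @param mode `"bottom_quantile"` (keep the poorest fraction) or
#'   `"threshold"` (keep strains growing below an absolute value).
#' @param cutoff quantile in (0, 1) for `"bottom_quantile"` (default 0.05,
#'   matching a poor-grower frequency of about 5 percent), or an absolute
#'   growth threshold for `"threshold"`.
#' @return An object of class `selection_rule`.
#' @export
selection_rule <- function(condition = "E37",
                           mode = c("bottom_quantile", "threshold"),
                           cutoff = 0.05) {
  mode <- match.arg(mode)
  if (mode == "bottom_quantile" && (cutoff <= 0 || cutoff >= 1))
    stop("quantile cutoff must lie in (0, 1)")
  structure(list(condition = condition, mode = mode, cutoff = cutoff),
            class = "selection_rule")
}

selection_cutoff <- function(rule, phenotypes) {
  if (rule$mode == "threshold") rule$cutoff
  else stats::quantile(phenotypes, rule$cutoff, names = FALSE)
}

format_rule <- function(rule) {
  sprintf("%s at %s in %s", rule$mode, format(rule$cutoff), rule$condition)
}

#' Backcross breeding program parameters
#'
#' Defaults follow the study design: 112 F2 segregants screened, at least
#' 576 progeny phenotyped per backcross, six rounds of backcrossing in
#' total, and seven independent lineages per recurrent parent.
#'
#' @param n_f2 number of F2 segregants screened.
#' @param n_progeny_per_backcross progeny generated and phenotyped per
#'   backcross round.
#' @param n_backcross_rounds total backcross rounds (0 returns the selected
#'   F2 itself).
#' @param n_lineages_per_parent independent backcross lineages per recurrent
#'   parent.
#' @param selection a [selection_rule()].
#' @return An object of class `cross_program`.
#' @export
cross_program <- function(n_f2 = 112, n_progeny_per_backcross = 576,
                          n_backcross_rounds = 6, n_lineages_per_parent = 7,
                          selection = selection_rule()) {
  stopifnot(n_f2 >= 1, n_progeny_per_backcross >= 1,
            n_backcross_rounds >= 0, n_lineages_per_parent >= 1,
            inherits(selection, "selection_rule"))
  structure(list(n_f2 = n_f2,
                 n_progeny_per_backcross = n_progeny_per_backcross,
                 n_backcross_rounds = n_backcross_rounds,
                 n_lineages_per_parent = n_lineages_per_parent,
                 selection = selection),
            class = "cross_program")
}

# Generate n gametes of mother x father, phenotype them in the selection
# condition, and return the k poorest eligible individuals (plus summary
# statistics). Genotypes are kept only for the current k poorest, so memory
# stays flat in n.
generate_and_select <- function(mother, father, n, k, rule, model, map) {
  loci_idx <- locus_snp_indices(map, model$loci)
  phen <- numeric(n)
  pool_g <- vector("list", k)
  pool_p <- rep(Inf, k)
  for (i in seq_len(n)) {
    g <- meiosis(mother, father, map)
    p <- simulate_phenotype_at_loci(matrix(g[loci_idx], nrow = 1),
                                    rule$condition, model)
    phen[i] <- p
    j <- which.max(pool_p)
    if (p < pool_p[j]) {
      pool_p[j] <- p
      pool_g[[j]] <- g
    }
  }
  cutoff <- selection_cutoff(rule, phen)
  keep <- order(pool_p)
  keep <- keep[pool_p[keep] <= cutoff]
  if (length(keep) < k)
    stop("selection rule (", format_rule(rule), ") admits only ",
         length(keep), " of the ", k, " required individuals")
  list(genotypes = pool_g[keep], phenotypes = pool_p[keep],
       mean_all = mean(phen), mean_selected = mean(pool_p[keep]),
       n_eligible = sum(phen <= cutoff))
}

#' Run the recurrent backcross-with-selection program
#'
#' Executes the full breeding design: an F2 generation is screened and the
#' poorest grower passing the selection rule becomes the progenitor; it is
#' backcrossed to each parent, the poorest progeny found one lineage each;
#' and each lineage undergoes further rounds of backcrossing to its
#' recurrent parent with selection for poor growth. The final haploid of
#' each lineage is returned as a nearly isogenic line (NIL) together with
#' its true introgression segments (the maximal runs of SNPs where it
#' differs from the recurrent parent), which serve as ground truth for the
#' genotyper.
#'
#' Uses the R session RNG; seed with [set.seed()].
#'
#' @param by,yjm founder haploid genotypes (conventionally all-0 and all-1).
#' @param program a [cross_program()].
#' @param model a [phenotype_model()] with at least one causal locus.
#' @param map a [genetic_map()].
#' @return An object of class `backcross_result`: list with elements `f2`
#'   (the selected F2 genotype), `nils` (list of NIL records, each with
#'   `background` ("BY"/"YJM"), `background_allele`, `lineage`, `genotype`,
#'   and `segments`, a [segment_set()]), and `history` (per-round selection
#'   statistics).
#' @export
run_backcross_program <- function(by, yjm, program, model, map) {
  stopifnot(inherits(program, "cross_program"),
            inherits(model, "phenotype_model"), nrow(model$loci) >= 1)
  rule <- program$selection
  hist <- list()
  note <- function(bg, lineage, round, sel) {
    hist[[length(hist) + 1L]] <<- data.frame(
      background = bg, lineage = lineage, round = round,
      mean_all = sel$mean_all, mean_selected = sel$mean_selected,
      n_eligible = sel$n_eligible, stringsAsFactors = FALSE)
  }

  f2sel <- generate_and_select(by, yjm, program$n_f2, 1L, rule, model, map)
  note("F2", 0L, 0L, f2sel)
  f2 <- f2sel$genotypes[[1]]

  nils <- list()
  if (program$n_backcross_rounds > 0) {
    parents <- list(BY = by, YJM = yjm)
    for (bg in names(parents)) {
      parent <- parents[[bg]]
      bg_allele <- parent[1]
      r1 <- generate_and_select(f2, parent, program$n_progeny_per_backcross,
                                program$n_lineages_per_parent, rule, model,
                                map)
      note(bg, NA_integer_, 1L, r1)
      for (lin in seq_len(program$n_lineages_per_parent)) {
        cur <- r1$genotypes[[lin]]
        if (program$n_backcross_rounds > 1) {
          for (round in 2:program$n_backcross_rounds) {
            s <- generate_and_select(cur, parent,
                                     program$n_progeny_per_backcross, 1L,
                                     rule, model, map)
            note(bg, lin, round, s)
            cur <- s$genotypes[[1]]
          }
        }
        id <- sprintf("%s_NIL_%d", bg, lin)
        nils[[id]] <- list(
          background = bg, background_allele = bg_allele, lineage = lin,
          genotype = cur,
          segments = true_segments(cur, bg_allele, map, strain = id))
      }
    }
  }
  structure(list(f2 = f2, nils = nils,
                 history = do.call(rbind, hist)),
            class = "backcross_result")
}

#' True introgression segments of a genotype
#'
#' Maximal runs of SNPs at which a genotype differs from the recurrent
#' (background) parent, as 1-based inclusive intervals spanned by the run's
#' SNPs. This is the simulator's ground-truth counterpart of the segments
#' decoded by the genotyper.
#'
#' @param g haploid genotype vector over all SNPs of `map`.
#' @param background_allele the recurrent parent's allele (0 or 1).
#' @param map a [genetic_map()].
#' @param strain strain identifier stored in the result.
#' @return A [segment_set()].
#' @export
true_segments <- function(g, background_allele, map, strain = "strain") {
  states <- segments_from_states(g, map$snp[, c("chrom", "pos")],
                                 background_allele)
  segment_set(strain = strain, segments = states,
              background_allele = background_allele)
}

#' Construct a NIL-like genotype with defined introgressions
#'
#' Builds a haploid genotype in one parent's background carrying
#' introgressed segments of the other parent's allele centred on named map
#' loci. The default reproduces the reference-NIL configuration used by the
#' demonstration pipeline: sensitive-allele (0) segments at the four causal
#' loci, the neutral chromosome XVI and two other neutral loci, and the
#' \emph{CAN1} marker region, all in a type-1 background.
#'
#' @param map a [genetic_map()] with a locus table.
#' @param background_allele background parent's allele (default 1).
#' @param loci character vector of locus names to introgress (default: all
#'   causal and neutral loci plus `CAN1`).
#' @param halfwidth half-width in bp of each introgressed segment (default
#'   15000, i.e. 30 kb segments).
#' @return Integer genotype vector of length [n_snps()].
#' @export
synthetic_nil_genotype <- function(map, background_allele = 1L,
                                   loci = NULL, halfwidth = 15000) {
  if (is.null(map$loci)) stop("map has no locus table")
  if (is.null(loci))
    loci <- map$loci$name[map$loci$role %in% c("causal", "neutral") |
                            map$loci$name == "CAN1"]
  g <- parental_genotype(map, background_allele)
  donor <- 1L - as.integer(background_allele)
  for (nm in loci) {
    i <- match(nm, map$loci$name)
    if (is.na(i)) stop("unknown locus: ", nm)
    sel <- map$snp$chrom == map$loci$chrom[i] &
      abs(map$snp$pos - map$loci$pos[i]) <= halfwidth
    g[sel] <- donor
  }
  g
}

#' Simulate a population of final-round backcross segregants
#'
#' Draws `n` haploid segregants from one further backcross of a NIL to its
#' recurrent parent (each segregant is a single meiosis of the NIL x parent
#' diploid). Only SNPs that are polymorphic between the NIL and the parent
#' are returned: all other SNPs are identical in every segregant by
#' construction. The chromosome-wide crossover process is simulated in
#' full, so linkage between segments on a chromosome is exact.
#'
#' @param nil haploid genotype of the NIL (full map).
#' @param parent haploid genotype of the recurrent parent (full map).
#' @param n number of segregants.
#' @param map a [genetic_map()].
#' @return List with elements `genotypes` (n x m integer matrix, columns
#'   named by SNP id), `snp` (data.frame of the m polymorphic SNPs),
#'   `poly_idx` (their indices in `map$snp`), and `parent_allele` (the
#'   background allele at monomorphic SNPs).
#' @export
simulate_f2b7_population <- function(nil, parent, n, map) {
  poly <- which(nil != parent)
  if (length(poly) == 0L) stop("NIL and parent are identical: nothing segregates")
  sub <- lapply(seq_len(nrow(map$chrom)), function(i) {
    rows <- which(map$snp$chrom[poly] == map$chrom$name[i])
    list(rows = rows, cM = map$snp$cM[poly[rows]])
  })
  keep <- vapply(sub, function(s) length(s$rows) > 0L, logical(1))
  sub <- sub[keep]
  lens <- map$chrom$length_cM[keep]
  nil_sub <- nil[poly]
  par_sub <- parent[poly]
  G <- matrix(0L, nrow = n, ncol = length(poly),
              dimnames = list(NULL, map$snp$id[poly]))
  for (i in seq_len(n))
    G[i, ] <- meiosis_subset(nil_sub, par_sub, sub, lens)
  list(genotypes = G, snp = map$snp[poly, , drop = FALSE],
       poly_idx = poly, parent_allele = parent[1])
}

#' Expand a polymorphic-subset genotype to the full map
#'
#' Segregants of a NIL x recurrent-parent backcross carry the parent allele
#' at every SNP outside the polymorphic subset, so the full genotype is
#' recovered exactly.
#'
#' @param g_sub genotype vector over the polymorphic subset.
#' @param poly_idx indices of the subset SNPs in `map$snp`.
#' @param parent full-map genotype of the recurrent parent.
#' @return Full-length integer genotype vector.
#' @export
expand_f2b7_genotype <- function(g_sub, poly_idx, parent) {
  g <- parent
  g[poly_idx] <- g_sub
  g
}
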