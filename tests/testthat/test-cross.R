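test_that("meiosis copies identical parents and respects the map", {
  map <- toy_map()
  g <- meiosis(parental_genotype(map, 1L), parental_genotype(map, 1L), map)
  expect_equal(g, parental_genotype(map, 1L))
  expect_error(meiosis(rep(0L, 5), parental_genotype(map, 1L), map),
               "every SNP")
})

test_that("terminal-marker recombination matches the Haldane closed form", {
  # one 100 cM chromosome: recombinant fraction between the terminal SNPs
  # is (1 - exp(-2 * d/100)) / 2 = 0.4323 at d = 100 cM
  chrom <- data.frame(name = "chr1", length_bp = 100000L, length_cM = 100)
  map <- genetic_map(chrom, list(chr1 = c(1L, 100000L)))
  mo <- parental_genotype(map, 0L)
  fa <- parental_genotype(map, 1L)
  set.seed(11)
  n <- 10000
  rec <- vapply(seq_len(n), function(i) {
    g <- meiosis(mo, fa, map)
    g[1] != g[2]
  }, logical(1))
  p <- (1 - exp(-2)) / 2
  expect_lt(abs(mean(rec) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("a chromosome with (near) zero genetic length never recombines", {
  chrom <- data.frame(name = "chr1", length_bp = 50000L, length_cM = 1e-9)
  map <- genetic_map(chrom, list(chr1 = seq.int(1000L, 50000L, 1000L)))
  mo <- parental_genotype(map, 0L)
  fa <- parental_genotype(map, 1L)
  set.seed(5)
  for (i in 1:20) {
    g <- meiosis(mo, fa, map)
    expect_true(all(g == 0L) || all(g == 1L))
  }
})

test_that("phenotype model evaluates its linear form exactly", {
  map <- toy_causal_map()
  model <- toy_model(map, beta = c(1, 2, 3, 4), sigma = 0)
  all_yjm <- matrix(1L, 1, 4)
  all_by <- matrix(0L, 1, 4)
  expect_equal(simulate_phenotype_at_loci(all_yjm, "E37", model), 100)
  expect_equal(simulate_phenotype_at_loci(all_by, "E37", model),
               100 - sum(1:4))
  # severity 0 silences the loci entirely
  m0 <- toy_model(map, beta = c(1, 2, 3, 4), sigma = 0, severity = 0)
  expect_equal(simulate_phenotype_at_loci(all_by, "E37", m0), 100)
  expect_error(simulate_phenotype_at_loci(all_by, "G30", model),
               "unknown condition")
  # full-genotype interface agrees with the locus-level one
  g <- parental_genotype(map, 0L)
  expect_equal(simulate_phenotype(g, "E37", model, map), 100 - sum(1:4))
})

test_that("phenotypic variance matches the closed-form decomposition", {
  # free segregation at allele frequency 1/2: var = sum(beta^2 s^2)/4 + sd^2
  map <- yeast_map()
  model <- calibrate_phenotype_model(map)
  expected <- sum(model$loci$beta^2) / 4 + model$noise_sd[["E37"]]^2
  set.seed(17)
  vars <- replicate(20, {
    G <- matrix(rbinom(192 * 4, 1, 0.5), 192, 4)
    stats::var(simulate_phenotype_at_loci(G, "E37", model))
  })
  expect_lt(abs(mean(vars) - expected) / expected, 0.15)
})

test_that("shipped calibration reproduces its PVE targets", {
  model <- calibrate_phenotype_model(yeast_map())
  e37 <- expected_pve(model, "E37")
  expect_equal(as.numeric(e37), c(11.1, 32.4, 7.0, 24.7),
               tolerance = 1e-8)
  for (cn in c("G30", "G37", "E30", "E37")) {
    m <- mean(expected_pve(model, cn))
    target <- c(G30 = 0.48, G37 = 5.4, E30 = 9.2, E37 = 18.8)[[cn]]
    expect_lt(abs(m - target), 0.01)
  }
  # severity encodes increasing environmental perturbation
  expect_false(is.unsorted(model$severity[c("G30", "G37", "E30", "E37")],
                           strictly = TRUE))
})

test_that("zero backcross rounds return the selected F2 itself", {
  map <- toy_causal_map()
  model <- toy_model(map)
  prog <- cross_program(n_f2 = 30, n_progeny_per_backcross = 20,
                        n_backcross_rounds = 0,
                        n_lineages_per_parent = 1,
                        selection = selection_rule("E37",
                                                   "bottom_quantile", 0.2))
  set.seed(3)
  res <- run_backcross_program(parental_genotype(map, 0L),
                               parental_genotype(map, 1L),
                               prog, model, map)
  expect_length(res$nils, 0)
  expect_length(res$f2, n_snps(map))
  expect_true(all(res$f2 %in% c(0L, 1L)))
})

test_that("selection retains the sensitive alleles at strong causal loci", {
  # beta * s = 10 >= 4 * sigma: nearly deterministic genotype-phenotype map
  # enough progeny that the fully sensitive multi-locus class (frequency
  # 1/16 per backcross) is essentially always present to be selected
  map <- toy_causal_map()
  model <- toy_model(map, beta = rep(10, 4), sigma = 2)
  prog <- cross_program(n_f2 = 112, n_progeny_per_backcross = 200,
                        n_backcross_rounds = 4,
                        n_lineages_per_parent = 2,
                        selection = selection_rule("E37",
                                                   "bottom_quantile", 0.1))
  loci_idx <- vapply(seq_len(4), function(i)
    snp_index(map, map$loci$chrom[i], map$loci$pos[i]), integer(1))
  set.seed(23)
  carries_all <- unlist(lapply(1:20, function(r) {
    res <- run_backcross_program(parental_genotype(map, 0L),
                                 parental_genotype(map, 1L),
                                 prog, model, map)
    yjm_nils <- Filter(function(n) n$background == "YJM", res$nils)
    vapply(yjm_nils, function(n) all(n$genotype[loci_idx] == 0L),
           logical(1))
  }))
  expect_gte(mean(carries_all), 0.95)
})

test_that("selected progeny grow worse than the round average, every round", {
  map <- toy_causal_map()
  model <- toy_model(map, beta = rep(6, 4), sigma = 2)
  prog <- cross_program(n_f2 = 30, n_progeny_per_backcross = 30,
                        n_backcross_rounds = 3,
                        n_lineages_per_parent = 1,
                        selection = selection_rule("E37",
                                                   "bottom_quantile", 0.2))
  set.seed(7)
  for (s in 1:5) {
    res <- run_backcross_program(parental_genotype(map, 0L),
                                 parental_genotype(map, 1L),
                                 prog, model, map)
    expect_true(all(res$history$mean_selected < res$history$mean_all))
  }
})

test_that("non-causal introgression dilutes with additional backcrossing", {
  # with neutral loci (beta = 0) selection is random drift: donor-genome
  # fraction in the recurrent background decays roughly as (1/2)^(r+1)
  map <- toy_causal_map()
  model <- toy_model(map, beta = rep(0, 4), sigma = 2)
  set.seed(31)
  frac_by_round <- vapply(c(1, 3, 5), function(r) {
    prog <- cross_program(n_f2 = 10, n_progeny_per_backcross = 10,
                          n_backcross_rounds = r,
                          n_lineages_per_parent = 2,
                          selection = selection_rule("E37",
                                                     "bottom_quantile",
                                                     0.5))
    mean(unlist(lapply(1:15, function(i) {
      res <- run_backcross_program(parental_genotype(map, 0L),
                                   parental_genotype(map, 1L),
                                   prog, model, map)
      yjm <- Filter(function(n) n$background == "YJM", res$nils)
      vapply(yjm, function(n) mean(n$genotype == 0L), numeric(1))
    })))
  }, numeric(1))
  expect_true(all(diff(frac_by_round) < 0))
})

test_that("unselected backcross progeny segregate 1:1 at polymorphic loci", {
  map <- toy_causal_map()
  nil <- synthetic_nil_genotype(map, background_allele = 1L,
                                loci = paste0("Q", 1:4),
                                halfwidth = 10000)
  set.seed(41)
  pop <- simulate_f2b7_population(nil, parental_genotype(map, 1L), 1000,
                                  map)
  for (nm in paste0("Q", 1:4)) {
    i <- match(nm, map$loci$name)
    id <- map$snp$id[snp_index(map, map$loci$chrom[i], map$loci$pos[i])]
    n0 <- sum(pop$genotypes[, id] == 0L)
    expect_gt(stats::binom.test(n0, 1000, 0.5)$p.value, 0.001)
  }
})

test_that("recorded introgression segments exactly bookkeep the genotype", {
  map <- toy_causal_map()
  model <- toy_model(map, beta = rep(8, 4), sigma = 2)
  prog <- cross_program(n_f2 = 20, n_progeny_per_backcross = 20,
                        n_backcross_rounds = 2,
                        n_lineages_per_parent = 2,
                        selection = selection_rule("E37",
                                                   "bottom_quantile", 0.3))
  set.seed(13)
  res <- run_backcross_program(parental_genotype(map, 0L),
                               parental_genotype(map, 1L),
                               prog, model, map)
  for (nl in res$nils) {
    bg <- nl$background_allele
    # SNPs inside recorded segments must differ from the background, and
    # SNPs outside must match it
    inside <- rep(FALSE, n_snps(map))
    segs <- nl$segments$segments
    for (i in seq_len(nrow(segs))) {
      sel <- map$snp$chrom == segs$chrom[i] &
        map$snp$pos >= segs$start_bp[i] & map$snp$pos <= segs$end_bp[i]
      inside <- inside | sel
    }
    expect_equal(inside, nl$genotype != bg)
  }
})

test_that("f2b7 subset population expands back to full genotypes", {
  map <- toy_causal_map()
  nil <- synthetic_nil_genotype(map, loci = c("Q1", "Q3"),
                                halfwidth = 8000)
  parent <- parental_genotype(map, 1L)
  set.seed(2)
  pop <- simulate_f2b7_population(nil, parent, 5, map)
  g <- expand_f2b7_genotype(pop$genotypes[3, ], pop$poly_idx, parent)
  expect_length(g, n_snps(map))
  expect_equal(g[pop$poly_idx], unname(pop$genotypes[3, ]))
  expect_true(all(g[-pop$poly_idx] == 1L))
  expect_error(simulate_f2b7_population(parent, parent, 5, map),
               "nothing segregates")
})
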