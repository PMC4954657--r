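test_that("isolated discordant calls are absorbed by the state path", {
  params <- hmm_params()
  expect_equal(decode_genotypes(obs_from_calls(rep(0L, 5)), params),
               rep(0L, 5))
  # one discordant call among five: two transitions cost far more than one
  # emission mismatch, so the path stays in state 0
  expect_equal(decode_genotypes(obs_from_calls(c(0L, 0L, 1L, 0L, 0L)),
                                params),
               rep(0L, 5))
  # short discordant runs are still cheaper to absorb than to switch
  # (four mismatches at ~2.94 nats each versus two switches at ~9.2 each)
  mid <- decode_genotypes(obs_from_calls(c(0L, 0L, 1L, 1L, 1L, 1L, 0L,
                                           0L)), params)
  expect_true(all(mid == mid[1]))
  # a long discordant run (> 2 * log(switch) / log(eps/(1-eps)) calls)
  # does switch the state
  calls <- c(rep(0L, 5), rep(1L, 8), rep(0L, 5))
  expect_equal(decode_genotypes(obs_from_calls(calls), params), calls)
})

test_that("Viterbi equals the exhaustive path maximum on random chains", {
  set.seed(101)
  for (i in 1:200) {
    T_ <- sample(1:10, 1)
    calls <- sample(0:1, T_, replace = TRUE)
    depth <- sample(0:6, T_, replace = TRUE)  # includes zero coverage
    obs <- data.frame(chrom = "c", pos = seq_len(T_) * 50L,
                      reads_A = ifelse(calls == 0L, depth, 0L),
                      reads_total = depth)
    if (all(depth == 0)) next
    params <- hmm_params(p_stay = stats::runif(1, 0.6, 0.9999),
                         epsilon = stats::runif(1, 0.01, 0.4))
    path <- decode_genotypes(obs, params)
    em <- nilmap:::emission_loglik(obs$reads_A, obs$reads_total, params)
    oracle <- enum_viterbi(em, params)
    expect_equal(path_loglik(path, em, params), oracle$max_loglik,
                 tolerance = 1e-9)
  }
})

test_that("uninformative emissions decode to state 0 by tie-breaking", {
  obs <- obs_from_calls(c(0L, 1L, 0L, 1L))
  params <- hmm_params(emission_mode = "literal_uniform")
  expect_equal(decode_genotypes(obs, params), rep(0L, 4))
})

test_that("decoding validates its inputs", {
  params <- hmm_params()
  empty <- data.frame(chrom = character(), pos = integer(),
                      reads_A = integer(), reads_total = integer())
  expect_error(decode_genotypes(empty, params), "empty")
  nocov <- data.frame(chrom = "c", pos = c(10L, 20L), reads_A = 0L,
                      reads_total = 0L)
  expect_error(decode_genotypes(nocov, params), "no covered SNP")
  bad <- data.frame(chrom = "c", pos = 10L, reads_A = 5L,
                    reads_total = 3L)
  expect_error(decode_genotypes(bad, params), "malformed")
  unsorted <- data.frame(chrom = "c", pos = c(20L, 10L), reads_A = 1L,
                         reads_total = 1L)
  expect_error(decode_genotypes(unsorted, params), "sorted")
  expect_error(hmm_params(epsilon = 0.7), "epsilon")
})

test_that("segments round-trip through state vectors", {
  pos <- data.frame(chrom = rep(c("c1", "c2"), each = 5),
                    pos = rep(c(10L, 20L, 30L, 40L, 50L), 2))
  st <- c(0L, 0L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L)
  seg <- segments_from_states(st, pos, background_allele = 0L)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_bp, 30L)
  expect_equal(seg$end_bp, 40L)
  expect_equal(seg$chrom, "c1")
  # all-background gives an empty list
  expect_equal(nrow(segments_from_states(rep(0L, 10), pos, 0L)), 0)

  # random 200-SNP round trip: states -> segments -> states
  set.seed(33)
  pos200 <- data.frame(chrom = rep(c("c1", "c2"), each = 100),
                       pos = rep(seq(100L, 10000L, 100L), 2))
  for (i in 1:20) {
    st <- integer(200)
    cur <- 0L
    for (j in 1:200) {  # sticky random walk generates realistic runs
      if (stats::runif(1) < 0.05) cur <- 1L - cur
      st[j] <- cur
    }
    seg <- segments_from_states(st, pos200, 0L)
    back <- integer(200)
    for (k in seq_len(nrow(seg))) {
      sel <- pos200$chrom == seg$chrom[k] & pos200$pos >= seg$start_bp[k] &
        pos200$pos <= seg$end_bp[k]
      back[sel] <- 1L
    }
    expect_equal(back, st)
  }
})

test_that("decoded segments recover simulator ground truth at depth 10", {
  map <- toy_map(lengths_bp = c(chrA = 400000, chrB = 400000),
                 spacing = 500)
  parent <- parental_genotype(map, 1L)
  set.seed(55)
  acc <- replicate(20, {
    # random NIL-like genotype: a couple of introgressed blocks
    g <- parent
    for (ch in c("chrA", "chrB")) {
      start <- sample.int(300000, 1)
      sel <- map$snp$chrom == ch & map$snp$pos >= start &
        map$snp$pos <= start + 40000
      g[sel] <- 0L
    }
    obs <- simulate_read_observations(g, map, 10, base_error = 0.01)
    mean(decode_genotypes(obs, hmm_params()) == g)
  })
  expect_gte(mean(acc), 0.999)
})

test_that("posterior decoding agrees with Viterbi at confident SNPs", {
  map <- toy_map(lengths_bp = c(chrA = 200000), spacing = 500)
  parent <- parental_genotype(map, 1L)
  set.seed(77)
  g <- parent
  g[100:180] <- 0L
  obs <- simulate_read_observations(g, map, 8, base_error = 0.02)
  params <- hmm_params()
  vit <- decode_genotypes(obs, params, method = "viterbi")
  post <- state_posteriors(obs, params)
  conf <- apply(post, 1, max) > 0.99
  post_call <- ifelse(post[, 1] >= post[, 2], 0L, 1L)
  expect_true(all(vit[conf] == post_call[conf]))
  expect_gt(mean(conf), 0.5)  # the comparison is not vacuous
})

test_that("lowering the switch probability never fragments the decode", {
  set.seed(88)
  for (i in 1:10) {
    calls <- sample(0:1, 60, replace = TRUE, prob = c(0.7, 0.3))
    obs <- obs_from_calls(calls)
    n_seg <- vapply(c(0.9, 0.99, 0.999, 0.9999), function(ps) {
      st <- decode_genotypes(obs, hmm_params(p_stay = ps))
      nrow(segments_from_states(st, obs[, c("chrom", "pos")], 0L))
    }, numeric(1))
    expect_true(all(diff(n_seg) <= 0))
  }
})

test_that("coverage ratios flag aneuploid chromosomes at the 1.5x rule", {
  cov <- list(per_chrom = c(chr1 = 20, chr2 = 20, chr3 = 20), genome = 20)
  expect_length(detect_aneuploidy(cov), 0)
  cov$per_chrom[["chr2"]] <- 40  # 2x the genome mean
  expect_equal(detect_aneuploidy(cov), "chr2")
  cov$per_chrom[["chr2"]] <- 16  # 0.8x: above 1/1.5, not flagged
  expect_length(detect_aneuploidy(cov), 0)
  cov$per_chrom[["chr2"]] <- 10  # 0.5x: flagged low
  expect_equal(detect_aneuploidy(cov), "chr2")
  expect_error(detect_aneuploidy(list(per_chrom = c(chr1 = 0), genome = 0)),
               "zero")
})

test_that("replicate NILs are detected by introgression Jaccard overlap", {
  seg <- function(strain, start, end) {
    segment_set(strain, data.frame(chrom = "c1", start_bp = start,
                                   end_bp = end, allele = 0L), 1L)
  }
  a <- seg("a", 1001L, 11000L)       # 10 kb
  b <- seg("b", 1001L, 11000L)       # identical
  c_ <- seg("c", 50001L, 60000L)     # disjoint
  d <- seg("d", 2001L, 12000L)       # overlaps a by 9 kb: J = 9/11
  expect_equal(segment_jaccard(a, b), 1)
  expect_equal(segment_jaccard(a, c_), 0)
  expect_equal(segment_jaccard(a, d), 9000 / 11000)
  reps <- find_replicate_nils(list(a, b, c_, d), jaccard_min = 0.9)
  expect_equal(nrow(reps), 1)
  expect_equal(reps$strain1, "a")
  expect_equal(reps$strain2, "b")
})

test_that("segment sets validate their invariants", {
  expect_error(segment_set("s", data.frame(chrom = "c", start_bp = 10L,
                                           end_bp = 5L, allele = 0L), 1L),
               "start after end")
  expect_error(segment_set("s", data.frame(chrom = "c", start_bp = 10L,
                                           end_bp = 20L, allele = 1L), 1L),
               "non-background")
  expect_error(segment_set("s", data.frame(chrom = c("c", "c"),
                                           start_bp = c(10L, 15L),
                                           end_bp = c(20L, 30L),
                                           allele = 0L), 1L),
               "overlapping")
})
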