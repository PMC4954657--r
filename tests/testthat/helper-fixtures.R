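# Small maps and models used across the test files. All fixtures are built
# in code; nothing is read from disk.

toy_map <- function(lengths_bp = c(chrA = 100000, chrB = 80000),
                    spacing = 2000, cm_per_kb = 0.4, loci = NULL) {
  chrom <- data.frame(name = names(lengths_bp),
                      length_bp = unname(lengths_bp),
                      length_cM = unname(lengths_bp) / 1000 * cm_per_kb,
                      stringsAsFactors = FALSE)
  snps <- lapply(lengths_bp, function(L) seq.int(spacing, L, by = spacing))
  names(snps) <- names(lengths_bp)
  genetic_map(chrom, snps, loci = loci)
}

# four strong causal loci on four chromosomes, used for selection tests
toy_causal_map <- function() {
  toy_map(lengths_bp = c(chrA = 100000, chrB = 100000, chrC = 100000,
                         chrD = 100000),
          spacing = 2000,
          loci = data.frame(
            name = paste0("Q", 1:4),
            chrom = c("chrA", "chrB", "chrC", "chrD"),
            pos = rep(50000L, 4), role = rep("causal", 4),
            stringsAsFactors = FALSE))
}

toy_model <- function(map, beta = rep(10, 4), sigma = 2,
                      severity = c(E37 = 1), baseline = c(E37 = 100)) {
  causal <- map$loci[map$loci$role == "causal", , drop = FALSE]
  phenotype_model(
    baseline = baseline,
    loci = data.frame(name = causal$name, chrom = causal$chrom,
                      pos = causal$pos, beta = beta,
                      stringsAsFactors = FALSE),
    severity = stats::setNames(rep(severity, length.out = length(baseline)),
                               names(baseline)),
    noise_sd = stats::setNames(rep(sigma, length(baseline)),
                               names(baseline)))
}

# random observation table on one chromosome with given binarized calls
obs_from_calls <- function(calls, depth = 10L, chrom = "chr1") {
  # calls: 0 -> majority allele A, 1 -> majority allele B
  data.frame(chrom = chrom, pos = seq_along(calls) * 100L,
             reads_A = ifelse(calls == 0L, depth, 0L),
             reads_total = depth, stringsAsFactors = FALSE)
}

random_segment_set <- function(strain, chroms = c("chr1", "chr2"),
                               max_pos = 1000L, background = 1L) {
  segs <- do.call(rbind, lapply(chroms, function(ch) {
    k <- sample(0:3, 1)
    if (k == 0) return(NULL)
    bounds <- sort(sample.int(max_pos, 2 * k))
    data.frame(chrom = ch,
               start_bp = bounds[seq(1, 2 * k, 2)],
               end_bp = bounds[seq(2, 2 * k, 2)],
               allele = 1L - background, stringsAsFactors = FALSE)
  }))
  if (is.null(segs))
    segs <- data.frame(chrom = character(), start_bp = integer(),
                       end_bp = integer(), allele = integer(),
                       stringsAsFactors = FALSE)
  segment_set(strain, segs, background)
}
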