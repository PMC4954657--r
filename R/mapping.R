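#' Count introgression recurrence across strains
#'
#' Partitions the genome at every segment endpoint and, for each atomic
#' interval, counts how many strains carry an introgression overlapping it.
#' Adjacent atomic intervals with identical member sets are merged, so each
#' returned region is the maximal interval shared by exactly that set of
#' strains.
#'
#' @param sets list of [segment_set()] objects on a shared map.
#' @return data.frame `chrom`, `start_bp`, `end_bp`, `count`, `members`
#'   (comma-separated strain ids), sorted by chromosome then start.
#' @export
count_region_overlaps <- function(sets) {
  stopifnot(length(sets) >= 1)
  segs <- do.call(rbind, lapply(sets, function(s) {
    if (nrow(s$segments) == 0L) return(NULL)
    cbind(s$segments, strain = s$strain)
  }))
  empty <- data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), count = integer(),
                      members = character(), stringsAsFactors = FALSE)
  if (is.null(segs) || nrow(segs) == 0L) return(empty)
  out <- list()
  for (ch in unique(segs$chrom)) {
    s <- segs[segs$chrom == ch, , drop = FALSE]
    # atomic intervals between consecutive breakpoints (1-based inclusive)
    bounds <- sort(unique(c(s$start_bp, s$end_bp + 1L)))
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1L] - 1L
    members <- lapply(seq_along(starts), function(i) {
      sort(unique(s$strain[s$start_bp <= starts[i] & s$end_bp >= ends[i]]))
    })
    keep <- lengths(members) > 0L
    starts <- starts[keep]; ends <- ends[keep]; members <- members[keep]
    if (length(starts) == 0L) next
    key <- vapply(members, paste, character(1), collapse = ",")
    # merge contiguous atoms with identical membership
    new_run <- c(TRUE, key[-1] != key[-length(key)] |
                   starts[-1] != ends[-length(ends)] + 1L)
    run <- cumsum(new_run)
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch,
      start_bp = tapply(starts, run, min),
      end_bp = tapply(ends, run, max),
      count = lengths(members)[new_run],
      members = key[new_run],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Recurrently introgressed loci
#'
#' Regions introgressed independently in at least `min_count` strains,
#' excluding regions that overlap configured selection-marker windows
#' (whose retention reflects the breeding protocol rather than phenotype).
#'
#' @param regions output of [count_region_overlaps()].
#' @param min_count minimum number of carrier strains (default 2; regions
#'   seen in a single strain are not considered validated).
#' @param exclude_regions optional data.frame `chrom`, `start_bp`, `end_bp`
#'   of intervals to mask (see [marker_regions()]).
#' @return Subset of `regions`.
#' @export
recurrent_loci <- function(regions, min_count = 2, exclude_regions = NULL) {
  keep <- regions$count >= min_count
  if (!is.null(exclude_regions) && nrow(exclude_regions)) {
    for (i in seq_len(nrow(exclude_regions))) {
      hit <- regions$chrom == exclude_regions$chrom[i] &
        regions$start_bp <= exclude_regions$end_bp[i] &
        regions$end_bp >= exclude_regions$start_bp[i]
      keep <- keep & !hit
    }
  }
  res <- regions[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact test computed directly from the hypergeometric mass with both
#' margins fixed. The two-sided p-value uses the minimum-likelihood
#' convention: the sum of probabilities of all tables whose point
#' probability does not exceed that of the observed table (the convention
#' of standard statistical environments). The odds ratio is the sample
#' cross-product ratio `ad/bc` (infinite when `bc = 0`).
#'
#' @param tab 2x2 matrix of non-negative integer counts with both row and
#'   both column margins positive.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to the upper-left cell.
#' @return List with `odds_ratio` and `p_value`.
#' @export
fisher_exact_2x2 <- function(tab, alternative = c("two.sided", "less",
                                                  "greater")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0),
            all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("both margins of the 2x2 table must be positive")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  x <- lo:hi
  probs <- stats::dhyper(x, c1, n - c1, r1)
  p_obs <- probs[match(a, x)]
  p <- switch(alternative,
              two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
              less = sum(probs[x <= a]),
              greater = sum(probs[x >= a]))
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  list(odds_ratio = or, p_value = min(p, 1))
}

#' Allelic enrichment of a locus in selected versus control strains
#'
#' For every typed SNP inside the locus, builds the 2x2 table of allele
#' counts (rows: selected poor growers, random controls; columns: alleles 0
#' and 1) and tests it with [fisher_exact_2x2()]. The SNP with maximal
#' enrichment (minimal p-value; ties broken toward the smallest genomic
#' position) is reported. No multiple-testing correction is applied.
#'
#' @param locus list or one-row data.frame with `chrom`, `start_bp`,
#'   `end_bp` and optionally `name`.
#' @param selected_geno,control_geno 0/1 genotype matrices (strains x
#'   SNPs) whose columns are named by SNP id and described by `positions`.
#' @param positions data.frame `chrom`, `pos`, `id` covering the matrix
#'   columns.
#' @return One-row data.frame `locus`, `chrom`, `pos`, `sel_0`, `sel_1`,
#'   `ctl_0`, `ctl_1`, `odds_ratio`, `p_value`.
#' @export
locus_enrichment <- function(locus, selected_geno, control_geno,
                             positions) {
  sel_ids <- positions$id[positions$chrom == locus$chrom &
                            positions$pos >= locus$start_bp &
                            positions$pos <= locus$end_bp]
  sel_ids <- sel_ids[sel_ids %in% colnames(selected_geno) &
                       sel_ids %in% colnames(control_geno)]
  if (length(sel_ids) == 0L)
    stop("no typed SNPs within locus ",
         if (!is.null(locus$name)) locus$name else locus$chrom)
  pos <- positions$pos[match(sel_ids, positions$id)]
  o <- order(pos)
  sel_ids <- sel_ids[o]; pos <- pos[o]
  best <- NULL
  for (k in seq_along(sel_ids)) {
    gs <- selected_geno[, sel_ids[k]]
    gc <- control_geno[, sel_ids[k]]
    tab <- matrix(c(sum(gs == 0), sum(gs == 1),
                    sum(gc == 0), sum(gc == 1)), 2, 2, byrow = TRUE)
    ft <- fisher_exact_2x2(tab)
    if (is.null(best) || ft$p_value < best$p_value) {
      best <- data.frame(
        locus = if (!is.null(locus$name)) locus$name else
          sprintf("%s:%d-%d", locus$chrom, locus$start_bp, locus$end_bp),
        chrom = locus$chrom, pos = pos[k],
        sel_0 = tab[1, 1], sel_1 = tab[1, 2],
        ctl_0 = tab[2, 1], ctl_1 = tab[2, 2],
        odds_ratio = ft$odds_ratio, p_value = ft$p_value,
        stringsAsFactors = FALSE)
    }
  }
  best
}

#' Refine a locus to a candidate interval
#'
#' Intersects, within the locus, the causal-allele segments of every
#' selected segregant: since each selected strain must carry the causal
#' allele, only the shared core of their (recombination-trimmed) segments
#' can contain the causal variant. An empty intersection signals a
#' phenotyping or genotyping inconsistency and raises an error.
#'
#' @param locus list/one-row data.frame with `chrom`, `start_bp`, `end_bp`.
#' @param selected_segment_sets list of [segment_set()] objects for the
#'   selected segregants.
#' @param causal_allele allele carried by the causal segments (default 0).
#' @return Numeric vector `c(start_bp, end_bp)`.
#' @export
refine_interval <- function(locus, selected_segment_sets,
                            causal_allele = 0L) {
  lo <- locus$start_bp
  hi <- locus$end_bp
  for (s in selected_segment_sets) {
    seg <- s$segments
    seg <- seg[seg$chrom == locus$chrom & seg$allele == causal_allele &
                 seg$start_bp <= hi & seg$end_bp >= lo, , drop = FALSE]
    if (nrow(seg) == 0L)
      stop("strain ", s$strain, " carries no allele-", causal_allele,
           " segment overlapping the current interval: ",
           "phenotype/genotype inconsistency")
    # widest overlapping segment governs this strain's constraint
    j <- which.max(pmin(seg$end_bp, hi) - pmax(seg$start_bp, lo))
    lo <- max(lo, seg$start_bp[j])
    hi <- min(hi, seg$end_bp[j])
    if (lo > hi)
      stop("empty intersection while refining ", locus$chrom,
           ": phenotype/genotype inconsistency")
  }
  c(start_bp = lo, end_bp = hi)
}
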