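#' Two-state HMM genotyper parameters
#'
#' Hidden states are the two parental origins (0 and 1). Transitions are
#' symmetric with a high stay probability (default 0.9999 stay / 0.0001
#' switch), reflecting the rarity of recombination breakpoints relative to
#' SNP spacing; the initial distribution defaults to uniform.
#'
#' Two emission modes are available. `"binarized_error"` (the default)
#' reduces each covered SNP to its majority allele (allele fraction at or
#' above one half calls "A") and emits it with probability `1 - epsilon`
#' from the matching state and `epsilon` otherwise; zero-coverage SNPs are
#' uninformative (probability 1 from both states), so they contribute only
#' transition geometry. `"literal_uniform"` makes every emission
#' probability one half, a constant-likelihood mode retained for fidelity
#' experiments: it cannot distinguish states from data and decodes from the
#' initial/transition structure alone, with ties broken toward state 0.
#'
#' @param p_stay probability of remaining in the same state between
#'   adjacent SNPs.
#' @param initial length-2 initial state distribution.
#' @param emission_mode `"binarized_error"` or `"literal_uniform"`.
#' @param epsilon per-call error under `"binarized_error"`, in (0, 0.5).
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(p_stay = 0.9999, initial = c(0.5, 0.5),
                       emission_mode = c("binarized_error",
                                         "literal_uniform"),
                       epsilon = 0.05) {
  emission_mode <- match.arg(emission_mode)
  stopifnot(p_stay > 0, p_stay < 1, length(initial) == 2,
            all(initial >= 0), abs(sum(initial) - 1) < 1e-12,
            epsilon > 0, epsilon < 0.5)
  transition <- matrix(c(p_stay, 1 - p_stay, 1 - p_stay, p_stay), 2, 2,
                       byrow = TRUE)
  structure(list(transition = transition, initial = initial,
                 emission_mode = emission_mode, epsilon = epsilon),
            class = "hmm_params")
}

check_obs <- function(obs) {
  need <- c("chrom", "pos", "reads_A", "reads_total")
  if (!all(need %in% names(obs)))
    stop("observation table must have columns ",
         paste(need, collapse = ", "))
  if (any(obs$reads_A < 0) || any(obs$reads_total < 0) ||
      any(obs$reads_A > obs$reads_total))
    stop("malformed read counts: need 0 <= reads_A <= reads_total")
  for (ch in unique(obs$chrom)) {
    if (is.unsorted(obs$pos[obs$chrom == ch]))
      stop("positions must be sorted within chromosome ", ch)
  }
  invisible(obs)
}

# log emission likelihood matrix (2 x T) for one chromosome
emission_loglik <- function(reads_A, reads_total, params) {
  T_ <- length(reads_A)
  em <- matrix(0, 2, T_)
  covered <- reads_total > 0
  if (params$emission_mode == "binarized_error") {
    maj_A <- reads_A / pmax(reads_total, 1L) >= 0.5
    eps <- params$epsilon
    em[1, covered] <- ifelse(maj_A[covered], log1p(-eps), log(eps))
    em[2, covered] <- ifelse(maj_A[covered], log(eps), log1p(-eps))
  } else {
    em[, covered] <- log(0.5)
  }
  em
}

# Viterbi with ties broken toward state 0 (>= comparisons favour state 1 of
# the matrix, i.e. model state 0)
viterbi_path <- function(em, params) {
  T_ <- ncol(em)
  lt <- log(params$transition)
  li <- log(params$initial)
  delta <- li + em[, 1]
  psi <- matrix(1L, 2, T_)
  if (T_ > 1) {
    for (t in 2:T_) {
      c0 <- delta + lt[, 1]
      c1 <- delta + lt[, 2]
      psi[1, t] <- if (c0[1] >= c0[2]) 1L else 2L
      psi[2, t] <- if (c1[1] >= c1[2]) 1L else 2L
      delta <- c(c0[psi[1, t]], c1[psi[2, t]]) + em[, t]
    }
  }
  path <- integer(T_)
  path[T_] <- if (delta[1] >= delta[2]) 1L else 2L
  if (T_ > 1) for (t in (T_ - 1):1) path[t] <- psi[path[t + 1], t + 1]
  path - 1L
}

# forward-backward posterior state probabilities (2 x T), in log space with
# per-column normalisation
posterior_probs <- function(em, params) {
  T_ <- ncol(em)
  tr <- params$transition
  fwd <- matrix(0, 2, T_)
  bwd <- matrix(0, 2, T_)
  a <- params$initial * exp(em[, 1])
  fwd[, 1] <- a / sum(a)
  if (T_ > 1) {
    for (t in 2:T_) {
      a <- (t(tr) %*% fwd[, t - 1]) * exp(em[, t])
      fwd[, t] <- a / sum(a)
    }
  }
  bwd[, T_] <- 1
  if (T_ > 1) {
    for (t in (T_ - 1):1) {
      b <- tr %*% (exp(em[, t + 1]) * bwd[, t + 1])
      bwd[, t] <- b / sum(b)
    }
  }
  post <- fwd * bwd
  sweep(post, 2, colSums(post), "/")
}

#' Decode parental-origin genotypes from allele-count observations
#'
#' Runs the two-state HMM independently on each chromosome of a
#' SNP-observation table and returns the most probable state path (Viterbi,
#' the default) or the per-SNP posterior-mode path. All arithmetic is in
#' log space.
#'
#' @param obs SNP-observation table (`chrom`, `pos`, `reads_A`,
#'   `reads_total`), positions sorted within chromosome.
#' @param params an [hmm_params()].
#' @param method `"viterbi"` or `"posterior"`.
#' @return Integer vector of decoded states (0/1) aligned to the rows of
#'   `obs`.
#' @export
decode_genotypes <- function(obs, params = hmm_params(),
                             method = c("viterbi", "posterior")) {
  method <- match.arg(method)
  check_obs(obs)
  if (nrow(obs) == 0L) stop("empty observation table")
  states <- integer(nrow(obs))
  for (ch in unique(obs$chrom)) {
    rows <- which(obs$chrom == ch)
    if (!any(obs$reads_total[rows] > 0))
      stop("chromosome ", ch, " has no covered SNP")
    em <- emission_loglik(obs$reads_A[rows], obs$reads_total[rows], params)
    states[rows] <- if (method == "viterbi") viterbi_path(em, params)
    else {
      post <- posterior_probs(em, params)
      ifelse(post[1, ] >= post[2, ], 0L, 1L)
    }
  }
  states
}

#' Posterior state probabilities per SNP
#'
#' Forward-backward posterior probability of each hidden state at every SNP,
#' by chromosome.
#'
#' @inheritParams decode_genotypes
#' @return Numeric matrix (rows of `obs` x 2 states).
#' @export
state_posteriors <- function(obs, params = hmm_params()) {
  check_obs(obs)
  out <- matrix(NA_real_, nrow(obs), 2)
  for (ch in unique(obs$chrom)) {
    rows <- which(obs$chrom == ch)
    em <- emission_loglik(obs$reads_A[rows], obs$reads_total[rows], params)
    out[rows, ] <- t(posterior_probs(em, params))
  }
  out
}

#' Extract segments from a per-SNP state vector
#'
#' Maximal runs of the non-background state become segments. A segment's
#' start is the position of the first SNP in the run and its end the
#' position of the last SNP (1-based inclusive, SNP-spanned convention).
#'
#' @param states integer vector of 0/1 states.
#' @param positions data.frame `chrom`, `pos` aligned to `states`.
#' @param background_allele the background state (0 or 1); runs of the
#'   other state are reported.
#' @return data.frame `chrom`, `start_bp`, `end_bp`, `allele` (possibly
#'   zero rows).
#' @export
segments_from_states <- function(states, positions, background_allele) {
  stopifnot(length(states) == nrow(positions),
            background_allele %in% c(0L, 1L))
  out <- list()
  for (ch in unique(positions$chrom)) {
    rows <- which(positions$chrom == ch)
    r <- rle(states[rows] != background_allele)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    seg <- which(r$values)
    if (length(seg))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start_bp = positions$pos[rows[starts[seg]]],
        end_bp = positions$pos[rows[ends[seg]]],
        allele = 1L - as.integer(background_allele),
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), allele = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Introgression segment set of one strain
#'
#' Container for the decoded (or true) introgressions of a strain:
#' non-overlapping sorted segments of the non-background allele, the
#' background allele, and any chromosomes flagged as aneuploid.
#'
#' @param strain strain identifier.
#' @param segments data.frame `chrom`, `start_bp`, `end_bp`, `allele`.
#' @param background_allele the strain's background allele (0 or 1).
#' @param aneuploid_chroms character vector of flagged chromosomes.
#' @return An object of class `segment_set`.
#' @export
segment_set <- function(strain, segments, background_allele,
                        aneuploid_chroms = character()) {
  stopifnot(all(c("chrom", "start_bp", "end_bp", "allele") %in%
                  names(segments)))
  if (nrow(segments)) {
    if (any(segments$start_bp > segments$end_bp))
      stop("segment start after end")
    if (any(segments$allele == background_allele))
      stop("segments must carry the non-background allele")
    for (ch in unique(segments$chrom)) {
      s <- segments[segments$chrom == ch, , drop = FALSE]
      s <- s[order(s$start_bp), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start_bp[-1] <= s$end_bp[-nrow(s)]))
        stop("overlapping segments on ", ch)
    }
    segments <- segments[order(match(segments$chrom, unique(segments$chrom)),
                               segments$start_bp), , drop = FALSE]
    rownames(segments) <- NULL
  }
  structure(list(strain = strain, segments = segments,
                 background_allele = as.integer(background_allele),
                 aneuploid_chroms = aneuploid_chroms),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat("segment_set ", x$strain, ": ", nrow(x$segments),
      " introgressed segments (background allele ", x$background_allele,
      ")\n", sep = "")
  if (length(x$aneuploid_chroms))
    cat("  aneuploid:", paste(x$aneuploid_chroms, collapse = ", "), "\n")
  invisible(x)
}

#' Call introgression segments of one strain from observations
#'
#' Convenience wrapper: decodes states with [decode_genotypes()], screens
#' coverage for aneuploidy with [detect_aneuploidy()], and packages the
#' result as a [segment_set()].
#'
#' @inheritParams decode_genotypes
#' @param strain strain identifier.
#' @param background_allele the recurrent-parent allele.
#' @param aneuploidy_threshold coverage-ratio threshold (see
#'   [detect_aneuploidy()]).
#' @return A [segment_set()]; decoded states are attached as attribute
#'   `"states"`.
#' @export
call_introgressions <- function(obs, strain, background_allele,
                                params = hmm_params(),
                                method = "viterbi",
                                aneuploidy_threshold = 1.5) {
  states <- decode_genotypes(obs, params, method)
  segs <- segments_from_states(states, obs[, c("chrom", "pos")],
                               background_allele)
  flagged <- detect_aneuploidy(coverage_profile(obs),
                               aneuploidy_threshold)
  out <- segment_set(strain, segs, background_allele, flagged)
  attr(out, "states") <- states
  out
}

#' Flag aneuploid chromosomes from coverage ratios
#'
#' A chromosome is flagged when its mean depth is at least `threshold`
#' times higher, or at most `1/threshold` times lower, than the genome-wide
#' mean.
#'
#' @param cov a [coverage_profile()].
#' @param threshold ratio threshold (default 1.5).
#' @return Character vector of flagged chromosome names.
#' @export
detect_aneuploidy <- function(cov, threshold = 1.5) {
  if (cov$genome <= 0) stop("genome-wide coverage is zero")
  ratio <- cov$per_chrom / cov$genome
  names(ratio)[ratio >= threshold | ratio <= 1 / threshold]
}

introgressed_bp <- function(set) {
  if (nrow(set$segments) == 0L) return(0)
  sum(set$segments$end_bp - set$segments$start_bp + 1)
}

# intersection width (bp, 1-based inclusive) of two segment data.frames
segments_intersection_bp <- function(a, b) {
  tot <- 0
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    sa <- a[a$chrom == ch, , drop = FALSE]
    sb <- b[b$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(sa))) {
      lo <- pmax(sa$start_bp[i], sb$start_bp)
      hi <- pmin(sa$end_bp[i], sb$end_bp)
      w <- hi - lo + 1
      tot <- tot + sum(w[w > 0])
    }
  }
  tot
}

#' Jaccard index of two strains' introgressed base pairs
#'
#' @param a,b [segment_set()] objects.
#' @return Numeric Jaccard index (intersection over union of introgressed
#'   bp); 0 when both are empty.
#' @export
segment_jaccard <- function(a, b) {
  inter <- segments_intersection_bp(a$segments, b$segments)
  union <- introgressed_bp(a) + introgressed_bp(b) - inter
  if (union == 0) 0 else inter / union
}

#' Find replicate NILs by introgression overlap
#'
#' Independent backcross lineages should carry distinct random
#' introgressions; a pair of strains whose introgressed base pairs are
#' nearly identical (Jaccard index at or above the threshold) indicates a
#' replicated lineage, of which only one should be analysed.
#'
#' @param sets list of [segment_set()] objects sharing one map and
#'   background.
#' @param jaccard_min minimum Jaccard index to report a pair (default 0.9).
#' @return data.frame `strain1`, `strain2`, `jaccard` (zero rows if none).
#' @export
find_replicate_nils <- function(sets, jaccard_min = 0.9) {
  n <- length(sets)
  out <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        jc <- segment_jaccard(sets[[i]], sets[[j]])
        if (jc >= jaccard_min)
          out[[length(out) + 1L]] <- data.frame(
            strain1 = sets[[i]]$strain, strain2 = sets[[j]]$strain,
            jaccard = jc, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(strain1 = character(), strain2 = character(),
                      jaccard = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
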