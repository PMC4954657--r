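# Independent oracles: brute-force or closed-form routes that do not share
# code with the implementations they check.

# log-probability of one explicit state path (states in 0/1)
path_loglik <- function(path, em, params) {
  lt <- log(params$transition)
  li <- log(params$initial)
  lp <- li[path[1] + 1] + em[path[1] + 1, 1]
  if (length(path) > 1) {
    for (t in 2:length(path))
      lp <- lp + lt[path[t - 1] + 1, path[t] + 1] + em[path[t] + 1, t]
  }
  lp
}

# all 0/1 paths of length T (cached), as a 2^T x T matrix
all_paths <- local({
  cache <- list()
  function(T_) {
    key <- as.character(T_)
    if (is.null(cache[[key]]))
      cache[[key]] <<- as.matrix(expand.grid(rep(list(0:1), T_)))
    cache[[key]]
  }
})

# exhaustive maximum over all state paths; returns max log-lik and the set
# of optimal paths
enum_viterbi <- function(em, params) {
  T_ <- ncol(em)
  paths <- all_paths(T_)
  lt <- log(params$transition)
  li <- log(params$initial)
  lp <- li[paths[, 1] + 1] + em[cbind(paths[, 1] + 1, 1)]
  if (T_ > 1) {
    for (t in 2:T_) {
      lp <- lp + lt[cbind(paths[, t - 1] + 1, paths[, t] + 1)] +
        em[cbind(paths[, t] + 1, t)]
    }
  }
  best <- max(lp)
  list(max_loglik = best,
       argmax = paths[lp >= best - 1e-9, , drop = FALSE])
}

# sequential SS by explicitly fitting the nested sequence of least-squares
# models on the expanding model matrix and differencing residual SS
nested_ss_oracle <- function(y, G) {
  dat <- as.data.frame(G)
  fml <- stats::as.formula(
    paste("~", paste(colnames(G), collapse = " * ")))
  mm <- stats::model.matrix(fml, dat)
  asgn <- attr(mm, "assign")
  rss <- function(X) {
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  ks <- sort(unique(asgn))
  r <- vapply(ks, function(k) rss(mm[, asgn <= k, drop = FALSE]),
              numeric(1))
  ss <- -diff(r)                       # term SS, skipping the intercept
  names(ss) <- attr(stats::terms(fml), "term.labels")
  c(ss, Residuals = r[length(r)])
}

# two-sided Fisher p by enumerating every feasible table with the observed
# margins and summing multinomial-style point probabilities computed from
# log-factorials
fisher_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2]); n <- sum(tab)
  lp_table <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
      lfactorial(n) - lfactorial(a) - lfactorial(b) - lfactorial(cc) -
      lfactorial(d)
  }
  av <- max(0, c1 - r2):min(r1, c1)
  lp <- vapply(av, lp_table, numeric(1))
  p_obs <- lp[match(tab[1, 1], av)]
  sum(exp(lp[lp <= p_obs + log(1 + 1e-7)]))
}

# per-bp introgression carrier counts on small coordinates
perbp_counts <- function(sets, chrom, max_pos) {
  counts <- integer(max_pos)
  for (s in sets) {
    seg <- s$segments[s$segments$chrom == chrom, , drop = FALSE]
    covered <- logical(max_pos)
    for (i in seq_len(nrow(seg)))
      covered[seg$start_bp[i]:seg$end_bp[i]] <- TRUE
    counts <- counts + covered
  }
  counts
}

# expand a region table back to per-bp counts
regions_to_perbp <- function(regions, chrom, max_pos) {
  counts <- integer(max_pos)
  r <- regions[regions$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(r)))
    counts[r$start_bp[i]:r$end_bp[i]] <- r$count[i]
  counts
}
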