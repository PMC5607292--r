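# Independent oracles used to check the package's own implementations.
# These deliberately share no code with the package: the aligner oracle is
# a top-down memoized recursion (the package aligner is bottom-up C++),
# the cutoff oracle is a plain loop, and the likelihood oracle is dense
# trapezoid integration.

# Optimal global alignment score by memoized recursion over (i, j) =
# (reference prefix, read prefix), with the same bisulfite scoring rule.
oracle_align_score <- function(read, ref, cpg_pos, match = 1,
                               mismatch = -1, gap = -2) {
  rb <- strsplit(ref, "")[[1]]
  qb <- strsplit(read, "")[[1]]
  L <- length(rb)
  m <- length(qb)
  memo <- matrix(NA_real_, L + 1, m + 1)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    val <- if (i == 0 && j == 0) {
      0
    } else {
      cand <- c()
      if (i > 0 && j > 0) {
        ok <- qb[j] == rb[i] || (i %in% cpg_pos && rb[i] == "C" && qb[j] == "T")
        cand <- c(cand, rec(i - 1, j - 1) + if (ok) match else mismatch)
      }
      if (i > 0) cand <- c(cand, rec(i - 1, j) + gap)
      if (j > 0) cand <- c(cand, rec(i, j - 1) + gap)
      max(cand)
    }
    memo[i + 1, j + 1] <<- val
    val
  }
  rec(L, m)
}

# Brute-force cutoff + diversity: a literal loop over patterns.
oracle_cutoff_diversity <- function(tab, cutoff) {
  depth <- sum(tab)
  kept <- character()
  for (p in names(tab)) {
    if (tab[[p]] / depth >= cutoff) kept <- c(kept, p)
  }
  list(retained = kept, diversity = length(kept))
}

# Dense-grid (trapezoid) integration of the NB x Gaussian integrand for one
# cluster, on [-halfwidth, halfwidth] * sigma around zero.
oracle_cluster_loglik <- function(y, eta, theta, sigma, n_grid = 40001,
                                  halfwidth = 12) {
  b <- seq(-halfwidth * sigma, halfwidth * sigma, length.out = n_grid)
  h <- vapply(b, function(bb) {
    sum(dnbinom(y, size = theta, mu = exp(eta + bb), log = TRUE)) +
      dnorm(bb, 0, sigma, log = TRUE)
  }, numeric(1))
  m <- max(h)
  db <- b[2] - b[1]
  m + log(sum(exp(h - m)) * db -
            0.5 * (exp(h[1] - m) + exp(h[length(h)] - m)) * db)
}

# Counts-level cohort generator at the longitudinal two-arm design scale:
# 4 patients per arm, 10 crypts per patient per timepoint at years
# (0, 1/3, 2), NB2 counts with a Gaussian patient intercept. Used for
# parameter-recovery and calibration experiments on the fitting code.
sim_count_cohort <- function(seed, rate_a = 1.3, rate_b = 1.0,
                             base_a = 2.2, base_b = 4.4,
                             theta = 20, sigma = 0.2,
                             n_patients = 4, n_crypts = 10) {
  set.seed(seed)
  tps <- rep(c(0, 1 / 3, 2), each = n_crypts)
  labs <- rep(c("t0", "t4m", "t2y"), each = n_crypts)
  rows <- list()
  for (g in c("placebo", "sulindac")) {
    rate <- if (g == "placebo") rate_a else rate_b
    base <- if (g == "placebo") base_a else base_b
    for (p in seq_len(n_patients)) {
      b <- rnorm(1, 0, sigma)
      mu <- exp(log(base) + log(rate) * tps + b)
      rows[[paste(g, p)]] <- data.frame(
        patient_id = sprintf("%s%02d", g, p), group = g,
        timepoint_years = tps, timepoint_label = labs,
        diversity = rnbinom(length(tps), size = theta, mu = mu),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Random pattern tables over up to 2^8 distinct 8-site patterns.
random_pattern_table <- function(n_patterns, max_count = 2000) {
  all_pat <- apply(expand.grid(rep(list(c("M", "U")), 8)), 1, paste,
                   collapse = "")
  pats <- sample(all_pat, n_patterns)
  stats::setNames(sample.int(max_count, n_patterns, replace = TRUE), pats)
}

# Tiny toy amplicon for aligner tests: random reference with a couple of
# CpG sites.
random_toy_amplicon <- function(len = 20) {
  repeat {
    b <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    cpg <- which(b == "C" & c(b[-1], "A") == "G")
    if (length(cpg) >= 1) break
  }
  list(ref = paste(b, collapse = ""), cpg = cpg)
}

# Mutate a string with k random substitutions.
mutate_string <- function(s, k) {
  b <- strsplit(s, "")[[1]]
  pos <- sample(seq_along(b), min(k, length(b)))
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  paste(b, collapse = "")
}
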