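test_that("degenerate niches stay homogeneous", {
  # no methylation errors: everyone keeps the ancestor pattern
  st <- simulate_niche(niche_params(mu_gain = 0, mu_loss = 0), 10, seed = 1)
  expect_equal(nrow(unique(st)), 1L)
  # single stem cell: diversity 1 always
  st1 <- simulate_niche(niche_params(n_stem = 1), 10, seed = 2)
  expect_equal(nrow(st1), 1L)
})

test_that("diversity drifts up with time and down with replacement rate", {
  mean_div <- function(rate, dur, seeds) {
    mean(vapply(seeds, function(s) {
      st <- simulate_niche(niche_params(replacement_rate = rate), dur,
                           seed = s)
      nrow(unique(st))
    }, numeric(1)))
  }
  seeds <- 1:250
  d_short <- mean_div(1, 0.3, seeds)
  d_long <- mean_div(1, 3, seeds)
  se <- 6 / sqrt(length(seeds))  # conservative bound on the MC error
  expect_gt(d_long, d_short - se)
  expect_gt(d_long - d_short, 0.3)  # clearly rising, not just noise

  d_slow <- mean_div(0.5, 3, seeds)
  d_fast <- mean_div(8, 3, seeds)
  expect_lt(d_fast, d_slow)
})

test_that("fast replacement homogenizes toward a recent common ancestor", {
  seeds <- 1:200
  div_at <- function(rate) {
    mean(vapply(seeds, function(s) {
      st <- simulate_niche(niche_params(replacement_rate = rate), 2, seed = s)
      nrow(unique(st))
    }, numeric(1)))
  }
  expect_lt(div_at(50), 1.8)   # near-instant succession: ~1 pattern
  expect_gt(div_at(0.5), div_at(50))
})

test_that("percent methylation rises with burn-in under gain-only drift", {
  mean_pm <- function(tb) {
    mean(vapply(1:150, function(s) {
      p <- niche_params(mu_gain = 0.1, mu_loss = 0, ancestor_meth = 0,
                        t_burnin = tb)
      mean(simulate_niche(p, tb, seed = s))
    }, numeric(1)))
  }
  pms <- c(mean_pm(0.5), mean_pm(2), mean_pm(8))
  expect_true(all(diff(pms) > 0))
})

test_that("sequencing truth is conserved at zero error rates", {
  spec <- csx_synthetic_spec(2)
  perfect <- assay_params(p_conversion_failure = 0,
                          p_inappropriate_conversion = 0, p_seq_error = 0,
                          depth_meanlog = log(500), depth_sdlog = 0.3)
  st <- simulate_niche(niche_params(), 2, seed = 21)
  sq <- sequence_crypt(st, perfect, spec,
                       barcode = names(spec$barcode_map)[1], seed = 22)
  # read-weighted true pattern frequencies equal the emitted read patterns
  res <- call_reads(sq$reads$sequence, spec)
  got <- tabulate_patterns(res$calls$pattern[res$calls$status == "passed"])
  want <- tabulate_patterns(sq$truth$source_pattern)
  expect_equal(got, want)
  expect_equal(sq$truth$depth, nrow(sq$reads))
})

test_that("cohort simulation is seed-reproducible and has the design shape", {
  des <- cohort_design(n_patients = 2, n_crypts = 2,
                       assay = assay_params(depth_meanlog = log(60),
                                            depth_sdlog = 0.2))
  s1 <- simulate_cohort(des, seed = 5)
  s2 <- simulate_cohort(des, seed = 5)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth_crypts, s2$truth_crypts)
  expect_identical(s1$polyps, s2$polyps)

  # default design: 2 groups x 4 patients x 3 timepoints x 10 crypts
  full <- simulate_cohort(cohort_design(), seed = 1, reads = FALSE)
  expect_equal(nrow(full$truth_crypts), 240L)
  expect_equal(nrow(full$sample_sheet), 240L)
  expect_equal(length(unique(full$sample_sheet$barcode)), 240L)
  expect_equal(nrow(full$patients), 8L)
  # polyp-free at baseline, counts accumulate in the placebo arm
  expect_true(all(full$polyps$polyps[full$polyps$timepoint_years == 0] == 0))
})

test_that("treated and untreated arms diverge in the expected direction", {
  # truth-level contrast: fitted placebo rate/yr exceeds the treated rate
  # in nearly all cohort replicates
  wins <- 0
  n_rep <- 25
  for (s in seq_len(n_rep)) {
    sim <- simulate_cohort(cohort_design(), seed = 1000 + s, reads = FALSE)
    tc <- sim$truth_crypts
    tc$diversity <- tc$true_diversity
    fit <- suppressWarnings(fit_nb_mixed(tc, "diversity", "continuous"))
    r <- fit$derived
    if (r$rate_per_year[r$group == "placebo"] >
        r$rate_per_year[r$group == "sulindac"]) wins <- wins + 1
  }
  expect_gte(wins / n_rep, 0.9)
})
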