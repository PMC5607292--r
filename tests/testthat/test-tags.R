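test_that("pattern tabulation counts exact multisets", {
  tab <- tabulate_patterns(c(rep("MMMMMMMM", 3), "UUUUUUUU", NA))
  expect_equal(tab, c(MMMMMMMM = 3L, UUUUUUUU = 1L))
  expect_equal(length(tabulate_patterns(character())), 0L)
})

test_that("frequency cutoff retains at the inclusive boundary", {
  ret <- apply_frequency_cutoff(c(A = 990, B = 9, C = 1), 0.01)
  expect_equal(names(ret), "A")
  expect_equal(compute_diversity(ret), 1L)
  expect_equal(sum(ret) + sum(attr(ret, "discarded")), 1000)

  # exactly 1% survives
  ret2 <- apply_frequency_cutoff(c(A = 99, B = 1), 0.01)
  expect_setequal(names(ret2), c("A", "B"))

  # cutoff 0: identity
  tab <- c(A = 5, B = 1, C = 1)
  expect_equal(sort(apply_frequency_cutoff(tab, 0)), sort(tab))

  # 100 equal patterns at depth 10000: each exactly 1%, all retained
  tab100 <- stats::setNames(rep(100L, 100), sprintf("p%03d", 1:100))
  expect_equal(compute_diversity(apply_frequency_cutoff(tab100, 0.01)), 100L)
  # 256 equal patterns cannot all reach 1%: all fall below and are removed
  tab256 <- stats::setNames(rep(100L, 256), sprintf("q%03d", 1:256))
  expect_warning(
    expect_equal(compute_diversity(apply_frequency_cutoff(tab256, 0.01)), 0L),
    "degenerate")

  # nothing retained: diversity 0 with a warning
  expect_warning(d0 <- compute_diversity(
    apply_frequency_cutoff(c(A = 1), 0.5)[0]), "degenerate")
  expect_equal(d0, 0L)
})

test_that("cutoff/diversity match the brute-force oracle on random tables", {
  set.seed(99)
  for (i in 1:400) {
    tab <- random_pattern_table(sample(1:256, 1))
    cutoff <- sample(c(0, 0.001, 0.01, 0.05, 0.2), 1)
    ret <- apply_frequency_cutoff(tab, cutoff)
    want <- oracle_cutoff_diversity(tab, cutoff)
    expect_setequal(names(ret), want$retained)
    expect_equal(length(ret), want$diversity)
  }
})

test_that("percent methylation computes site fractions under both weightings", {
  expect_equal(compute_percent_methylation(c(MMUUUUUU = 10, UUUUUUUU = 10)),
               12.5)
  expect_equal(compute_percent_methylation(c(MMMMMMMM = 7)), 100)
  # equal counts: weightings agree
  tab <- c(MMMMMMMM = 1, UUUUUUUU = 1)
  expect_equal(compute_percent_methylation(tab, "reads"), 50)
  expect_equal(compute_percent_methylation(tab, "patterns"), 50)
  # unequal counts: they differ
  tab2 <- c(MMMMMMMM = 3, UUUUUUUU = 1)
  expect_equal(compute_percent_methylation(tab2, "reads"), 75)
  expect_equal(compute_percent_methylation(tab2, "patterns"), 50)
})

test_that("diversity is non-increasing in the cutoff and percent methylation is scale-free", {
  set.seed(7)
  for (i in 1:50) {
    tab <- random_pattern_table(sample(2:40, 1))
    cuts <- sort(runif(5, 0, 0.3))
    divs <- vapply(cuts, function(cf) {
      length(apply_frequency_cutoff(tab, cf))
    }, integer(1))
    expect_true(all(diff(divs) <= 0))
    # rescaling read counts changes nothing
    expect_equal(compute_percent_methylation(tab * 7L),
                 compute_percent_methylation(tab))
    expect_equal(names(apply_frequency_cutoff(tab * 7L, 0.02)),
                 names(apply_frequency_cutoff(tab, 0.02)))
  }
})

test_that("complementing all calls mirrors percent methylation and fixes diversity", {
  set.seed(13)
  for (i in 1:20) {
    tab <- random_pattern_table(sample(2:30, 1))
    flipped <- stats::setNames(as.integer(tab), chartr("MU", "UM", names(tab)))
    expect_equal(compute_percent_methylation(flipped),
                 100 - compute_percent_methylation(tab))
    expect_equal(length(apply_frequency_cutoff(flipped, 0.01)),
                 length(apply_frequency_cutoff(tab, 0.01)))
  }
})

test_that("crypt profiles aggregate calls and flag degenerate crypts", {
  calls <- data.frame(
    read_id = sprintf("r%02d", 1:7),
    sample_id = c(rep("c1", 5), "c2", "c2"),
    status = c(rep("passed", 5), "failed_conversion_control",
               "failed_conversion_control"),
    pattern = c(rep("MMMMMMMM", 4), "UUUUUUUU", NA, NA),
    stringsAsFactors = FALSE)
  sheet <- data.frame(sample_id = c("c1", "c2"), patient_id = "p1",
                      group = "placebo", timepoint_label = "t0",
                      timepoint_years = 0, stringsAsFactors = FALSE)
  expect_message(prof <- crypt_profiles(calls, sheet), "zero passed reads")
  expect_equal(prof$depth, c(5L, 0L))
  expect_equal(prof$diversity[1], 2L)
  expect_equal(prof$percent_methylation[1], 100 * (4 * 8) / (5 * 8))
  expect_false(prof$ok[2])
})

test_that("depth sensitivity filter keeps crypts at or above the threshold", {
  crypts <- data.frame(sample_id = letters[1:4],
                       depth = c(4, 999, 1000, 49360))
  expect_message(kept <- depth_sensitivity_filter(crypts, 1000),
                 "2 of 4")
  expect_equal(attr(kept, "retained"), c(kept = 2L, total = 4L))
  expect_message(all4 <- depth_sensitivity_filter(crypts, 0), "4 of 4")
  expect_equal(nrow(all4), 4L)
})

test_that("clone subsampling is seeded and bounded by NGS diversity", {
  expect_equal(clone_subsample(rep("MMMMMMMM", 10), seed = 1)$diversity, 1L)
  pats <- c(rep("MMMMMMMM", 400), rep("UUUUUUUU", 300), rep("MUMUMUMU", 250),
            rep("UUMMUUMM", 50))
  s1 <- clone_subsample(pats, seed = 42)
  s2 <- clone_subsample(pats, seed = 42)
  expect_identical(s1$clone_patterns, s2$clone_patterns)

  full_div <- length(apply_frequency_cutoff(tabulate_patterns(pats), 0.01))
  divs <- vapply(1:200, function(s) clone_subsample(pats, seed = s)$diversity,
                 integer(1))
  expect_lte(mean(divs), full_div)
  expect_gt(mean(divs), 1)
  expect_warning(clone_subsample(rep("MMMMMMMM", 4), n_clones = 10),
                 "taking all")
})
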