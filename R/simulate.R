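#' Stem-cell niche parameters
#'
#' Parameters of the neutral-drift (Moran-type) model of a crypt stem-cell
#' niche. Two processes run side by side. Lineage replacement: events
#' arrive at rate `replacement_rate * n_stem` per year (so
#' `replacement_rate` is per stem cell per year); each event kills a
#' uniformly chosen stem cell and replaces it with an exact copy of
#' another, which is what homogenizes the niche (niche succession is this
#' process run to fixation). Methylation drift: every cell continuously
#' accumulates methylation errors over the divisions of its own lineage,
#' modeled per CpG site as a two-state Markov process with gain rate
#' `mu_gain` (per unmethylated site per year) and loss rate `mu_loss`
#' (per methylated site per year).
#'
#' Keeping error accrual on the time axis rather than tying it to
#' replacement events matters: stem cells divide continuously regardless
#' of how often lineages replace one another, so a higher replacement rate
#' prunes diversity faster without adding errors faster, which is exactly
#' why crypts with fewer unique patterns are read as having undergone a
#' more recent niche succession.
#'
#' The niche is initialized from a single ancestor whose pattern carries
#' each site methylated with probability `ancestor_meth` (the accumulated
#' mitotic age of the patient at the last niche succession), and then
#' drifts for `t_burnin` years before observation, representing the time
#' since that succession. Defaults are calibrated so that simulated
#' baseline crypts show a handful of retained patterns and roughly 15-25%
#' methylation, the magnitudes seen in crypt assays; they are calibration
#' choices, not measured biology.
#'
#' @param n_stem stem cells per niche.
#' @param replacement_rate replacements per stem cell per year.
#' @param mu_gain,mu_loss per-site methylation gain/loss rate per year.
#' @param n_cpg number of CpG sites (default 8).
#' @param t_burnin years of drift since the founding ancestor.
#' @param ancestor_meth per-site methylation probability of the founding
#'   ancestor pattern.
#' @return list of class `niche_params`.
#' @export
niche_params <- function(n_stem = 6, replacement_rate = 1.0,
                         mu_gain = 0.07, mu_loss = 0.28, n_cpg = 8,
                         t_burnin = 0.3, ancestor_meth = 0.22) {
  stopifnot(n_stem >= 1, replacement_rate >= 0,
            mu_gain >= 0, mu_loss >= 0,
            n_cpg >= 1, t_burnin >= 0,
            ancestor_meth >= 0, ancestor_meth <= 1)
  structure(list(n_stem = as.integer(n_stem),
                 replacement_rate = replacement_rate,
                 mu_gain = mu_gain, mu_loss = mu_loss,
                 n_cpg = as.integer(n_cpg), t_burnin = t_burnin,
                 ancestor_meth = ancestor_meth),
            class = "niche_params")
}

#' Simulate neutral drift in one stem-cell niche
#'
#' Runs the niche process for `duration_years`: Moran replacement events
#' (Poisson(`replacement_rate * n_stem * duration_years`) of them, at
#' uniform times) interleaved with continuous per-site methylation drift.
#' Between events each cell's sites evolve independently under the
#' two-state gain/loss Markov process, using the exact finite-time
#' transition probabilities, so no time discretization error is incurred.
#' If `state` is NULL the niche starts from a single ancestor pattern (all
#' cells identical).
#'
#' @param params a [niche_params()].
#' @param duration_years years of drift.
#' @param seed optional integer seed.
#' @param state optional starting niche state (logical matrix, cells x
#'   sites) to continue an existing niche.
#' @return logical matrix `n_stem x n_cpg` (TRUE = methylated), with
#'   attribute `ancestor` (the founding pattern).
#' @examples
#' st <- simulate_niche(niche_params(mu_gain = 0, mu_loss = 0), 5, seed = 1)
#' nrow(unique(st))  # 1: no errors, all cells share the ancestor pattern
#' @export
simulate_niche <- function(params, duration_years, seed = NULL,
                           state = NULL) {
  stopifnot(inherits(params, "niche_params"), duration_years >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_stem
  if (is.null(state)) {
    ancestor <- stats::runif(params$n_cpg) < params$ancestor_meth
    state <- matrix(ancestor, nrow = n, ncol = params$n_cpg, byrow = TRUE)
  } else {
    ancestor <- attr(state, "ancestor")
    if (is.null(ancestor)) ancestor <- state[1, ]
  }
  n_events <- stats::rpois(1, params$replacement_rate * n * duration_years)
  times <- sort(stats::runif(n_events, 0, duration_years))
  bounds <- c(0, times, duration_years)
  for (k in seq_len(n_events + 1L)) {
    state <- drift_sites(state, bounds[k + 1L] - bounds[k], params)
    if (k <= n_events && n > 1) {
      dies <- sample.int(n, 1)
      parent <- sample.int(n - 1L, 1)
      if (parent >= dies) parent <- parent + 1L
      state[dies, ] <- state[parent, ]
    }
  }
  attr(state, "ancestor") <- ancestor
  state
}

# Exact two-state Markov transition over dt for every cell x site:
# gain rate a = mu_gain (U -> M), loss rate b = mu_loss (M -> U).
drift_sites <- function(state, dt, params) {
  if (dt <= 0) return(state)
  a <- params$mu_gain
  b <- params$mu_loss
  if (a + b == 0) return(state)
  decay <- exp(-(a + b) * dt)
  p_u_to_m <- a / (a + b) * (1 - decay)
  p_m_to_u <- b / (a + b) * (1 - decay)
  u <- matrix(stats::runif(length(state)), nrow = nrow(state))
  flip <- (!state & u < p_u_to_m) | (state & u < p_m_to_u)
  st <- xor(state, flip)
  attributes(st) <- attributes(state)
  st
}

# True summaries of a niche state
niche_truth <- function(state) {
  pat <- apply(state, 1L, function(r) paste(ifelse(r, "M", "U"),
                                            collapse = ""))
  tab <- table(pat)
  list(true_diversity = length(tab),
       true_percent_methylation = 100 * mean(state),
       cell_patterns = pat)
}

#' Assay noise parameters
#'
#' Error layer applied when a niche is "sequenced". Read depth per crypt is
#' lognormal (floored at 1, clipped at `depth_max`), emulating the wide
#' per-crypt depth variation of amplicon runs. Bisulfite conversion failure
#' is modeled per molecule: with probability `p_conversion_failure` a read
#' derives from an incompletely converted molecule, in which each
#' unmethylated cytosine (controls and unmethylated CpGs) independently
#' escapes conversion and reads C with probability `conv_retention` -
#' conversion failure is strongly correlated within a molecule, which is
#' what makes the control sites informative. `p_inappropriate_conversion`
#' is a per-site chance that a methylated CpG reads T, and `p_seq_error` a
#' per-base substitution rate applied across the whole read.
#'
#' @param depth_meanlog,depth_sdlog lognormal read-depth parameters.
#' @param depth_max depth clip (default 50000).
#' @param p_conversion_failure per-read incomplete-conversion probability.
#' @param conv_retention within a failed molecule, per-site probability an
#'   unmethylated C escapes conversion.
#' @param p_inappropriate_conversion per-site probability a methylated CpG
#'   reads as T.
#' @param p_seq_error per-base substitution error rate.
#' @return list of class `assay_params`.
#' @export
assay_params <- function(depth_meanlog = log(5000), depth_sdlog = 1.4,
                         depth_max = 50000,
                         p_conversion_failure = 0.01, conv_retention = 0.5,
                         p_inappropriate_conversion = 0.002,
                         p_seq_error = 0.001) {
  p <- c(p_conversion_failure, conv_retention, p_inappropriate_conversion,
         p_seq_error)
  stopifnot(all(p >= 0 & p <= 1), depth_max >= 1)
  structure(list(depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 depth_max = depth_max,
                 p_conversion_failure = p_conversion_failure,
                 conv_retention = conv_retention,
                 p_inappropriate_conversion = p_inappropriate_conversion,
                 p_seq_error = p_seq_error),
            class = "assay_params")
}

# Render an M/U pattern onto the converted reference: CpG position i gets C
# if methylated, T if not.
render_pattern <- function(pattern, cref) {
  spec <- cref$source
  b <- strsplit(cref$converted_seq, "")[[1]]
  st <- strsplit(pattern, "")[[1]]
  b[spec$cpg_positions] <- ifelse(st == "M", "C", "T")
  paste(b, collapse = "")
}

#' Sequence one crypt in silico
#'
#' Draws a read depth, samples a stem cell uniformly per read, renders its
#' epigenotype onto the converted reference, applies the assay noise layer
#' of [assay_params()], and prepends the crypt barcode.
#'
#' @param state niche state from [simulate_niche()].
#' @param assay an [assay_params()].
#' @param spec the `amplicon_spec` (must carry at least one barcode if
#'   `barcode` is not given).
#' @param barcode barcode sequence to prepend (default: the assay's first).
#' @param crypt_id identifier used in read names.
#' @param seed optional integer seed.
#' @return list with `reads` (data.frame `read_id`, `sequence`), and
#'   `truth` (depth, source cell per read, true diversity / percent
#'   methylation and the true pattern mixture).
#' @export
sequence_crypt <- function(state, assay, spec, barcode = NULL,
                           crypt_id = "crypt", seed = NULL) {
  stopifnot(inherits(assay, "assay_params"), inherits(spec, "amplicon_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(barcode)) {
    if (!length(spec$barcode_map)) stop("no barcode available")
    barcode <- names(spec$barcode_map)[1]
  }
  cref <- convert_reference(spec)
  depth <- min(max(1, round(stats::rlnorm(1, assay$depth_meanlog,
                                          assay$depth_sdlog))),
               assay$depth_max)
  tr <- niche_truth(state)
  cells <- sample.int(nrow(state), depth, replace = TRUE)
  templates <- vapply(tr$cell_patterns, render_pattern, character(1),
                      cref = cref)
  seqs <- unname(templates[cells])
  L <- nchar(cref$converted_seq)
  spec1 <- cref$source

  # positions of unmethylated (converted) cytosines per cell: controls plus
  # U CpGs; used for the per-molecule conversion-failure model
  u_sites <- lapply(seq_len(nrow(state)), function(i) {
    c(spec1$control_positions, spec1$cpg_positions[!state[i, ]])
  })
  m_sites <- lapply(seq_len(nrow(state)), function(i) {
    spec1$cpg_positions[state[i, ]]
  })

  subst <- function(s, pos, ch) {
    for (k in seq_along(pos)) substr(s, pos[k], pos[k]) <- ch[k]
    s
  }
  other_bases <- c("A", "C", "G", "T")

  # incomplete conversion (per molecule)
  failed <- which(stats::runif(depth) < assay$p_conversion_failure)
  for (i in failed) {
    us <- u_sites[[cells[i]]]
    hit <- us[stats::runif(length(us)) < assay$conv_retention]
    if (length(hit)) seqs[i] <- subst(seqs[i], hit, rep("C", length(hit)))
  }
  # inappropriate conversion of methylated CpGs (per site); vectorized per
  # source cell, touching only the (rare) reads that draw a hit
  if (assay$p_inappropriate_conversion > 0) {
    for (cell in unique(cells)) {
      ms <- m_sites[[cell]]
      if (!length(ms)) next
      idx <- which(cells == cell)
      hitmat <- matrix(stats::runif(length(idx) * length(ms)) <
                         assay$p_inappropriate_conversion,
                       nrow = length(idx))
      for (r in which(rowSums(hitmat) > 0L)) {
        hit <- ms[hitmat[r, ]]
        seqs[idx[r]] <- subst(seqs[idx[r]], hit, rep("T", length(hit)))
      }
    }
  }
  # sequencing substitution errors (per base)
  if (assay$p_seq_error > 0) {
    n_err <- stats::rbinom(depth, L, assay$p_seq_error)
    for (i in which(n_err > 0)) {
      pos <- sample.int(L, n_err[i])
      for (p in pos) {
        cur <- substr(seqs[i], p, p)
        substr(seqs[i], p, p) <- sample(setdiff(other_bases, cur), 1)
      }
    }
  }

  reads <- data.frame(
    read_id = sprintf("%s_r%06d", crypt_id, seq_len(depth)),
    sequence = paste0(barcode, seqs),
    stringsAsFactors = FALSE
  )
  mixture <- table(tr$cell_patterns[cells])
  list(reads = reads,
       truth = list(crypt_id = crypt_id, depth = depth,
                    source_cell = cells,
                    source_pattern = tr$cell_patterns[cells],
                    true_diversity = tr$true_diversity,
                    true_percent_methylation = tr$true_percent_methylation,
                    mixture = mixture))
}

#' Cohort design for the crypt simulator
#'
#' Mirrors the longitudinal two-arm study layout: two treatment groups
#' (placebo, sulindac), `n_patients` per group, `n_crypts` crypts sampled
#' per patient at each of three timepoints (0, 4 months, 2 years). The
#' treatment is modeled as a multiplier on the stem-cell replacement rate
#' from the start of treatment onward; each sampled crypt carries
#' pre-treatment drift (`t_burnin` of [niche_params()]) at the baseline
#' rate, then drifts for the sampling time at its group's rate. Per-patient
#' polyp burdens follow a linear-in-time Poisson model with a per-patient
#' slope drawn around the group mean; everyone starts polyp-free.
#'
#' @param n_patients patients per group (default 4).
#' @param n_crypts crypts per patient per timepoint (default 10).
#' @param timepoints_years sampling times (default `c(0, 1/3, 2)`).
#' @param niche baseline [niche_params()].
#' @param assay an [assay_params()].
#' @param sulindac_replacement_multiplier replacement-rate multiplier under
#'   treatment (default 4).
#' @param polyp_slope_mean named mean polyp accrual per year by group.
#' @param polyp_slope_cv coefficient of variation of the per-patient slope.
#' @param ages named list of baseline ages per group (recycled/truncated to
#'   `n_patients`).
#' @return list of class `cohort_design`.
#' @export
cohort_design <- function(n_patients = 4, n_crypts = 10,
                          timepoints_years = c(0, 1 / 3, 2),
                          niche = niche_params(), assay = assay_params(),
                          sulindac_replacement_multiplier = 4,
                          polyp_slope_mean = c(placebo = 7, sulindac = 0.4),
                          polyp_slope_cv = 0.6,
                          ages = list(placebo = c(8, 9, 14, 16),
                                      sulindac = c(8, 9, 9, 14))) {
  stopifnot(n_patients >= 1, n_crypts >= 1, length(timepoints_years) >= 2)
  structure(list(groups = c("placebo", "sulindac"),
                 n_patients = as.integer(n_patients),
                 n_crypts = as.integer(n_crypts),
                 timepoints_years = timepoints_years,
                 niche = niche, assay = assay,
                 sulindac_replacement_multiplier = sulindac_replacement_multiplier,
                 polyp_slope_mean = polyp_slope_mean,
                 polyp_slope_cv = polyp_slope_cv,
                 ages = ages),
            class = "cohort_design")
}

timepoint_label <- function(years) {
  vapply(years, function(y) {
    if (abs(y) < 1e-9) "t0"
    else if (abs(y - 1 / 3) < 1e-9) "t4m"
    else sprintf("t%gy", y)
  }, character(1))
}

# Per-crypt substream seed: a fixed affine counter scheme on the global
# seed, kept below 2^31 so it is a valid R seed everywhere.
crypt_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter * 1009) %% 2147483629)
}

#' Simulate a full longitudinal cohort
#'
#' Generates every crypt of a [cohort_design()]: niche drift, in-silico
#' sequencing (optional), a sample sheet, per-patient polyp counts and
#' ages, and ground-truth tables. All randomness derives from `seed` via a
#' fixed per-crypt counter scheme, so any crypt can be regenerated in
#' isolation and the whole dataset is byte-reproducible.
#'
#' @param design a [cohort_design()].
#' @param seed integer master seed.
#' @param reads if FALSE, skip read generation and emit truth tables only
#'   (fast path for design-level experiments).
#' @return list with `spec` (the assay incl. per-crypt barcodes), `reads`
#'   (data.frame of all reads; NULL when `reads = FALSE`), `sample_sheet`,
#'   `patients` (patient_id, group, age, polyp slope), `polyps` (long
#'   table: patient_id, timepoint_label, timepoint_years, polyps),
#'   `truth_crypts` and `truth_reads` (NULL when `reads = FALSE`).
#' @export
simulate_cohort <- function(design = cohort_design(), seed = 1,
                            reads = TRUE) {
  stopifnot(inherits(design, "cohort_design"))
  groups <- design$groups
  tps <- design$timepoints_years
  n_crypt_total <- length(groups) * design$n_patients * length(tps) *
    design$n_crypts
  spec <- csx_synthetic_spec(0)

  # patient-level draws (ages, polyp slopes) from the master seed
  set.seed(as.integer(seed))
  patients <- do.call(rbind, lapply(groups, function(g) {
    ag <- rep_len(design$ages[[g]], design$n_patients)
    sl_mean <- design$polyp_slope_mean[[g]]
    cv <- design$polyp_slope_cv
    shape <- 1 / cv^2
    slope <- stats::rgamma(design$n_patients, shape = shape,
                           rate = shape / sl_mean)
    data.frame(patient_id = sprintf("%s%02d", toupper(substr(g, 1, 1)),
                                    seq_len(design$n_patients)),
               group = g, age = ag, polyp_slope = slope,
               stringsAsFactors = FALSE)
  }))
  polyps <- do.call(rbind, lapply(seq_len(nrow(patients)), function(i) {
    data.frame(patient_id = patients$patient_id[i],
               group = patients$group[i],
               timepoint_label = timepoint_label(tps),
               timepoint_years = tps,
               polyps = stats::rpois(length(tps),
                                     patients$polyp_slope[i] * tps),
               stringsAsFactors = FALSE)
  }))

  sheet <- list(); truth <- list(); read_blocks <- list()
  truth_reads <- list()
  barcodes <- barcode_kmer(seq_len(n_crypt_total))
  counter <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    mult <- if (g == "sulindac") design$sulindac_replacement_multiplier else 1
    np <- design$niche
    np_treated <- niche_params(
      n_stem = np$n_stem, replacement_rate = np$replacement_rate * mult,
      mu_gain = np$mu_gain, mu_loss = np$mu_loss, n_cpg = np$n_cpg,
      t_burnin = np$t_burnin, ancestor_meth = np$ancestor_meth)
    for (pi in seq_len(design$n_patients)) {
      pid <- patients$patient_id[patients$group == g][pi]
      for (ti in seq_along(tps)) {
        t_yr <- tps[ti]
        for (ci in seq_len(design$n_crypts)) {
          counter <- counter + 1L
          cid <- sprintf("%s_%s_c%02d", pid, timepoint_label(t_yr), ci)
          set.seed(crypt_seed(seed, counter))
          st <- simulate_niche(np, np$t_burnin)
          if (t_yr > 0) st <- simulate_niche(np_treated, t_yr, state = st)
          tr <- niche_truth(st)
          row <- data.frame(
            sample_id = cid, patient_id = pid, group = g,
            timepoint_label = timepoint_label(t_yr),
            timepoint_years = t_yr, barcode = barcodes[counter],
            stringsAsFactors = FALSE)
          sheet[[counter]] <- row
          if (reads) {
            sq <- sequence_crypt(st, design$assay, spec,
                                 barcode = barcodes[counter], crypt_id = cid)
            read_blocks[[counter]] <- sq$reads
            truth_reads[[counter]] <- data.frame(
              read_id = sq$reads$read_id, sample_id = cid,
              source_pattern = sq$truth$source_pattern,
              stringsAsFactors = FALSE)
            depth <- sq$truth$depth
          } else {
            depth <- NA_integer_
          }
          truth[[counter]] <- data.frame(
            sample_id = cid, patient_id = pid, group = g,
            timepoint_label = timepoint_label(t_yr), timepoint_years = t_yr,
            depth = depth,
            true_diversity = tr$true_diversity,
            true_percent_methylation = tr$true_percent_methylation,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  sheet <- do.call(rbind, sheet)
  spec$barcode_map <- stats::setNames(sheet$sample_id, sheet$barcode)
  list(spec = spec,
       reads = if (reads) do.call(rbind, read_blocks) else NULL,
       sample_sheet = sheet,
       patients = patients,
       polyps = polyps,
       truth_crypts = do.call(rbind, truth),
       truth_reads = if (reads) do.call(rbind, truth_reads) else NULL)
}
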