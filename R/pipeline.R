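# End-to-end pipeline drivers: simulate -> process -> analyze. These are
# thin orchestration layers over the module functions; every run directory
# gets its parameters, seed and input checksums written alongside the
# outputs so a run is reproducible from what it leaves behind.

write_tsv <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a crypt-level table
#'
#' The crypt-level TSV is the interchange format between processing and
#' analysis (and the ingestion format for externally derived per-crypt
#' tables). Required columns: `sample_id` (or `crypt_id`), `patient_id`,
#' `group`, `timepoint_label`, `timepoint_years`, `diversity`,
#' `percent_methylation`; `depth` is optional but enables the depth
#' sensitivity re-analysis.
#'
#' @param path TSV path (lines starting with `#` are metadata).
#' @return data.frame.
#' @export
read_crypt_table <- function(path) {
  d <- read_tsv(path)
  if (!"sample_id" %in% names(d) && "crypt_id" %in% names(d)) {
    d$sample_id <- d$crypt_id
  }
  need <- c("sample_id", "patient_id", "group", "timepoint_label",
            "timepoint_years", "diversity", "percent_methylation")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("crypt table lacks column(s): ", paste(miss, collapse = ", "))
  }
  d
}

provenance <- function(outdir, seed, params = list(), inputs = character()) {
  prov <- list(
    package = "crypttags",
    version = as.character(utils::packageVersion("crypttags")),
    r_version = R.version.string,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params,
    input_checksums = as.list(tools::md5sum(inputs[file.exists(inputs)]))
  )
  yaml::write_yaml(prov, file.path(outdir, "params.yaml"))
}

#' Simulate a cohort dataset to disk
#'
#' Writes `reads.fastq.gz`, `reference.fasta`, `assay.yaml`,
#' `sample_sheet.tsv`, `patients.tsv`, `polyps.tsv`, `truth_crypts.tsv`,
#' `truth_reads.tsv` and `params.yaml` under `outdir`.
#'
#' @param outdir output directory (created if needed).
#' @param design a [cohort_design()].
#' @param seed master seed.
#' @param quick if TRUE, shrink to 2 patients x 2 crypts with modest depth
#'   for a seconds-scale smoke dataset.
#' @return `outdir`, invisibly.
#' @export
run_simulate <- function(outdir, design = cohort_design(), seed = 1,
                         quick = FALSE) {
  if (quick) {
    design <- cohort_design(
      n_patients = 2, n_crypts = 2,
      timepoints_years = design$timepoints_years,
      niche = design$niche,
      assay = assay_params(depth_meanlog = log(200), depth_sdlog = 0.5),
      sulindac_replacement_multiplier = design$sulindac_replacement_multiplier)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(design, seed = seed, reads = TRUE)
  write_fastq(sim$reads, file.path(outdir, "reads.fastq.gz"))
  writeLines(c(">CSX-synthetic", sim$spec$reference_seq),
             file.path(outdir, "reference.fasta"))
  yaml::write_yaml(list(
    name = sim$spec$name,
    coordinate_base = 1,
    cpg_positions = sim$spec$cpg_positions,
    control_positions = sim$spec$control_positions,
    primer_fwd = sim$spec$primer_fwd,
    primer_rev = sim$spec$primer_rev,
    barcodes = as.list(sim$spec$barcode_map)
  ), file.path(outdir, "assay.yaml"))
  write_tsv(sim$sample_sheet, file.path(outdir, "sample_sheet.tsv"),
            meta = sprintf("simulated cohort, seed %d", seed))
  write_tsv(sim$patients, file.path(outdir, "patients.tsv"))
  write_tsv(sim$polyps, file.path(outdir, "polyps.tsv"))
  write_tsv(sim$truth_crypts, file.path(outdir, "truth_crypts.tsv"))
  write_tsv(sim$truth_reads, file.path(outdir, "truth_reads.tsv"))
  provenance(outdir, seed, params = list(
    n_patients = design$n_patients, n_crypts = design$n_crypts,
    timepoints_years = design$timepoints_years,
    niche = unclass(design$niche), assay = unclass(design$assay),
    sulindac_replacement_multiplier = design$sulindac_replacement_multiplier))
  invisible(outdir)
}

#' Process raw reads into a crypt-level table
#'
#' Demultiplex, align, filter, genotype, tabulate, apply the frequency
#' cutoff and write the crypt-level table plus the per-read call table and
#' the filter ledger.
#'
#' @param fastq FASTQ path.
#' @param reference reference FASTA path.
#' @param assay_config assay YAML path (sites, barcodes).
#' @param sample_sheet sample sheet TSV path.
#' @param outdir output directory.
#' @param cutoff frequency cutoff (default 0.01).
#' @param config a [process_config()].
#' @param seed recorded in provenance (processing is deterministic).
#' @return the crypt-level data.frame, invisibly.
#' @export
run_process <- function(fastq, reference, assay_config, sample_sheet,
                        outdir, cutoff = 0.01, config = process_config(),
                        seed = 0) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  spec <- read_amplicon_spec(reference, assay_config)
  sheet <- read_tsv(sample_sheet)
  orphans <- setdiff(spec$barcode_map, sheet$sample_id)
  if (length(orphans)) {
    stop("barcodes map to samples absent from the sample sheet: ",
         paste(utils::head(orphans, 10), collapse = ", "))
  }
  reads <- read_fastq(fastq)
  res <- call_reads(reads$sequence, spec, config, read_ids = reads$read_id)
  crypts <- crypt_profiles(res$calls, sheet, cutoff_fraction = cutoff)
  write_tsv(res$calls, file.path(outdir, "read_calls.tsv"))
  write_tsv(data.frame(reason = names(res$ledger),
                       reads = as.integer(res$ledger)),
            file.path(outdir, "filter_ledger.tsv"),
            meta = sprintf("total input reads: %d", attr(res$ledger, "total")))
  write_tsv(crypts, file.path(outdir, "crypts.tsv"),
            meta = sprintf("cutoff %g", cutoff))
  provenance(outdir, seed,
             params = c(unclass(config), list(cutoff = cutoff)),
             inputs = c(fastq, reference, assay_config, sample_sheet))
  invisible(crypts)
}

#' Trend analysis of a crypt-level table
#'
#' Runs the full analysis battery: mixed NB (diversity) and mixed linear
#' (percent methylation) models under both time codings, interaction tests
#' (Wald plus likelihood ratio), per-patient trends with polyp
#' correlations, and - when depths are available - a sensitivity
#' re-analysis restricted to crypts at or above `min_depth_sensitivity`.
#' Writes a report JSON and TSVs under `outdir`.
#'
#' @param crypts crypt-level data.frame or TSV path.
#' @param polyps polyp table (data.frame or TSV path) with `patient_id`,
#'   `timepoint_years`, `polyps`; optional.
#' @param outdir output directory (optional; no files written when NULL).
#' @param min_depth_sensitivity depth threshold for the sensitivity
#'   re-analysis (default 1000).
#' @param nodes quadrature nodes for the NB model.
#' @return list with `fits` (trend_fit objects), `interaction`,
#'   `patient_trends`, `sensitivity` (or NULL), `table` (the tidy
#'   group-by-timepoint summary).
#' @export
run_analyze <- function(crypts, polyps = NULL, outdir = NULL,
                        min_depth_sensitivity = 1000, nodes = 25) {
  if (is.character(crypts)) crypts <- read_crypt_table(crypts)
  if (is.character(polyps)) polyps <- read_tsv(polyps)
  use <- crypts[!is.na(crypts$diversity) & crypts$diversity > 0 &
                  is.finite(crypts$percent_methylation), , drop = FALSE]
  n_per_group <- tapply(use$patient_id, use$group,
                        function(p) length(unique(p)))
  if (any(n_per_group < 2)) {
    message("fewer than 2 patients in a group; mixed fits refused, ",
            "reporting per-patient trends only")
    pt <- if (!is.null(polyps)) per_patient_trends(use, polyps) else NULL
    return(list(fits = NULL, interaction = NULL, patient_trends = pt,
                sensitivity = NULL, table = NULL))
  }

  fits <- list(
    nb_categorical = fit_nb_mixed(use, "diversity", "categorical",
                                  nodes = nodes),
    nb_continuous = fit_nb_mixed(use, "diversity", "continuous",
                                 nodes = nodes),
    lmm_categorical = fit_lmm(use, "percent_methylation", "categorical"),
    lmm_continuous = fit_lmm(use, "percent_methylation", "continuous")
  )
  red_nb <- fit_reduced(use, "diversity", "nb_mixed", "continuous",
                        nodes = nodes)
  red_lm <- fit_reduced(use, "percent_methylation", "linear_mixed",
                        "continuous")
  interaction <- list(
    diversity = test_interaction(fits$nb_continuous, red_nb),
    percent_methylation = test_interaction(fits$lmm_continuous, red_lm)
  )
  pt <- if (!is.null(polyps)) per_patient_trends(use, polyps) else NULL

  sens <- NULL
  if ("depth" %in% names(crypts) && !all(is.na(crypts$depth))) {
    kept <- depth_sensitivity_filter(crypts, min_depth_sensitivity)
    sens <- list(retained = attr(kept, "retained"))
    kept <- kept[!is.na(kept$diversity) & kept$diversity > 0 &
                   is.finite(kept$percent_methylation), , drop = FALSE]
    ok <- nrow(kept) > 0 &&
      length(unique(kept$group)) == length(unique(use$group)) &&
      all(tapply(kept$patient_id, kept$group,
                 function(p) length(unique(p))) >= 2)
    if (ok) {
      sens$nb_continuous <- fit_nb_mixed(kept, "diversity", "continuous",
                                         nodes = nodes)
      sens$lmm_continuous <- fit_lmm(kept, "percent_methylation",
                                     "continuous")
    }
  }

  table2 <- trend_report_table(fits, interaction)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(table2, file.path(outdir, "trend_report.tsv"))
    if (!is.null(pt)) {
      write_tsv(pt$trends, file.path(outdir, "patient_trends.tsv"))
      write_tsv(pt$correlations, file.path(outdir, "correlations.tsv"))
    }
    jsonlite::write_json(list(
      interaction = interaction,
      rates = list(
        diversity = fits$nb_continuous$derived,
        percent_methylation = fits$lmm_continuous$derived),
      sensitivity = if (!is.null(sens)) list(retained = sens$retained)
    ), file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  list(fits = fits, interaction = interaction, patient_trends = pt,
       sensitivity = sens, table = table2)
}

# Tidy group x timepoint summary mirroring the usual presentation of these
# analyses: per-timepoint means from the categorical fits, rates/changes
# per year from the continuous fits, and interaction p-values.
trend_report_table <- function(fits, interaction) {
  mn <- fits$nb_categorical$derived
  names(mn)[names(mn) == "mean"] <- "patterns_mean"
  mp <- fits$lmm_categorical$derived
  out <- merge(
    mn[, c("group", "timepoint_label", "timepoint_years", "patterns_mean",
           "ci_lo", "ci_hi")],
    stats::setNames(mp[, c("group", "timepoint_label", "mean", "ci_lo",
                           "ci_hi")],
                    c("group", "timepoint_label", "percent_mean",
                      "percent_ci_lo", "percent_ci_hi")),
    by = c("group", "timepoint_label"))
  rates <- fits$nb_continuous$derived
  out$patterns_rate_per_year <-
    rates$rate_per_year[match(out$group, rates$group)]
  ch <- fits$lmm_continuous$derived
  out$percent_change_per_year <-
    ch$change_per_year[match(out$group, ch$group)]
  out$interaction_p_patterns <- interaction$diversity$p_wald
  out$interaction_p_percent <- interaction$percent_methylation$p_wald
  out[order(out$group, out$timepoint_years), ]
}

#' End-to-end demonstration run
#'
#' Simulates a small cohort, processes its reads and prints the trend
#' report, exercising every stage in one call.
#'
#' @param outdir output directory.
#' @param seed master seed.
#' @param quick use the small smoke design (default TRUE).
#' @return the [run_analyze()] result, invisibly.
#' @export
run_demo <- function(outdir = tempfile("crypttags_demo"), seed = 1,
                     quick = TRUE) {
  simdir <- file.path(outdir, "sim")
  procdir <- file.path(outdir, "proc")
  run_simulate(simdir, seed = seed, quick = quick)
  crypts <- run_process(
    fastq = file.path(simdir, "reads.fastq.gz"),
    reference = file.path(simdir, "reference.fasta"),
    assay_config = file.path(simdir, "assay.yaml"),
    sample_sheet = file.path(simdir, "sample_sheet.tsv"),
    outdir = procdir)
  res <- run_analyze(crypts, polyps = file.path(simdir, "polyps.tsv"),
                     outdir = file.path(outdir, "analysis"))
  if (!is.null(res$table)) print(res$table, digits = 3)
  invisible(res)
}
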