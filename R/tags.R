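#' Tabulate methylation patterns for one crypt
#'
#' Exact multiset counts of the distinct per-read M/U patterns among the
#' passed reads of one crypt.
#'
#' @param patterns character vector of per-read patterns (M/U strings) for a
#'   single crypt; NAs (non-passed reads) are ignored.
#' @return named integer vector, pattern -> read count, sorted by
#'   decreasing count then pattern.
#' @examples
#' tabulate_patterns(c("MMMMMMMM", "MMMMMMMM", "UUUUUUUU"))
#' @export
tabulate_patterns <- function(patterns) {
  patterns <- patterns[!is.na(patterns)]
  if (!length(patterns)) return(stats::setNames(integer(), character()))
  tab <- table(patterns)
  out <- stats::setNames(as.integer(tab), names(tab))
  out[order(-out, names(out))]
}

#' Apply the error-frequency cutoff to a pattern table
#'
#' Rare patterns are assumed to arise from PCR/sequencing errors or residual
#' incomplete conversion rather than from real stem-cell lineages. A pattern
#' is retained when its read count is at least `cutoff_fraction` of the
#' crypt's total passed reads (the boundary is inclusive: a pattern at
#' exactly the cutoff survives). The default 1% follows diagnostic practice
#' for amplicon NGS of FFPE material.
#'
#' @param pattern_table named counts from [tabulate_patterns()].
#' @param cutoff_fraction minimum frequency (default 0.01).
#' @return named integer vector of retained patterns, with attributes
#'   `discarded` (counts removed) and `depth` (total reads).
#' @examples
#' apply_frequency_cutoff(c(A = 990, B = 9, C = 1))  # retains A only
#' @export
apply_frequency_cutoff <- function(pattern_table, cutoff_fraction = 0.01) {
  depth <- sum(pattern_table)
  if (depth == 0L) {
    return(structure(pattern_table, discarded = pattern_table, depth = 0L))
  }
  keep <- pattern_table / depth >= cutoff_fraction
  structure(pattern_table[keep],
            discarded = pattern_table[!keep], depth = depth)
}

#' Tag diversity: number of retained unique methylation patterns
#'
#' @param retained_patterns retained pattern counts (post-cutoff).
#' @return integer; a degenerate crypt with nothing retained gives 0 with a
#'   warning.
#' @export
compute_diversity <- function(retained_patterns) {
  d <- length(retained_patterns)
  if (d == 0L) {
    warning("no patterns retained; degenerate crypt (diversity 0)",
            call. = FALSE)
  }
  d
}

#' Percent methylation of a crypt
#'
#' 100 x (methylated CpG site-calls) / (total CpG site-calls). With
#' `weighting = "reads"` every read contributes its sites (so a pattern's
#' weight is its read count); with `"patterns"` each distinct pattern
#' contributes once. The 10-clone Sanger workflow is inherently
#' read-weighted, so reads is the default.
#'
#' @param pattern_table named pattern counts (pre- or post-cutoff, caller's
#'   choice of scope).
#' @param weighting `"reads"` or `"patterns"`.
#' @return percent in `[0, 100]`; NA for an empty table.
#' @examples
#' compute_percent_methylation(c(MMUUUUUU = 10, UUUUUUUU = 10))  # 12.5
#' @export
compute_percent_methylation <- function(pattern_table,
                                        weighting = c("reads", "patterns")) {
  weighting <- match.arg(weighting)
  if (!length(pattern_table) || sum(pattern_table) == 0L) return(NA_real_)
  pat <- names(pattern_table)
  n_m <- vapply(strsplit(pat, ""), function(p) sum(p == "M"), integer(1))
  n_sites <- nchar(pat)
  w <- if (weighting == "reads") as.numeric(pattern_table) else rep(1, length(pat))
  100 * sum(w * n_m) / sum(w * n_sites)
}

#' Per-crypt profiles from read calls
#'
#' Aggregates a read-call table into one row per crypt: depth, tag
#' diversity after the frequency cutoff, and percent methylation (both
#' read- and pattern-weighted, over the post-cutoff patterns by default).
#' Crypts with zero passed reads, or with nothing surviving the cutoff, are
#' flagged (`ok = FALSE`) and should be excluded downstream: a sampled
#' crypt always contains at least one true lineage, so an empty profile
#' marks assay failure rather than biology.
#'
#' @param calls read-call data.frame from [call_reads()] (or any data.frame
#'   with `sample_id`, `status`, `pattern`).
#' @param sample_sheet data.frame with `sample_id`, `patient_id`, `group`,
#'   `timepoint_label`, `timepoint_years`; one row per crypt.
#' @param cutoff_fraction frequency cutoff (default 0.01).
#' @param percent_scope compute percent methylation `"post_cutoff"`
#'   (default) or `"pre_cutoff"`.
#' @return data.frame, one row per sample-sheet crypt: the sheet columns
#'   plus `depth`, `diversity`, `percent_methylation` (read-weighted,
#'   the default reported value), `percent_methylation_patternweighted`,
#'   and `ok`. Pattern tables are attached as attribute `pattern_tables`.
#' @export
crypt_profiles <- function(calls, sample_sheet, cutoff_fraction = 0.01,
                           percent_scope = c("post_cutoff", "pre_cutoff")) {
  percent_scope <- match.arg(percent_scope)
  need <- c("sample_id", "patient_id", "group", "timepoint_label",
            "timepoint_years")
  missing_cols <- setdiff(need, names(sample_sheet))
  if (length(missing_cols)) {
    stop("sample_sheet lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  passed <- calls[calls$status == "passed", , drop = FALSE]
  tables <- list()
  out <- sample_sheet[need]
  n <- nrow(sample_sheet)
  out$depth <- integer(n)
  out$diversity <- NA_integer_
  out$percent_methylation <- NA_real_
  out$percent_methylation_patternweighted <- NA_real_
  out$ok <- FALSE
  for (i in seq_len(n)) {
    sid <- sample_sheet$sample_id[i]
    tab <- tabulate_patterns(passed$pattern[passed$sample_id == sid])
    tables[[sid]] <- tab
    out$depth[i] <- sum(tab)
    if (!length(tab)) {
      message("crypt ", sid, ": zero passed reads; excluded")
      next
    }
    ret <- apply_frequency_cutoff(tab, cutoff_fraction)
    if (!length(ret)) {
      message("crypt ", sid, ": nothing retained at cutoff ",
              cutoff_fraction, "; excluded")
      out$diversity[i] <- 0L
      next
    }
    scope_tab <- if (percent_scope == "post_cutoff") ret else tab
    out$diversity[i] <- length(ret)
    out$percent_methylation[i] <-
      compute_percent_methylation(scope_tab, "reads")
    out$percent_methylation_patternweighted[i] <-
      compute_percent_methylation(scope_tab, "patterns")
    out$ok[i] <- TRUE
  }
  attr(out, "pattern_tables") <- tables
  out
}

#' Sequencing-depth sensitivity filter
#'
#' Restricts a crypt table to crypts sequenced at or above `min_depth`
#' reads, for re-analysis at high coverage only.
#'
#' @param crypts crypt-level data.frame with a `depth` column.
#' @param min_depth minimum passed-read depth (default 1000).
#' @return the filtered data.frame, with attribute `retained` =
#'   `c(kept, total)`.
#' @export
depth_sensitivity_filter <- function(crypts, min_depth = 1000) {
  keep <- crypts$depth >= min_depth
  out <- crypts[keep, , drop = FALSE]
  attr(out, "retained") <- c(kept = sum(keep), total = nrow(crypts))
  message(sprintf("depth filter >= %d: %d of %d crypts retained",
                  min_depth, sum(keep), nrow(crypts)))
  out
}

#' Sanger-style clone subsampling of one crypt
#'
#' Emulates the cloning workflow in which only a handful of molecules per
#' crypt are sequenced: draws `n_clones` passed reads uniformly without
#' replacement and computes diversity and percent methylation on the sample
#' with no frequency cutoff (every sequenced clone counts).
#'
#' @param patterns per-read patterns of one crypt (NAs dropped).
#' @param n_clones clones to draw (default 10); if fewer reads are
#'   available all are taken, with a warning.
#' @param seed integer seed for reproducible draws (optional).
#' @return list with `diversity`, `percent_methylation`, `clone_patterns`.
#' @export
clone_subsample <- function(patterns, n_clones = 10, seed = NULL) {
  patterns <- patterns[!is.na(patterns)]
  if (!is.null(seed)) set.seed(seed)
  if (length(patterns) < n_clones) {
    warning(sprintf("only %d passed reads; taking all", length(patterns)),
            call. = FALSE)
    sel <- patterns
  } else {
    sel <- sample(patterns, n_clones, replace = FALSE)
  }
  tab <- tabulate_patterns(sel)
  list(diversity = length(tab),
       percent_methylation = compute_percent_methylation(tab, "reads"),
       clone_patterns = sel)
}
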