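#' Demultiplex barcoded amplicon reads
#'
#' Barcodes are anchored at the 5' end of each read and have equal length.
#' A read is assigned to the unique barcode within `max_mismatch` Hamming
#' distance of its prefix; a read matching two or more barcodes at the same
#' (minimal) distance is never guessed at and goes to `"unassigned"`.
#'
#' @param reads character vector of read sequences.
#' @param spec an `amplicon_spec` carrying the barcode map.
#' @param max_mismatch maximum Hamming mismatches tolerated (default 0).
#' @return data.frame with `sample_id` (NA for unassigned) and `insert`
#'   (the read with the barcode removed; unchanged for unassigned reads).
#' @examples
#' spec <- amplicon_spec("AACGTT", cpg_positions = 3,
#'                       barcode_map = c(ACGT = "c1"))
#' demultiplex(c("ACGTTTTT", "GGGGTTTT"), spec)$sample_id
#' @export
demultiplex <- function(reads, spec, max_mismatch = 0) {
  bc <- names(spec$barcode_map)
  if (!length(bc)) stop("spec has no barcodes")
  bl <- nchar(bc[1])
  reads <- toupper(as.character(reads))
  prefix <- substr(reads, 1L, bl)
  insert <- substring(reads, bl + 1L)

  if (max_mismatch == 0) {
    hit <- match(prefix, bc)
  } else {
    # distance of every read prefix to every barcode
    d <- matrix(0L, nrow = length(reads), ncol = length(bc))
    for (k in seq_len(bl)) {
      pc <- substr(prefix, k, k)
      for (j in seq_along(bc)) {
        d[, j] <- d[, j] + (pc != substr(bc[j], k, k))
      }
    }
    dmin <- apply(d, 1L, min)
    nmin <- rowSums(d == dmin)
    hit <- apply(d, 1L, which.min)
    hit[dmin > max_mismatch | nmin > 1L] <- NA_integer_
  }
  sample_id <- spec$barcode_map[hit]
  assigned <- !is.na(hit)
  data.frame(
    sample_id = ifelse(assigned, sample_id, NA_character_),
    insert = ifelse(assigned, insert, reads),
    stringsAsFactors = FALSE
  )
}

#' Processing configuration for read calling
#'
#' @param match,mismatch,gap alignment scores.
#' @param score_floor_frac alignments scoring below this fraction of the
#'   maximum attainable score (reference length times `match`) are discarded.
#' @param coverage_policy `"strict"` (every reference position covered) or
#'   `"sites-only"` (CpG and control positions covered).
#' @param max_mismatch barcode mismatches tolerated in demultiplexing.
#' @param both_orientations align both orientations and keep the better.
#' @return list of class `process_config`.
#' @export
process_config <- function(match = 1, mismatch = -1, gap = -2,
                           score_floor_frac = 0.6,
                           coverage_policy = c("strict", "sites-only"),
                           max_mismatch = 0, both_orientations = TRUE) {
  structure(list(
    match = match, mismatch = mismatch, gap = gap,
    score_floor_frac = score_floor_frac,
    coverage_policy = match.arg(coverage_policy),
    max_mismatch = max_mismatch,
    both_orientations = both_orientations
  ), class = "process_config")
}

#' Call per-read methylation patterns from raw barcoded reads
#'
#' Runs the whole per-read pipeline: demultiplex, bisulfite-aware global
#' alignment (memoized over identical read sequences, which dominate
#' amplicon data), alignment score floor, full-amplicon coverage filter,
#' conversion-control filter, and CpG genotyping. Reads are dropped at the
#' first filter they fail, and every fate is accounted for in the returned
#' ledger.
#'
#' @param reads character vector of raw read sequences (barcode still
#'   attached).
#' @param spec an `amplicon_spec` with barcodes.
#' @param config a [process_config()].
#' @param read_ids optional read identifiers (default `read000001`, ...).
#' @return list with `calls` (data.frame: read_id, sample_id, status,
#'   pattern, n_ambiguous_sites, alignment_score, orientation, where status
#'   is one of passed/unassigned_barcode/low_alignment_score/
#'   partial_coverage/failed_conversion_control/ambiguous_cpg) and `ledger`
#'   (a `filter_ledger`).
#' @export
call_reads <- function(reads, spec, config = process_config(),
                       read_ids = NULL) {
  stopifnot(inherits(spec, "amplicon_spec"))
  reads <- toupper(as.character(reads))
  n <- length(reads)
  if (is.null(read_ids)) read_ids <- sprintf("read%06d", seq_len(n))
  stopifnot(length(read_ids) == n)

  dm <- demultiplex(reads, spec, max_mismatch = config$max_mismatch)
  status <- rep("passed", n)
  status[is.na(dm$sample_id)] <- "unassigned_barcode"

  cref <- convert_reference(spec)
  L <- nchar(cref$converted_seq)
  floor_score <- config$score_floor_frac * L * config$match

  # align unique insert sequences once, then broadcast
  assigned <- which(status == "passed")
  score <- rep(NA_real_, n)
  aligned <- rep(NA_character_, n)
  orientation <- rep(NA_character_, n)
  if (length(assigned)) {
    uq <- unique(dm$insert[assigned])
    al <- align_reads(uq, cref, match = config$match,
                      mismatch = config$mismatch, gap = config$gap,
                      both_orientations = config$both_orientations)
    idx <- match(dm$insert[assigned], uq)
    score[assigned] <- al$score[idx]
    aligned[assigned] <- al$aligned[idx]
    orientation[assigned] <- al$orientation[idx]

    low <- assigned[score[assigned] < floor_score]
    status[low] <- "low_alignment_score"

    keep <- which(status == "passed")
    cov <- covers_amplicon(aligned[keep], spec, policy = config$coverage_policy)
    status[keep[!cov]] <- "partial_coverage"

    keep <- which(status == "passed")
    ok <- controls_converted(aligned[keep], spec)
    status[keep[!ok]] <- "failed_conversion_control"
  }

  pattern <- rep(NA_character_, n)
  n_amb <- rep(NA_integer_, n)
  keep <- which(status == "passed")
  if (length(keep)) {
    g <- genotype_cpgs(aligned[keep], spec)
    pattern[keep] <- g$pattern
    n_amb[keep] <- g$n_ambiguous
    status[keep[g$n_ambiguous > 0L]] <- "ambiguous_cpg"
    pattern[status != "passed"] <- NA_character_
  }

  calls <- data.frame(
    read_id = read_ids,
    sample_id = dm$sample_id,
    status = status,
    pattern = pattern,
    n_ambiguous_sites = n_amb,
    alignment_score = score,
    orientation = orientation,
    stringsAsFactors = FALSE
  )
  list(calls = calls, ledger = filter_ledger(status))
}

#' Filter accounting ledger
#'
#' Counts reads by fate. The ledger conserves reads: `passed` plus all
#' discard categories equals the total input.
#'
#' @param status character vector of per-read fates.
#' @return named integer vector of class `filter_ledger`.
#' @export
filter_ledger <- function(status) {
  lv <- c("passed", "unassigned_barcode", "low_alignment_score",
          "partial_coverage", "failed_conversion_control", "ambiguous_cpg")
  out <- table(factor(status, levels = lv))
  structure(stats::setNames(as.integer(out), lv),
            total = length(status), class = "filter_ledger")
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat("<filter_ledger>", attr(x, "total"), "reads\n")
  for (nm in names(x)) cat(sprintf("  %-26s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Read a FASTQ file into read ids and sequences
#'
#' @param path FASTQ file, plain or gzip.
#' @return data.frame with `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x),
             stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#'
#' Constant placeholder qualities are written; the pipeline does not use
#' base qualities in calling.
#'
#' @param reads data.frame with `read_id` and `sequence`.
#' @param path output path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(reads$sequence),
                 function(k) paste(rep("I", k), collapse = ""), character(1))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", qual),
             con)
  invisible(path)
}
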