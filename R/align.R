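#' Bisulfite-aware global alignment of reads to the converted reference
#'
#' Needleman-Wunsch alignment, end-to-end over both the reference and the
#' read, with a bisulfite substitution rule: at CpG reference positions the
#' retained reference C matches both read C (methylated) and read T
#' (unmethylated); everywhere else standard match/mismatch scoring applies.
#' Gaps incur a linear penalty. Each read is optionally aligned in both
#' orientations and the better-scoring one kept (amplicon libraries contain
#' both strands of the PCR product).
#'
#' @param reads character vector of read sequences (barcode/primer removed).
#' @param ref a `converted_reference` (or an `amplicon_spec`, converted
#'   on the fly).
#' @param match,mismatch,gap alignment scores (defaults +1/-1/-2).
#' @param both_orientations also try the reverse complement and keep the
#'   better orientation (default TRUE).
#' @return data.frame with columns `score`, `aligned` (a string of length
#'   `nchar(converted_seq)` giving, per reference position, the aligned read
#'   base or `-`), and `orientation` (`"+"`/`"-"`).
#' @examples
#' spec <- amplicon_spec("ACGTCA", cpg_positions = 2)
#' cr <- convert_reference(spec)
#' align_reads(cr$converted_seq, cr)$score  # perfect: 6
#' @export
align_reads <- function(reads, ref, match = 1, mismatch = -1, gap = -2,
                        both_orientations = TRUE) {
  if (inherits(ref, "amplicon_spec")) ref <- convert_reference(ref)
  stopifnot(inherits(ref, "converted_reference"))
  cpg0 <- ref$source$cpg_positions - 1L
  reads <- toupper(as.character(reads))
  fwd <- cpp_align_reads(reads, ref$converted_seq, cpg0, match, mismatch, gap)
  out <- data.frame(score = fwd$score, aligned = fwd$aligned,
                    orientation = rep("+", length(reads)),
                    stringsAsFactors = FALSE)
  if (both_orientations && length(reads)) {
    rev <- cpp_align_reads(revcomp(reads), ref$converted_seq, cpg0,
                           match, mismatch, gap)
    take <- rev$score > fwd$score
    out$score[take] <- rev$score[take]
    out$aligned[take] <- rev$aligned[take]
    out$orientation[take] <- "-"
  }
  out
}

#' Coverage filter: did the read fully cover the amplicon?
#'
#' Under the default `"strict"` policy every reference position must be
#' aligned to a read base (no deletions anywhere, which for a global
#' alignment also excludes end gaps). Under `"sites-only"` only the CpG and
#' control positions must be covered, so an internal deletion away from any
#' genotyped site is tolerated.
#'
#' @param aligned per-reference-position alignment strings from
#'   [align_reads()].
#' @param spec the `amplicon_spec`.
#' @param policy `"strict"` or `"sites-only"`.
#' @return logical vector, TRUE where the read passes.
#' @export
covers_amplicon <- function(aligned, spec, policy = c("strict", "sites-only")) {
  policy <- match.arg(policy)
  if (policy == "strict") {
    !grepl("-", aligned, fixed = TRUE)
  } else {
    sites <- sort(c(spec$cpg_positions, spec$control_positions))
    m <- site_chars(aligned, sites)
    rowSums(m == "-") == 0L
  }
}

#' Conversion-control check
#'
#' A valid converted read must carry T at every non-CpG control cytosine: a
#' C there marks incomplete bisulfite conversion, and any other base is a
#' sequencing/alignment artifact. Either invalidates the read.
#'
#' @inheritParams covers_amplicon
#' @return logical vector, TRUE where all controls read T.
#' @export
controls_converted <- function(aligned, spec) {
  if (!length(spec$control_positions)) return(rep(TRUE, length(aligned)))
  m <- site_chars(aligned, spec$control_positions)
  rowSums(m != "T") == 0L
}

#' Genotype CpG sites from alignments
#'
#' Per CpG position, read C is called `M` (methylated, protected from
#' conversion) and read T is called `U` (unmethylated, converted); any other
#' base or a gap makes the site ambiguous.
#'
#' @inheritParams covers_amplicon
#' @return data.frame with `pattern` (string of M/U per CpG, NA if any site
#'   ambiguous) and `n_ambiguous` (count of ambiguous CpG sites).
#' @export
genotype_cpgs <- function(aligned, spec) {
  if (!length(aligned)) {
    return(data.frame(pattern = character(), n_ambiguous = integer(),
                      stringsAsFactors = FALSE))
  }
  m <- site_chars(aligned, spec$cpg_positions)
  call <- matrix("?", nrow = nrow(m), ncol = ncol(m))
  call[m == "C"] <- "M"
  call[m == "T"] <- "U"
  n_amb <- rowSums(call == "?")
  pattern <- apply(call, 1L, paste, collapse = "")
  pattern[n_amb > 0L] <- NA_character_
  data.frame(pattern = pattern, n_ambiguous = n_amb,
             stringsAsFactors = FALSE)
}

# Extract the characters at 1-based reference positions from alignment
# strings; returns a matrix reads x sites.
site_chars <- function(aligned, sites) {
  n <- length(aligned)
  m <- matrix("", nrow = n, ncol = length(sites))
  for (k in seq_along(sites)) {
    m[, k] <- substr(aligned, sites[k], sites[k])
  }
  m
}
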