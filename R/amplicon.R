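#' Define a bisulfite amplicon assay
#'
#' An `amplicon_spec` holds everything the pipeline needs to know about one
#' nested-PCR bisulfite amplicon: the unconverted reference sequence, the
#' offsets of the CpG cytosines that are genotyped per read, the offsets of
#' non-CpG cytosines used as bisulfite conversion controls (these must read
#' as T in every valid read), the PCR primers and the barcode-to-sample map.
#'
#' Positions may be given in the convention they were recorded in
#' (`coordinate_base = 1`, the default, treats them as 1-based as positions
#' are usually printed; `coordinate_base = 0` takes them as 0-based offsets).
#' Internally everything is stored 1-based relative to the amplicon insert.
#'
#' Duplicated control positions are tolerated: they are deduplicated with a
#' warning, since a duplicate carries no extra information.
#'
#' @param reference_seq unconverted reference sequence (A/C/G/T string) of
#'   the amplicon insert, excluding primers.
#' @param cpg_positions integer positions of CpG cytosines.
#' @param control_positions integer positions of non-CpG control cytosines.
#' @param coordinate_base 1 (positions as printed, 1-based) or 0 (offsets).
#' @param barcode_map named character vector: `barcode sequence -> sample id`.
#' @param primer_fwd,primer_rev primer sequences (annotation only).
#' @param name assay name.
#' @return An object of class `amplicon_spec`.
#' @examples
#' spec <- amplicon_spec("AACGTT", cpg_positions = 3, coordinate_base = 1)
#' n_cpg(spec)
#' @export
amplicon_spec <- function(reference_seq, cpg_positions,
                          control_positions = integer(),
                          coordinate_base = 1,
                          barcode_map = character(),
                          primer_fwd = "", primer_rev = "",
                          name = "amplicon") {
  reference_seq <- toupper(as.character(reference_seq))
  stopifnot(length(reference_seq) == 1L, nchar(reference_seq) > 0L)
  if (grepl("[^ACGT]", reference_seq)) {
    stop("reference_seq must contain only A/C/G/T")
  }
  if (!coordinate_base %in% c(0, 1)) stop("coordinate_base must be 0 or 1")
  cpg <- as.integer(cpg_positions) + (1L - as.integer(coordinate_base))
  ctl <- as.integer(control_positions) + (1L - as.integer(coordinate_base))

  if (anyDuplicated(ctl)) {
    dup <- unique(ctl[duplicated(ctl)])
    warning(sprintf(
      "duplicate control position(s) %s; deduplicating",
      paste(dup + (as.integer(coordinate_base) - 1L), collapse = ", ")
    ), call. = FALSE)
    ctl <- unique(ctl)
  }
  if (anyDuplicated(cpg)) stop("duplicate CpG positions")
  cpg <- sort(cpg)
  ctl <- sort(ctl)

  L <- nchar(reference_seq)
  bases <- strsplit(reference_seq, "")[[1]]
  check_range <- function(p, what) {
    bad <- p[p < 1L | p > L]
    if (length(bad)) {
      stop(sprintf("%s position %s outside reference [1, %d]",
                   what, bad[1], L))
    }
  }
  check_range(cpg, "CpG")
  check_range(ctl, "control")
  for (p in cpg) {
    if (bases[p] != "C") {
      stop(sprintf("position %d is not a C (found %s)", p, bases[p]))
    }
    if (p == L || bases[p + 1L] != "G") {
      stop(sprintf("position %d not followed by G", p))
    }
  }
  for (p in ctl) {
    if (bases[p] != "C") {
      stop(sprintf("control position %d is not a C (found %s)", p, bases[p]))
    }
    if (p < L && bases[p + 1L] == "G") {
      stop(sprintf("control position %d is followed by G (CpG context)", p))
    }
  }
  if (length(intersect(cpg, ctl))) {
    stop("CpG and control positions must be disjoint")
  }
  barcode_map <- validate_barcodes(barcode_map)

  structure(list(
    name = name,
    reference_seq = reference_seq,
    cpg_positions = cpg,
    control_positions = ctl,
    barcode_map = barcode_map,
    primer_fwd = toupper(primer_fwd),
    primer_rev = toupper(primer_rev)
  ), class = "amplicon_spec")
}

validate_barcodes <- function(barcode_map) {
  if (!length(barcode_map)) return(character())
  bc <- names(barcode_map)
  if (is.null(bc) || any(!nzchar(bc))) {
    stop("barcode_map must be named by barcode sequence")
  }
  bc <- toupper(bc)
  if (anyDuplicated(bc)) stop("barcode sequences must be unique")
  if (length(unique(nchar(bc))) != 1L) {
    stop("barcodes must all have the same length")
  }
  stats::setNames(as.character(barcode_map), bc)
}

#' @export
print.amplicon_spec <- function(x, ...) {
  cat(sprintf("<amplicon_spec> %s: %d bp, %d CpG site(s), %d control site(s), %d barcode(s)\n",
              x$name, nchar(x$reference_seq), length(x$cpg_positions),
              length(x$control_positions), length(x$barcode_map)))
  invisible(x)
}

#' Number of genotyped CpG sites in an assay
#' @param spec an `amplicon_spec`.
#' @return integer count of CpG sites.
#' @export
n_cpg <- function(spec) length(spec$cpg_positions)

#' In-silico bisulfite conversion of the reference
#'
#' Produces the alignment target used for converted reads: every non-CpG C
#' of the reference is replaced by T (complete conversion of unmethylated
#' cytosines), while CpG cytosines are retained as C, i.e. the reference is
#' rendered as a fully methylated, fully converted molecule. The bisulfite
#' C/T tolerance of the aligner then accommodates unmethylated epialleles.
#'
#' @param spec an `amplicon_spec`.
#' @return An object of class `converted_reference` with fields
#'   `converted_seq` and `source` (the input spec).
#' @examples
#' spec <- amplicon_spec("ACGTCA", cpg_positions = 2)
#' convert_reference(spec)$converted_seq  # "ACGTTA"
#' @export
convert_reference <- function(spec) {
  stopifnot(inherits(spec, "amplicon_spec"))
  bases <- strsplit(spec$reference_seq, "")[[1]]
  is_c <- bases == "C"
  keep <- seq_along(bases) %in% spec$cpg_positions
  bases[is_c & !keep] <- "T"
  structure(list(
    converted_seq = paste(bases, collapse = ""),
    source = spec
  ), class = "converted_reference")
}

#' @export
print.converted_reference <- function(x, ...) {
  cat(sprintf("<converted_reference> %d bp (assay %s)\n",
              nchar(x$converted_seq), x$source$name))
  invisible(x)
}

#' Build an amplicon spec from a FASTA reference and a config file
#'
#' The config is YAML (or JSON, which YAML subsumes) with keys `name`,
#' `cpg_positions`, `control_positions`, `coordinate_base`, `primer_fwd`,
#' `primer_rev` and optionally `barcodes` (a map barcode -> sample id).
#'
#' @param fasta path to a single-record FASTA with the unconverted reference.
#' @param config path to the assay config file.
#' @return An `amplicon_spec`.
#' @export
read_amplicon_spec <- function(fasta, config) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) {
    stop(sprintf("reference FASTA must contain exactly one sequence (found %d)",
                 length(seqs)))
  }
  cfg <- yaml::read_yaml(config)
  bc <- character()
  if (!is.null(cfg$barcodes)) bc <- unlist(cfg$barcodes)
  amplicon_spec(
    reference_seq = as.character(seqs[[1]]),
    cpg_positions = cfg$cpg_positions,
    control_positions = if (is.null(cfg$control_positions)) integer() else cfg$control_positions,
    coordinate_base = if (is.null(cfg$coordinate_base)) 1 else cfg$coordinate_base,
    barcode_map = bc,
    primer_fwd = if (is.null(cfg$primer_fwd)) "" else cfg$primer_fwd,
    primer_rev = if (is.null(cfg$primer_rev)) "" else cfg$primer_rev,
    name = if (is.null(cfg$name)) "amplicon" else cfg$name
  )
}

#' Synthetic CSX-style demonstration assay
#'
#' A fully synthetic 57 bp amplicon laid out like the CSX CpG-island assay
#' used for crypt stem-cell dynamics: 8 genotyped CpG cytosines at 1-based
#' positions 2, 4, 6, 18, 22, 37, 40 and 51 and two non-CpG conversion
#' controls at positions 14 and 20. The sequence itself is invented (the
#' real amplicon sequence is not modeled); only the site geometry matters
#' for the pipeline.
#'
#' @param n_barcodes number of sample barcodes to attach (0 for none);
#'   barcodes are deterministic 8-mers named `S001`, `S002`, ...
#' @return An `amplicon_spec`.
#' @examples
#' spec <- csx_synthetic_spec(4)
#' spec$cpg_positions
#' @export
csx_synthetic_spec <- function(n_barcodes = 0) {
  ref <- csx_synthetic_reference()
  bc <- character()
  if (n_barcodes > 0) {
    ids <- sprintf("S%03d", seq_len(n_barcodes))
    bc <- stats::setNames(ids, barcode_kmer(seq_len(n_barcodes)))
  }
  amplicon_spec(
    reference_seq = ref,
    cpg_positions = c(2, 4, 6, 18, 22, 37, 40, 51),
    control_positions = c(14, 20),
    coordinate_base = 1,
    barcode_map = bc,
    primer_fwd = "GGGGAGAAGGGGTTTTTAATAT",
    primer_rev = "AAAAACACTCCTAAAAAAACAACTAA",
    name = "CSX-synthetic"
  )
}

# Invented 57 bp sequence honoring the CpG/control site geometry: C appears
# only at CpG sites (each followed by G) and at the two control sites (not
# followed by G); everything else is A/G/T so the converted reference keeps
# C exclusively at the genotyped CpGs.
csx_synthetic_reference <- function() {
  b <- rep("A", 57)
  b[c(8, 10, 12, 16, 25, 28, 31, 34, 43, 45, 48, 54, 56)] <- "T"
  b[c(9, 11, 17, 26, 29, 32, 35, 44, 46, 49, 55)] <- "G"
  for (p in c(2, 4, 6, 18, 22, 37, 40, 51)) {
    b[p] <- "C"
    b[p + 1] <- "G"
  }
  b[c(14, 20)] <- "C"  # controls; next base stays non-G
  b[15] <- "T"
  b[21] <- "A"
  paste(b, collapse = "")
}

# Deterministic unique barcodes: index written in base 4 over ACGT, 8 digits.
barcode_kmer <- function(idx, width = 8L) {
  bases <- c("A", "C", "G", "T")
  vapply(idx, function(i) {
    d <- integer(width)
    x <- i
    for (k in width:1) {
      d[k] <- x %% 4L
      x <- x %/% 4L
    }
    paste(bases[d + 1L], collapse = "")
  }, character(1))
}

#' Reverse complement of DNA strings
#' @param x character vector of A/C/G/T(/N) strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
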