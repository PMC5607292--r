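test_that("demultiplexing assigns, tolerates configured mismatches, never guesses ties", {
  spec <- amplicon_spec("AACGTT", 3,
                        barcode_map = c(ACGT = "c1", TGCA = "c2"))
  # exact match
  d0 <- demultiplex(c("ACGTAACGTT", "GGGGAACGTT"), spec, max_mismatch = 0)
  expect_equal(d0$sample_id, c("c1", NA))
  expect_equal(d0$insert[1], "AACGTT")

  # one mismatch tolerated
  d1 <- demultiplex("ACGAAACGTT", spec, max_mismatch = 1)
  expect_equal(d1$sample_id, "c1")

  # equidistant from both barcodes: unassigned
  d2 <- demultiplex("ACGAAACGTT", amplicon_spec("AACGTT", 3,
                    barcode_map = c(ACGT = "c1", ACGG = "c2")),
                    max_mismatch = 1)
  expect_true(is.na(d2$sample_id))
})

test_that("filter ledger conserves reads per fate", {
  spec <- csx_synthetic_spec(4)
  st <- simulate_niche(niche_params(), 1, seed = 5)
  sq <- sequence_crypt(st, assay_params(depth_meanlog = log(400),
                                        depth_sdlog = 0.2,
                                        p_conversion_failure = 0.2,
                                        p_seq_error = 0.01),
                       spec, barcode = names(spec$barcode_map)[1], seed = 6)
  # salt in some unassignable reads
  reads <- c(sq$reads$sequence, paste0("NNNNNNNN", strrep("A", 57)))
  res <- call_reads(reads, spec)
  expect_equal(sum(res$ledger), attr(res$ledger, "total"))
  expect_equal(attr(res$ledger, "total"), length(reads))
  expect_gte(res$ledger[["failed_conversion_control"]], 1L)
  expect_equal(res$ledger[["unassigned_barcode"]], 1L)
  expect_equal(as.integer(table(res$calls$status)[names(res$ledger)[res$ledger > 0]]),
               as.integer(res$ledger[res$ledger > 0]))
})

test_that("processing is deterministic and error-free reads pass completely", {
  spec <- csx_synthetic_spec(2)
  perfect <- assay_params(p_conversion_failure = 0,
                          p_inappropriate_conversion = 0, p_seq_error = 0,
                          depth_meanlog = log(150), depth_sdlog = 0.2)
  st <- simulate_niche(niche_params(), 2, seed = 11)
  sq <- sequence_crypt(st, perfect, spec,
                       barcode = names(spec$barcode_map)[1], seed = 12)
  res1 <- call_reads(sq$reads$sequence, spec)
  res2 <- call_reads(sq$reads$sequence, spec)
  expect_identical(res1$calls, res2$calls)

  # zero error rates: every read passes and equals its source epigenotype
  expect_equal(res1$ledger[["passed"]], nrow(sq$reads))
  expect_equal(unname(res1$calls$pattern), unname(sq$truth$source_pattern))
})

test_that("conversion failure saturates the control filter when total", {
  spec <- csx_synthetic_spec(2)
  st <- simulate_niche(niche_params(), 1, seed = 3)
  sq <- sequence_crypt(st, assay_params(p_conversion_failure = 1,
                                        conv_retention = 1,
                                        p_seq_error = 0,
                                        depth_meanlog = log(100),
                                        depth_sdlog = 0),
                       spec, barcode = names(spec$barcode_map)[1], seed = 4)
  res <- call_reads(sq$reads$sequence, spec)
  expect_equal(res$ledger[["failed_conversion_control"]], sq$truth$depth)
  expect_equal(res$ledger[["passed"]], 0L)
})

test_that("low-scoring junk reads are floored out", {
  spec <- csx_synthetic_spec(2)
  junk <- paste0(names(spec$barcode_map)[1], strrep("A", 57))
  res <- call_reads(junk, spec)
  expect_equal(res$ledger[["low_alignment_score"]], 1L)
})

test_that("FASTQ round trip preserves ids and sequences", {
  spec <- csx_synthetic_spec(2)
  st <- simulate_niche(niche_params(), 1, seed = 8)
  sq <- sequence_crypt(st, assay_params(depth_meanlog = log(50),
                                        depth_sdlog = 0),
                       spec, barcode = names(spec$barcode_map)[1],
                       crypt_id = "cX", seed = 9)
  fp <- tempfile(fileext = ".fastq.gz")
  write_fastq(sq$reads, fp)
  back <- read_fastq(fp)
  expect_equal(back$read_id, sq$reads$read_id)
  expect_equal(back$sequence, sq$reads$sequence)
})
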