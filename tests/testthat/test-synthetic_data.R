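test_that("in-silico PCR reproduces the designed amplicon sizes", {
  loc <- test_locus()
  lac <- build_allele_sequence(loc, parse_haplotype_name("LAC"))
  ps <- primer_sets()
  for (k in seq_len(nrow(ps))) {
    prod <- in_silico_pcr(lac, ps$fwd_gene[k], ps$rev_gene[k])
    expect_equal(nrow(prod), 1L)
    expect_equal(prod$length, ps$expected_size[k])
  }
  # confirmation primer pair: 1026 bp product
  sp <- sanger_primers()
  prod <- in_silico_pcr(lac, sp$fwd, sp$rev)
  expect_equal(prod$length, 1026L)
  # S allele products are 43 bp shorter
  sac <- build_allele_sequence(loc, parse_haplotype_name("SAC"))
  prod_s <- in_silico_pcr(sac, sp$fwd, sp$rev)
  expect_equal(prod_s$length, 1026L - 43L)
})

test_that("in-silico PCR handles absent sites and mismatch tolerance", {
  loc <- test_locus()
  sp <- sanger_primers()
  # template lacking the reverse site: no product, empty frame, no error
  tmpl <- substr(build_allele_sequence(loc, parse_haplotype_name("LAC")),
                 1, 500)
  expect_equal(nrow(in_silico_pcr(tmpl, sp$fwd, sp$rev)), 0L)
  # one mismatch in the forward site blocks exact matching only
  lac <- build_allele_sequence(loc, parse_haplotype_name("LAC"))
  pos <- in_silico_pcr(lac, sp$fwd, sp$rev)$start + 3L
  mutated <- lac
  substr(mutated, pos, pos) <- if (substr(lac, pos, pos) == "A") "C" else "A"
  expect_equal(nrow(in_silico_pcr(mutated, sp$fwd, sp$rev, max_mm = 0)), 0L)
  expect_equal(in_silico_pcr(mutated, sp$fwd, sp$rev, max_mm = 1)$length,
               1026L)
  expect_error(in_silico_pcr(lac, "ACGTACGT", sp$rev), "15 nt")
})

test_that("error-free simulation returns the amplicon or its reverse complement", {
  amp <- build_allele_sequence(test_locus(), parse_haplotype_name("SAC"))
  rd <- simulate_reads(amp, 10, error_model(0, 0, 0, seed = 3))
  expect_equal(nrow(rd), 10L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(amp)))
  expect_true(all(rd$seq == ifelse(rd$is_rc, rc, amp)))
})

test_that("substitution counts follow the binomial error model", {
  withr::with_seed(21, {
    amp <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                 collapse = "")
  })
  p <- 0.01
  rd <- simulate_reads(amp, 1000, error_model(p, 0, 0, seed = 42))
  norm <- rd$seq
  norm[rd$is_rc] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(norm[rd$is_rc])))
  dists <- vapply(norm, httlpr:::cpp_hamming, integer(1), b = amp,
                  USE.NAMES = FALSE)
  # mean Hamming distance ~ Binomial(1000, 0.01): 10 +/- 3 sigma of the mean
  sigma_mean <- sqrt(1000 * p * (1 - p) / 1000)
  expect_lt(abs(mean(dists) - 1000 * p), 3 * sigma_mean)
})

test_that("simulation is byte-reproducible under a fixed seed", {
  amp <- build_allele_sequence(test_locus(), parse_haplotype_name("LGC"))
  em <- error_model(seed = 99)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  rd1 <- simulate_reads(amp, 50, em)
  rd2 <- simulate_reads(amp, 50, em)
  write_pooled_fastq(setNames(rd1$seq, sprintf("r%02d", 1:50)), f1)
  write_pooled_fastq(setNames(rd2$seq, sprintf("r%02d", 1:50)), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and the FASTQ re-parses losslessly
  back <- read_pooled_fastq(f1)
  expect_equal(unname(back), rd1$seq)
})

test_that("error model rejects invalid rates", {
  expect_error(error_model(-0.1), "non-negative")
  expect_error(error_model(0.3, 0.2, 0.1), "below 0.5")
})

test_that("barcode attachment follows the documented layout", {
  smp <- list(barcode_fwd = strrep("A", 16), barcode_rev = strrep("C", 16))
  read <- "ACGTACGTACGTACGTACGT"
  out <- attach_barcodes(read, smp)
  expect_equal(nchar(out), nchar(read) + 2L * 16L + 19L + 20L)
  expect_true(startsWith(out, paste0(smp$barcode_fwd, "ATGGGTTCCAGAGTCAATC")))
  # reverse orientation emits the same molecule on the other strand
  rc_read <- httlpr:::cpp_revcomp(read)
  out_rev <- attach_barcodes(rc_read, smp, orientation = "reverse")
  expect_equal(out_rev, httlpr:::cpp_revcomp(out))
  expect_error(attach_barcodes(read, list(barcode_fwd = "",
                                          barcode_rev = "C")),
               "invalid sample")
})

test_that("equimolar pooling volumes conserve total mass", {
  expect_equal(pooling_volume(4000, 120, 10), 4000 / (120 * 10))
  expect_equal(pooling_volume(4000, 120, 10), 3.3333, tolerance = 1e-4)
  expect_equal(pooling_volume(500, 20, 500 / 20), 1.0)
  withr::with_seed(5, {
    conc <- runif(120, 5, 60)
    vol <- pooling_volume(4000, 120, conc)
    expect_equal(sum(vol * conc), 4000)
  })
  expect_error(pooling_volume(4000, 120, 0), "division by zero")
  expect_error(pooling_volume(-1, 120, 10), "positive")
})

test_that("barcode tables meet the pairwise distance floor", {
  tbl <- make_barcode_table(120, seed = 8)
  expect_equal(nrow(tbl), 120L)
  expect_false(anyDuplicated(paste(tbl$barcode_fwd, tbl$barcode_rev)) > 0)
  expect_gte(attr(tbl, "min_pairwise_dist"), 5L)
  expect_true(all(nchar(tbl$barcode_fwd) == 16L))
})

test_that("cohort simulation respects configuration contracts", {
  loc <- test_locus()
  cohort <- simulate_cohort(loc, c(LAC = 1.0), n_samples = 5, coverage = 2,
                            em = error_model(0, 0, 0), seed = 2)
  expect_true(all(cohort$truth$hap1 == "LAC" & cohort$truth$hap2 == "LAC"))
  expect_length(cohort$reads, 5 * 2 * 2)
  expect_error(simulate_cohort(loc, c(LAC = 0.6, SAC = 0.3), 5),
               "sum to 1")
  empty <- simulate_cohort(loc, c(LAC = 1.0), n_samples = 0)
  expect_equal(nrow(empty$truth), 0L)
  expect_length(empty$reads, 0L)
})

test_that("cohort outputs re-parse losslessly from disk", {
  loc <- test_locus()
  out_dir <- withr::local_tempdir()
  cohort <- simulate_cohort(loc, c(LAC = 0.5, SAT = 0.5), n_samples = 3,
                            coverage = 3, seed = 6, out_dir = out_dir)
  back <- read_pooled_fastq(file.path(out_dir, "pool.fastq"))
  expect_equal(back, cohort$reads)
  truth <- read.table(file.path(out_dir, "truth.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
  expect_equal(truth$hap1, cohort$truth$hap1)
})
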