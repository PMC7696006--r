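test_that("clustering separates a balanced heterozygote", {
  feats <- rbind(fake_features(50, 16, "A", "C"),
                 fake_features(50, 14, "A", "T", prefix = "s"))
  cl <- cluster_reads(feats)
  expect_length(cl, 2)
  tuples <- vapply(cl, function(c)
    paste(c$repeat_count, c$rs25531, c$rs25532), character(1))
  expect_setequal(tuples, c("16 A C", "14 A T"))
  expect_equal(sort(vapply(cl, `[[`, integer(1), "support")), c(50L, 50L))
})

test_that("a homogeneous read set yields one homozygous cluster", {
  feats <- fake_features(100, 14, "A", "C")
  cl <- cluster_reads(feats)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$repeat_count, 14L)
  call <- call_diplotype(feats, test_locus())
  expect_equal(call$name, "SAC/SAC")
})

test_that("singleton noise groups merge into the nearest major group", {
  feats <- rbind(fake_features(98, 16, "A", "C"),
                 fake_features(1, 17, "A", "C", prefix = "n1"),
                 fake_features(1, 16, "G", "C", prefix = "n2"))
  cl <- cluster_reads(feats)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$support, 100L)
  expect_equal(cl[[1]]$repeat_count, 16L)
  expect_equal(cl[[1]]$rs25531, "A")
})

test_that("minor clusters below the fraction floor are dropped", {
  cfg <- haplotyping_config()
  hom <- rbind(fake_features(85, 16, "A", "C"),
               fake_features(15, 14, "A", "C", prefix = "m"))
  expect_length(cluster_reads(hom, cfg), 1)
  het <- rbind(fake_features(70, 16, "A", "C"),
               fake_features(30, 14, "A", "C", prefix = "m"))
  expect_length(cluster_reads(het, cfg), 2)
})

test_that("insufficient reads produce a typed no-call", {
  feats <- fake_features(5, 16, "A", "C")
  cl <- cluster_reads(feats)
  expect_true(cl$no_call)
  call <- call_diplotype(feats, test_locus(), sample_id = "X")
  expect_true(is.na(call$name))
  expect_equal(call$qc$no_call_reason, "insufficient reads")
  expect_error(emit_vcf(call, test_locus()), "no-call")
})

test_that("repeat-count heterozygotes with equal SNVs split on count alone", {
  feats <- rbind(fake_features(50, 16, "A", "C"),
                 fake_features(50, 17, "A", "C", prefix = "x"))
  call <- call_diplotype(feats, test_locus())
  expect_equal(call$name, "LAC/XLAC")
  expect_equal(call$genotypes$rs4795541_repeats, c(16L, 17L))
})

test_that("calls are deterministic for identical inputs", {
  feats <- rbind(fake_features(47, 16, "G", "C"),
                 fake_features(53, 14, "A", "C", prefix = "s"))
  c1 <- call_diplotype(feats, test_locus())
  c2 <- call_diplotype(feats, test_locus())
  expect_equal(c1$name, c2$name)
  expect_equal(c1$genotypes, c2$genotypes)
  expect_equal(c1$qc$cluster_fractions, c2$qc$cluster_fractions)
})

test_that("unclassifiable repeat counts are flagged, not fatal", {
  feats <- fake_features(40, 15, "A", "C")
  call <- call_diplotype(feats, test_locus())
  expect_equal(call$name, "(15)AC/(15)AC")
  expect_true(call$qc$unclassified)
})

test_that("noisy simulated samples call their generating diplotype", {
  pool <- panel_pool(data.frame(sample_id = c("S001", "S002"),
                                hap1 = c("LGC", "SAT"),
                                hap2 = c("SAC", "SAT"),
                                rc1 = c(16L, 14L), rc2 = c(14L, 14L),
                                stringsAsFactors = FALSE),
                     coverage = 100, seed = 77)
  res <- genotype_pool(pool$reads, pool$barcodes, test_locus())
  expect_equal(res$table$diplotype, c("LGC/SAC", "SAT/SAT"))
  # homozygous rs25532 T/T genotype on the SAT/SAT sample
  expect_equal(res$calls[["S002"]]$genotypes$rs25532, c("T", "T"))
})

test_that("phase consistency: genotypes equal the consensus haplotype multiset", {
  feats <- rbind(fake_features(40, 16, "G", "C"),
                 fake_features(40, 14, "A", "T", prefix = "s"))
  call <- call_diplotype(feats, test_locus())
  h1 <- call$diplotype$hap1; h2 <- call$diplotype$hap2
  expect_equal(call$genotypes$rs25531, c(h1$rs25531, h2$rs25531))
  expect_equal(call$genotypes$rs25532, c(h1$rs25532, h2$rs25532))
  expect_equal(call$genotypes$rs4795541_repeats,
               c(h1$repeat_count, h2$repeat_count))
})

test_that("emitted VCF is phased and round-trips the diplotype", {
  loc <- test_locus()
  # het on both SNV-bearing haplotypes: hap1 = LGC carries the rs25531 ALT
  call <- call_diplotype(rbind(fake_features(40, 16, "G", "C"),
                               fake_features(40, 14, "A", "C", prefix = "s")),
                         loc, sample_id = "HG01190")
  expect_equal(call$name, "LGC/SAC")
  v <- emit_vcf(call, loc)
  rs31 <- strsplit(grep("rs25531", v, value = TRUE), "\t")[[1]]
  expect_equal(sub(":.*$", "", rs31[10]), "1|0")
  expect_equal(diplotype_name(read_diplotype_vcf(v)), "LGC/SAC")

  # homozygous reference: every genotype is 0|0
  hom <- call_diplotype(fake_features(40, 16, "A", "C"), loc,
                        sample_id = "ref")
  vh <- emit_vcf(hom, loc)
  gts <- sub(":.*$", "", vapply(strsplit(grep("^SLC6A4", vh, value = TRUE),
                                         "\t"), `[`, character(1), 10))
  expect_true(all(gts == "0|0"))
  expect_equal(diplotype_name(read_diplotype_vcf(vh)), "LAC/LAC")

  # round-trip across the precision panel diplotypes
  for (i in seq_len(nrow(default_precision_panel()))) {
    row <- default_precision_panel()[i, ]
    feats <- rbind(
      fake_features(30, row$rc1, substr(row$hap1, nchar(row$hap1) - 1,
                                        nchar(row$hap1) - 1),
                    substr(row$hap1, nchar(row$hap1), nchar(row$hap1))),
      fake_features(30, row$rc2, substr(row$hap2, nchar(row$hap2) - 1,
                                        nchar(row$hap2) - 1),
                    substr(row$hap2, nchar(row$hap2), nchar(row$hap2)),
                    prefix = "s"))
    cc <- call_diplotype(feats, loc, sample_id = row$sample_id)
    expect_equal(diplotype_name(read_diplotype_vcf(emit_vcf(cc, loc))),
                 paste0(row$hap1, "/", row$hap2))
  }
})

test_that("consensus flank variants propagate into the call and VCF", {
  loc <- test_locus()
  cfg <- haplotyping_config(detect_flank_variants = TRUE)
  ref <- substr(loc$downstream_flank, 300, 300)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  h <- promoter_haplotype(16L, extra_variants = data.frame(
    pos = 300L, ref = ref, alt = alt))
  read <- httlpr:::amplicon_insert(loc, h)
  rd <- simulate_reads(read, 30, error_model(seed = 12))
  norm <- rd$seq
  norm[rd$is_rc] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(norm[rd$is_rc])))
  feats <- featurize_reads(norm, loc, cfg)
  call <- call_diplotype(feats, loc, cfg)
  expect_equal(call$name, "LAC/LAC")
  ev <- call$diplotype$hap1$extra_variants
  expect_equal(ev$pos, 300L)
  expect_equal(ev$alt, alt)
  v <- emit_vcf(call, loc)
  expect_true(any(grepl("flank_300", v)))
})
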