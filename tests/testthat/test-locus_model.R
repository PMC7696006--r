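test_that("repeat counts map to the documented length classes", {
  expect_equal(classify_repeat_count(16), "L")
  expect_equal(classify_repeat_count(14), "S")
  expect_equal(classify_repeat_count(18), "XL")
  expect_equal(classify_repeat_count(11:13), rep("XS", 3))
  # the class table has a gap at 15; nothing is silently binned
  expect_equal(classify_repeat_count(15), "UNCLASSIFIED")
  expect_equal(classify_repeat_count(10), "UNCLASSIFIED")
  expect_equal(classify_repeat_count(25), "UNCLASSIFIED")
  expect_error(classify_repeat_count(0), "between 1 and 50")
  expect_error(classify_repeat_count(-3))
  expect_error(classify_repeat_count(14.5), "whole number")
  expect_error(classify_repeat_count(NA))
  expect_error(classify_repeat_count(51))
})

test_that("class rank is monotone non-decreasing in repeat count", {
  rank <- c(XS = 1, S = 2, L = 3, XL = 4)
  n <- setdiff(11:24, 15)
  cls <- classify_repeat_count(n)
  expect_true(all(cls %in% names(rank)))
  expect_true(all(diff(rank[cls]) >= 0))
})

test_that("haplotype naming is bijective over the 16 nameable combinations", {
  for (cls in c("XS", "S", "L", "XL")) {
    for (b1 in c("A", "G")) {
      for (b2 in c("C", "T")) {
        nm <- paste0(cls, b1, b2)
        h <- parse_haplotype_name(nm)
        expect_equal(haplotype_name(h), nm)
        expect_equal(h$length_class, cls)
      }
    }
  }
})

test_that("unclassifiable haplotypes raise a typed error carrying the count", {
  h <- promoter_haplotype(15)
  err <- tryCatch(haplotype_name(h), httlpr_unnamable = function(e) e)
  expect_s3_class(err, "httlpr_unnamable")
  expect_equal(err$repeat_count, 15L)
})

test_that("canonical diplotype order matches report conventions", {
  nm <- function(a, b) diplotype_name(canonical_diplotype(
    parse_haplotype_name(a), parse_haplotype_name(b)))
  expect_equal(nm("SAC", "LGC"), "LGC/SAC")
  expect_equal(nm("XLAC", "SAC"), "SAC/XLAC")
  expect_equal(nm("LAC", "LAC"), "LAC/LAC")
  expect_equal(nm("SAT", "LAC"), "LAC/SAT")
  expect_equal(nm("XLAC", "LAC"), "LAC/XLAC")
})

test_that("canonical ordering is commutative and idempotent", {
  names16 <- as.vector(outer(c("XS", "S", "L", "XL"),
                             outer(c("A", "G"), c("C", "T"), paste0),
                             paste0))
  withr::with_seed(11, {
    for (i in 1:40) {
      a <- parse_haplotype_name(sample(names16, 1))
      b <- parse_haplotype_name(sample(names16, 1))
      d1 <- canonical_diplotype(a, b)
      d2 <- canonical_diplotype(b, a)
      expect_equal(diplotype_name(d1), diplotype_name(d2))
      d3 <- canonical_diplotype(d1$hap1, d1$hap2)
      expect_equal(diplotype_name(d3), diplotype_name(d1))
    }
  })
})

test_that("locus invariants hold for the default locus", {
  loc <- test_locus()
  expect_silent(validate_locus(loc))
  lens <- nchar(loc$unit_library)
  expect_true(all(lens >= 20 & lens <= 24))
  # pairwise unit identity at or above the homology floor
  d <- adist(loc$unit_library)
  id <- 1 - d / outer(lens, lens, pmax)
  expect_true(all(id[upper.tri(id)] >= loc$homology_floor))
})

test_that("the L allele is exactly 43 bp longer than the S allele", {
  loc <- test_locus()
  lac <- build_allele_sequence(loc, parse_haplotype_name("LAC"))
  sac <- build_allele_sequence(loc, parse_haplotype_name("SAC"))
  expect_equal(nchar(lac) - nchar(sac), 43L)
})

test_that("SNV substitutions land at their anchored positions", {
  loc <- test_locus()
  lac <- build_allele_sequence(loc, parse_haplotype_name("LAC"))
  lgc <- build_allele_sequence(loc, parse_haplotype_name("LGC"))
  expect_equal(nchar(lac), nchar(lgc))
  diffs <- which(strsplit(lac, "")[[1]] != strsplit(lgc, "")[[1]])
  # exactly one substitution, inside the sixth repeat unit
  expect_length(diffs, 1)
  up <- nchar(loc$upstream_flank)
  expected <- up + sum(nchar(loc$unit_library[1:5])) +
    loc$rs25531_offset_in_unit + 1L
  expect_equal(diffs, expected)

  sac <- build_allele_sequence(loc, parse_haplotype_name("SAC"))
  sat <- build_allele_sequence(loc, parse_haplotype_name("SAT"))
  diffs2 <- which(strsplit(sac, "")[[1]] != strsplit(sat, "")[[1]])
  expect_length(diffs2, 1)
  # rs25532 lies in the downstream flank, outside the VNTR
  expect_gt(diffs2, up + vntr_length(loc, 14L))
})

test_that("allele length is strictly increasing in repeat count", {
  loc <- test_locus()
  lens <- vapply(11:24, function(n)
    nchar(build_allele_sequence(loc, promoter_haplotype(n))), integer(1))
  expect_true(all(diff(lens) > 0))
})

test_that("unknown allele structures are rejected", {
  loc <- test_locus()
  expect_error(build_allele_sequence(loc, promoter_haplotype(30)),
               "unknown allele")
})

test_that("locus JSON serialization round-trips", {
  loc <- test_locus()
  path <- withr::local_tempfile(fileext = ".json")
  write_locus_json(loc, path)
  loc2 <- read_locus_json(path)
  expect_equal(loc2$unit_library, loc$unit_library)
  expect_equal(loc2$allele_structures, loc$allele_structures)
  for (nm in c("LAC", "SGC", "XLAC"))
    expect_equal(build_allele_sequence(loc2, parse_haplotype_name(nm)),
                 build_allele_sequence(loc, parse_haplotype_name(nm)))
})

test_that("allele FASTA has one record per haplotype with matching sequence", {
  loc <- test_locus()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_allele_fasta(loc, path)
  dss <- Biostrings::readDNAStringSet(path)
  expect_setequal(names(dss), c("LAC", "SAC", "LGC", "SAT", "XLAC", "SGC"))
  expect_equal(as.character(dss[["SAT"]]),
               build_allele_sequence(loc, parse_haplotype_name("SAT")))
})
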