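# Shared fixtures: one locus instance per test run, plus quick builders for
# synthetic feature tables and pooled libraries.

.fixture_env <- new.env(parent = emptyenv())

test_locus <- function() {
  if (is.null(.fixture_env$locus)) .fixture_env$locus <- default_locus()
  .fixture_env$locus
}

# fabricate a per-read feature table directly (bypasses sequencing), used by
# clustering/calling tests that exercise decision logic rather than alignment
fake_features <- function(n, repeat_count, rs25531 = "A", rs25532 = "C",
                          prefix = "r") {
  data.frame(read_id = sprintf("%s%04d_%d_%s%s", prefix, seq_len(n),
                               repeat_count, rs25531, rs25532),
             anchor_ok = TRUE, vntr_len = NA_integer_,
             repeat_count = as.integer(repeat_count),
             primary_count = as.integer(repeat_count),
             rs25531 = rs25531, rs25532 = rs25532,
             flank_mm = NA_character_, qc = "ok", stringsAsFactors = FALSE)
}

# simulate a pooled library for an explicit truth panel
panel_pool <- function(panel, coverage = 30L, em = error_model(),
                       seed = 1L, locus = test_locus()) {
  barcodes <- make_barcode_table(nrow(panel), seed = seed)
  samples <- cbind(barcodes, panel[, c("hap1", "hap2", "rc1", "rc2")])
  reads <- simulate_pool(locus, samples, coverage = coverage, em = em,
                         seed = seed + 1L)
  list(reads = reads, barcodes = barcodes, panel = panel)
}

# truth panel covering every repeat count in 11..24 except the unclassifiable
# 15, with varied SNV backgrounds
all_class_panel <- function() {
  counts <- list(c(11L, 12L), c(13L, 14L), c(16L, 17L), c(18L, 19L),
                 c(20L, 21L), c(22L, 23L), c(24L, 16L))
  snvs <- list(c("A", "C"), c("G", "C"), c("A", "T"), c("G", "C"),
               c("A", "C"), c("A", "T"), c("G", "C"))
  rows <- lapply(seq_along(counts), function(i) {
    h1 <- promoter_haplotype(counts[[i]][1], snvs[[i]][1], snvs[[i]][2])
    h2 <- promoter_haplotype(counts[[i]][2], "A", "C")
    d <- canonical_diplotype(h1, h2)
    data.frame(sample_id = sprintf("S%03d", i),
               hap1 = haplotype_name(d$hap1), hap2 = haplotype_name(d$hap2),
               rc1 = d$hap1$repeat_count, rc2 = d$hap2$repeat_count,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
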