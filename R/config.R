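#' Tunable thresholds for the haplotyping pipeline
#'
#' @param anchor_length flank anchor length (bp) used to locate the VNTR.
#' @param anchor_min_identity minimum alignment identity for a flank anchor
#'   to count as found.
#' @param site_min_identity minimum identity of a variant-site context
#'   alignment; below it the site base is reported missing.
#' @param unit_min_identity minimum identity for one repeat-unit alignment to
#'   be accepted during tandem counting.
#' @param min_total_reads minimum usable reads required to attempt a call.
#' @param min_reads_per_hap minimum supporting reads for a haplotype cluster.
#' @param min_minor_fraction minimum fraction of usable reads for the minor
#'   cluster of a heterozygote.
#' @param max_mm_barcode demultiplexing mismatch tolerance per barcode.
#' @param detect_flank_variants whether to scan flanks for additional
#'   substitutions per read (slower; off by default).
#' @param flank_variant_min_fraction fraction of a cluster's reads that must
#'   share a flank substitution for it to enter the consensus haplotype.
#' @return list of class `haplotyping_config`.
#' @export
haplotyping_config <- function(anchor_length = 30L,
                               anchor_min_identity = 0.8,
                               site_min_identity = 0.8,
                               unit_min_identity = 0.7,
                               min_total_reads = 20L,
                               min_reads_per_hap = 10L,
                               min_minor_fraction = 0.2,
                               max_mm_barcode = 1L,
                               detect_flank_variants = FALSE,
                               flank_variant_min_fraction = 0.7) {
  structure(list(anchor_length = anchor_length,
                 anchor_min_identity = anchor_min_identity,
                 site_min_identity = site_min_identity,
                 unit_min_identity = unit_min_identity,
                 min_total_reads = min_total_reads,
                 min_reads_per_hap = min_reads_per_hap,
                 min_minor_fraction = min_minor_fraction,
                 max_mm_barcode = max_mm_barcode,
                 detect_flank_variants = detect_flank_variants,
                 flank_variant_min_fraction = flank_variant_min_fraction),
            class = "haplotyping_config")
}
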