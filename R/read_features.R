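# Per-read feature extraction: VNTR repeat count plus the bases observed at
# the rs25531 and rs25532 anchors (and optionally additional flank
# substitutions).

#' Locate the VNTR within an orientation-normalized read
#'
#' Semi-globally aligns the last `anchor_length` bp of the upstream flank and
#' the first `anchor_length` bp of the downstream flank against the read and
#' returns the enclosed interval. Fails (a value, not an error) when either
#' anchor aligns below `anchor_min_identity`.
#'
#' @param read trimmed, orientation-normalized read (from [demux_pool()]).
#' @param locus an `slc6a4_locus`.
#' @param cfg a [haplotyping_config()].
#' @return list with `ok`; when `ok` is `TRUE` also `vntr_start`,
#'   `vntr_end` (1-based inclusive read positions) and `down_start` (read
#'   position of the first downstream-flank base); otherwise `reason`.
#' @export
locate_anchors <- function(read, locus, cfg = haplotyping_config()) {
  al <- cfg$anchor_length
  up_len <- nchar(locus$upstream_flank)
  up_anchor <- substr(locus$upstream_flank, up_len - al + 1L, up_len)
  dn_anchor <- substr(locus$downstream_flank, 1L, al)
  if (nchar(read) < 2L * al) return(list(ok = FALSE, reason = "read too short"))

  a_up <- cpp_align(up_anchor, read)
  if (a_up$identity < cfg$anchor_min_identity)
    return(list(ok = FALSE, reason = "upstream anchor not found"))

  # the downstream anchor must sit within one maximal VNTR of the upstream
  # anchor; restricting the search window keeps alignment cost bounded
  max_vntr <- max(vapply(names(locus$allele_structures), function(n)
    vntr_length(locus, as.integer(n)), integer(1)))
  ws <- a_up$end + 1L
  we <- min(nchar(read), a_up$end + max_vntr + 3L * al)
  if (we - ws + 1L < al)
    return(list(ok = FALSE, reason = "downstream anchor not found"))
  a_dn <- cpp_align(dn_anchor, substr(read, ws, we))
  if (a_dn$identity < cfg$anchor_min_identity)
    return(list(ok = FALSE, reason = "downstream anchor not found"))
  down_start <- ws - 1L + a_dn$start
  list(ok = TRUE, vntr_start = a_up$end + 1L, vntr_end = down_start - 1L,
       down_start = down_start)
}

#' Count repeat units in a VNTR segment
#'
#' The primary estimate is `round(length(segment) / mean unit length)`; it is
#' refined by greedy tandem alignment of the unit consensus along the
#' segment, counting accepted unit alignments (identity at or above
#' `unit_min_identity`). Both estimates are returned; the refined count is
#' the caller-facing value.
#'
#' @param segment VNTR segment (between the flank anchors).
#' @param locus an `slc6a4_locus`.
#' @param cfg a [haplotyping_config()].
#' @return list with `count` (refined), `primary`, and `qc` (`"ok"` or
#'   `"segment_too_short"`).
#' @export
count_repeats <- function(segment, locus, cfg = haplotyping_config()) {
  mean_len <- mean(nchar(locus$unit_library))
  if (nchar(segment) < min(nchar(locus$unit_library)))
    return(list(count = 0L, primary = 0L, qc = "segment_too_short"))
  primary <- as.integer(round(nchar(segment) / mean_len))
  refined <- cpp_count_tandem(segment, locus$unit_consensus,
                              cfg$unit_min_identity)[1]
  list(count = refined, primary = primary, qc = "ok")
}

#' Extract the base observed at a promoter variant site
#'
#' For rs25532 the 21 bp reference context centered on the site is aligned
#' within the downstream-flank portion of the read; for rs25531 the sixth
#' repeat unit (counted 5' to 3' from the VNTR start) is aligned within its
#' expected window of the VNTR portion. The aligned base is reported;
#' `NA` (missing) when the context identity falls below
#' `site_min_identity`, when the site position aligns to a gap, or -- for
#' rs25531 -- when the allele has fewer than six units.
#'
#' @param read trimmed, orientation-normalized read.
#' @param anchors result of [locate_anchors()] (must have `ok = TRUE`).
#' @param locus an `slc6a4_locus`.
#' @param site `"rs25531"` or `"rs25532"`.
#' @param cfg a [haplotyping_config()].
#' @return single base character, or `NA_character_` if missing.
#' @export
extract_site_base <- function(read, anchors, locus, site,
                              cfg = haplotyping_config()) {
  stopifnot(isTRUE(anchors$ok))
  site <- match.arg(site, c("rs25531", "rs25532"))
  slack <- 12L
  if (site == "rs25531") {
    ui <- locus$rs25531_unit_index
    unit6 <- locus$unit_library[ui]
    off5 <- vntr_prefix_length(locus, ui - 1L)
    vlen <- anchors$vntr_end - anchors$vntr_start + 1L
    if (vlen < off5 + nchar(unit6) - slack) return(NA_character_)
    ws <- max(anchors$vntr_start, anchors$vntr_start + off5 - slack)
    we <- min(anchors$vntr_end, anchors$vntr_start + off5 + nchar(unit6) +
                slack - 1L)
    pattern <- unit6
    center <- locus$rs25531_offset_in_unit + 1L
  } else {
    off <- locus$rs25532_offset                      # 0-based in flank
    ctx_r <- 10L
    pattern <- substr(locus$downstream_flank, off + 1L - ctx_r,
                      off + 1L + ctx_r)
    center <- ctx_r + 1L
    ws <- anchors$down_start + off - ctx_r - slack
    we <- min(nchar(read), anchors$down_start + off + ctx_r + slack)
    if (ws < anchors$down_start) ws <- anchors$down_start
  }
  if (we - ws + 1L < nchar(pattern) - slack) return(NA_character_)
  a <- cpp_align(pattern, substr(read, ws, we), want_map = TRUE)
  if (a$identity < cfg$site_min_identity) return(NA_character_)
  mp <- a$map[center]
  if (mp == 0L) return(NA_character_)
  substr(read, ws - 1L + mp, ws - 1L + mp)
}

# scan one flank portion of the read for substitutions relative to the
# reference flank; returns "coord:base" strings in VNTR-relative flank
# coordinates (negative upstream, positive downstream)
flank_mismatches <- function(read, anchors, locus, cfg) {
  out <- character(0)
  ins_up <- 150L  # the insert begins 150 bp before the VNTR by primer design
  up_len <- nchar(locus$upstream_flank)
  ref_up <- substr(locus$upstream_flank, up_len - ins_up + 1L, up_len)
  sub_up <- substr(read, 1L, anchors$vntr_start - 1L)
  if (nchar(sub_up) >= 0.8 * ins_up) {
    a <- cpp_align(ref_up, sub_up, want_map = TRUE)
    if (a$identity >= cfg$anchor_min_identity) {
      for (q in seq_len(nchar(ref_up))) {
        mp <- a$map[q]
        if (mp == 0L) next
        obs <- substr(sub_up, mp, mp)
        if (obs != substr(ref_up, q, q))
          out <- c(out, paste0(q - ins_up - 1L, ":", obs))
      }
    }
  }
  dlen <- nchar(read) - anchors$down_start + 1L
  ref_dn <- substr(locus$downstream_flank, 1L, min(dlen + 8L,
                                                   nchar(locus$downstream_flank)))
  sub_dn <- substr(read, anchors$down_start, nchar(read))
  if (nchar(sub_dn) >= 30L) {
    a <- cpp_align(ref_dn, sub_dn, want_map = TRUE)
    if (a$identity >= cfg$anchor_min_identity) {
      skip <- locus$rs25532_offset + 1L   # known site, reported separately
      for (q in seq_len(nchar(ref_dn))) {
        if (q == skip) next
        mp <- a$map[q]
        if (mp == 0L) next
        obs <- substr(sub_dn, mp, mp)
        if (obs != substr(ref_dn, q, q))
          out <- c(out, paste0(q, ":", obs))
      }
    }
  }
  paste(out, collapse = ";")
}

#' Extract the feature vector of one read
#'
#' @param read trimmed, orientation-normalized read.
#' @param locus an `slc6a4_locus`.
#' @param cfg a [haplotyping_config()].
#' @param read_id identifier carried into the output.
#' @return one-row data.frame with columns `read_id`, `anchor_ok`,
#'   `vntr_len`, `repeat_count`, `primary_count`, `rs25531`, `rs25532`,
#'   `flank_mm`, `qc`.
#' @export
extract_read_features <- function(read, locus, cfg = haplotyping_config(),
                                  read_id = "read1") {
  anchors <- locate_anchors(read, locus, cfg)
  if (!anchors$ok) {
    return(data.frame(read_id = read_id, anchor_ok = FALSE,
                      vntr_len = NA_integer_, repeat_count = NA_integer_,
                      primary_count = NA_integer_, rs25531 = NA_character_,
                      rs25532 = NA_character_, flank_mm = NA_character_,
                      qc = anchors$reason, stringsAsFactors = FALSE))
  }
  seg <- substr(read, anchors$vntr_start, anchors$vntr_end)
  cr <- count_repeats(seg, locus, cfg)
  b31 <- extract_site_base(read, anchors, locus, "rs25531", cfg)
  b32 <- extract_site_base(read, anchors, locus, "rs25532", cfg)
  fm <- if (isTRUE(cfg$detect_flank_variants))
    flank_mismatches(read, anchors, locus, cfg) else NA_character_
  data.frame(read_id = read_id, anchor_ok = TRUE,
             vntr_len = nchar(seg), repeat_count = cr$count,
             primary_count = cr$primary, rs25531 = b31, rs25532 = b32,
             flank_mm = fm, qc = cr$qc, stringsAsFactors = FALSE)
}

#' Extract features for a set of reads
#'
#' @param reads either a named character vector of trimmed reads, or a
#'   [demux_pool()] data.frame (only assigned rows are featurized; the
#'   sample assignment is carried through).
#' @param locus an `slc6a4_locus`.
#' @param cfg a [haplotyping_config()].
#' @return data.frame, one row per read, as in [extract_read_features()]
#'   plus `sample_id` when a demultiplexing frame was given.
#' @export
featurize_reads <- function(reads, locus, cfg = haplotyping_config()) {
  if (is.data.frame(reads)) {
    dm <- reads[reads$reason == "assigned", , drop = FALSE]
    feats <- featurize_reads(setNames(dm$seq, dm$read_id), locus, cfg)
    feats$sample_id <- dm$sample_id[match(feats$read_id, dm$read_id)]
    return(feats)
  }
  ids <- if (is.null(names(reads))) sprintf("read%06d", seq_along(reads))
         else names(reads)
  rows <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    rows[[i]] <- extract_read_features(reads[[i]], locus, cfg,
                                       read_id = ids[i])
  }
  do.call(rbind, rows)
}
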