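# Clustering of a sample's read features into one or two consensus
# haplotypes and emission of the phased diplotype call. Because each amplicon
# read spans the whole VNTR plus both SNV sites, phasing is per read:
# clustering replaces statistical phasing entirely.

#' Cluster read features into haplotype groups
#'
#' Reads are grouped by their exact feature tuple (repeat count, rs25531
#' base, rs25532 base). Singleton noise groups are merged into the nearest
#' major group (nearest = fewest differing fields; ties go to the larger
#' group, then to tuple order). The top two groups are kept if the minor one
#' reaches `min_minor_fraction` of usable reads and `min_reads_per_hap`
#' support; otherwise the call is homozygous from the top group. All
#' tie-breaks are deterministic.
#'
#' @param features data.frame from [featurize_reads()] (one sample).
#' @param cfg a [haplotyping_config()].
#' @return list of 1 or 2 cluster lists (fields `repeat_count`, `rs25531`,
#'   `rs25532`, `support`, `fraction`, `read_ids`, `flank_variants`), or a
#'   no-call marker (`list(no_call = TRUE, reason = ...)`) when fewer than
#'   `min_total_reads` usable reads are available.
#' @export
cluster_reads <- function(features, cfg = haplotyping_config()) {
  usable <- features[features$anchor_ok %in% TRUE &
                       !is.na(features$repeat_count) &
                       features$repeat_count > 0L &
                       !is.na(features$rs25531) &
                       !is.na(features$rs25532), , drop = FALSE]
  n <- nrow(usable)
  if (n < cfg$min_total_reads) {
    return(list(no_call = TRUE, reason = "insufficient reads",
                usable = n))
  }
  usable$key <- paste(usable$repeat_count, usable$rs25531, usable$rs25532,
                      sep = "_")
  sizes <- table(usable$key)
  keys <- names(sizes)
  fields <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  members <- split(usable$read_id, usable$key)[keys]

  singles <- keys[sizes == 1L]
  majors <- keys[sizes >= 2L]
  if (length(singles) && length(majors)) {
    for (s in singles) {
      sf <- fields[match(s, keys), ]
      diffs <- vapply(majors, function(m)
        sum(fields[match(m, keys), ] != sf), integer(1))
      best <- majors[order(diffs, -as.integer(sizes[majors]), majors)][1]
      members[[best]] <- c(members[[best]], members[[s]])
      members[[s]] <- NULL
    }
    keep <- names(members)
    sizes <- vapply(members, length, integer(1))
    keys <- keep
    fields <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  } else {
    sizes <- as.integer(sizes)
    names(sizes) <- keys
  }

  ord <- order(-sizes, keys)
  keys <- keys[ord]; sizes <- sizes[ord]
  fields <- fields[ord, , drop = FALSE]
  members <- members[keys]

  mk_cluster <- function(i) {
    ids <- members[[i]]
    rows <- usable[usable$read_id %in% ids, , drop = FALSE]
    modal <- function(x) {
      tb <- sort(table(x), decreasing = TRUE)
      names(tb)[1]
    }
    fv <- character(0)
    if (!is.null(rows$flank_mm) && any(!is.na(rows$flank_mm))) {
      toks <- unlist(strsplit(rows$flank_mm[!is.na(rows$flank_mm)], ";",
                              fixed = TRUE))
      toks <- toks[nzchar(toks)]
      if (length(toks)) {
        tb <- table(toks)
        fv <- names(tb)[tb >= cfg$flank_variant_min_fraction * length(ids)]
      }
    }
    list(repeat_count = as.integer(modal(rows$repeat_count)),
         rs25531 = modal(rows$rs25531), rs25532 = modal(rows$rs25532),
         support = length(ids), fraction = length(ids) / n,
         read_ids = ids, flank_variants = fv)
  }

  top <- mk_cluster(1L)
  if (length(keys) >= 2L) {
    minor <- mk_cluster(2L)
    if (minor$support >= cfg$min_reads_per_hap &&
        minor$fraction >= cfg$min_minor_fraction) {
      return(list(top, minor))
    }
  }
  list(top)
}

cluster_to_haplotype <- function(cl, locus) {
  ev <- NULL
  if (length(cl$flank_variants)) {
    parts <- do.call(rbind, strsplit(cl$flank_variants, ":", fixed = TRUE))
    pos <- as.integer(parts[, 1])
    ref <- vapply(pos, function(p) {
      if (p > 0) substr(locus$downstream_flank, p, p)
      else {
        ul <- nchar(locus$upstream_flank)
        substr(locus$upstream_flank, ul + p + 1L, ul + p + 1L)
      }
    }, character(1))
    ev <- data.frame(pos = pos, ref = ref, alt = parts[, 2],
                     stringsAsFactors = FALSE)
    ev <- ev[order(ev$pos), , drop = FALSE]
  }
  promoter_haplotype(cl$repeat_count, cl$rs25531, cl$rs25532,
                     extra_variants = ev)
}

#' Call the phased diplotype of one sample
#'
#' Runs [cluster_reads()], converts the cluster consensuses into promoter
#' haplotypes, renders the canonical diplotype name, and fills the per-site
#' genotypes (which are, by construction, the multiset of the two consensus
#' haplotypes' alleles at each site). Unclassifiable repeat counts (e.g. 15)
#' are flagged in the QC block rather than failing. An insufficient or
#' inconsistent read set yields a no-call with a reason and never a partial
#' phased genotype.
#'
#' @param features data.frame from [featurize_reads()] for one sample.
#' @param locus an `slc6a4_locus`.
#' @param cfg a [haplotyping_config()].
#' @param sample_id carried into the call.
#' @return object of class `diplotype_call`.
#' @export
call_diplotype <- function(features, locus, cfg = haplotyping_config(),
                           sample_id = "sample") {
  cl <- cluster_reads(features, cfg)
  if (isTRUE(cl$no_call)) {
    return(structure(list(sample_id = sample_id, diplotype = NULL,
                          name = NA_character_, genotypes = NULL,
                          clusters = NULL,
                          qc = list(usable = cl$usable,
                                    no_call_reason = cl$reason)),
                     class = "diplotype_call"))
  }
  haps <- tryCatch(lapply(cl, cluster_to_haplotype, locus = locus),
                   error = function(e) e)
  if (inherits(haps, "error")) {
    return(structure(list(sample_id = sample_id, diplotype = NULL,
                          name = NA_character_, genotypes = NULL,
                          clusters = cl,
                          qc = list(usable = sum(vapply(cl, `[[`, 1,
                                                        "support")),
                                    no_call_reason = conditionMessage(haps))),
                     class = "diplotype_call"))
  }
  if (length(haps) == 1L) haps <- c(haps, haps)
  d <- canonical_diplotype(haps[[1]], haps[[2]])
  h1 <- d$hap1; h2 <- d$hap2
  genotypes <- list(
    rs4795541_repeats = c(h1$repeat_count, h2$repeat_count),
    rs4795541_classes = c(h1$length_class, h2$length_class),
    rs25531 = c(h1$rs25531, h2$rs25531),
    rs25532 = c(h1$rs25532, h2$rs25532))
  structure(list(
    sample_id = sample_id, diplotype = d, name = diplotype_name(d),
    genotypes = genotypes, clusters = cl,
    qc = list(usable = as.integer(round(cl[[1]]$support / cl[[1]]$fraction)),
              cluster_fractions = vapply(cl, `[[`, numeric(1), "fraction"),
              unclassified = any(c(h1$length_class, h2$length_class) ==
                                   "UNCLASSIFIED"),
              no_call_reason = NA_character_)),
    class = "diplotype_call")
}

#' @export
print.diplotype_call <- function(x, ...) {
  if (is.na(x$name)) {
    cat(sprintf("<diplotype_call> %s: NO_CALL (%s)\n", x$sample_id,
                x$qc$no_call_reason))
  } else {
    cat(sprintf("<diplotype_call> %s: %s (usable reads %d; fractions %s)\n",
                x$sample_id, x$name, x$qc$usable,
                paste(sprintf("%.2f", x$qc$cluster_fractions),
                      collapse = "/")))
  }
  invisible(x)
}

#' Call diplotypes for every sample of a featurized pool
#'
#' @param features data.frame from [featurize_reads()] carrying `sample_id`.
#' @param locus an `slc6a4_locus`.
#' @param cfg a [haplotyping_config()].
#' @return list with `calls` (named list of `diplotype_call`) and `table`
#'   (data.frame: sample_id, diplotype, hap1, hap2, rc1, rc2, usable,
#'   no_call_reason).
#' @export
call_cohort <- function(features, locus, cfg = haplotyping_config()) {
  stopifnot("sample_id" %in% names(features))
  ids <- sort(unique(features$sample_id))
  calls <- lapply(ids, function(sid)
    call_diplotype(features[features$sample_id == sid, , drop = FALSE],
                   locus, cfg, sample_id = sid))
  names(calls) <- ids
  table <- do.call(rbind, lapply(calls, function(cc) {
    if (is.na(cc$name)) {
      data.frame(sample_id = cc$sample_id, diplotype = NA_character_,
                 hap1 = NA_character_, hap2 = NA_character_,
                 rc1 = NA_integer_, rc2 = NA_integer_,
                 usable = cc$qc$usable,
                 no_call_reason = cc$qc$no_call_reason,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(sample_id = cc$sample_id, diplotype = cc$name,
                 hap1 = hap_label(cc$diplotype$hap1),
                 hap2 = hap_label(cc$diplotype$hap2),
                 rc1 = cc$diplotype$hap1$repeat_count,
                 rc2 = cc$diplotype$hap2$repeat_count,
                 usable = cc$qc$usable,
                 no_call_reason = NA_character_, stringsAsFactors = FALSE)
    }
  }))
  rownames(table) <- NULL
  list(calls = calls, table = table)
}

#' Run the full pipeline on a pooled library
#'
#' Demultiplex, featurize and call every sample of one pooled read library.
#'
#' @param reads named character vector of pooled reads.
#' @param barcodes a `barcode_table`.
#' @param locus an `slc6a4_locus`.
#' @param cfg a [haplotyping_config()].
#' @return as [call_cohort()], plus `demux` (the demultiplexing frame) and
#'   `features`.
#' @export
genotype_pool <- function(reads, barcodes, locus,
                          cfg = haplotyping_config()) {
  dm <- demux_pool(reads, barcodes, max_mm = cfg$max_mm_barcode)
  feats <- featurize_reads(dm, locus, cfg)
  res <- call_cohort(feats, locus, cfg)
  res$demux <- dm
  res$features <- feats
  res
}

# ---------------------------------------------------------------------------
# VCF output

# locus coordinates on the 16-repeat (L) reference allele
l_reference_coords <- function(locus) {
  up <- nchar(locus$upstream_flank)
  vntr <- vntr_length(locus, 16L)
  list(up = up, vntr = vntr,
       rs25531 = up + vntr_prefix_length(locus, locus$rs25531_unit_index - 1L) +
         locus$rs25531_offset_in_unit + 1L,
       rs25532 = up + vntr + locus$rs25532_offset + 1L,
       contig_len = up + vntr + nchar(locus$downstream_flank))
}

#' Emit a phased VCF for one diplotype call
#'
#' Writes VCF 4.2 text against the 16-repeat (L) allele reference:
#' rs25531 / rs25532 / extra flank variants as phased SNV records (GT with
#' `|`) and the repeat-length polymorphism rs4795541 as a symbolic-length
#' record (`<VNTR:k>` alternate alleles with the repeat counts in INFO). A
#' shared phase set (PS) links all records. Positions are 1-based.
#'
#' @param call a successful `diplotype_call`.
#' @param locus an `slc6a4_locus`.
#' @param path optional file path; when given the text is written there.
#' @return character vector of VCF lines, invisibly when `path` is given.
#' @export
emit_vcf <- function(call, locus, path = NULL) {
  stopifnot(inherits(call, "diplotype_call"))
  if (is.na(call$name)) stop("cannot emit VCF for a no-call")
  co <- l_reference_coords(locus)
  h1 <- call$diplotype$hap1; h2 <- call$diplotype$hap2
  ps <- co$up  # phase set id shared by all records

  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=SLC6A4_promoter_L,length=%d>", co$contig_len),
           "##ALT=<ID=VNTR,Description=\"Promoter tandem repeat allele; repeat count in the symbolic allele id\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of the VNTR on the L reference\">",
           "##INFO=<ID=REPEAT_COUNTS,Number=2,Type=Integer,Description=\"Called repeat counts, phased order\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
           "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", call$sample_id, sep = "\t"))

  rec <- function(pos, id, ref, alt, info, gt) {
    paste("SLC6A4_promoter_L", pos, id, ref,
          if (length(alt)) paste(alt, collapse = ",") else ".",
          ".", "PASS", info, "GT:PS", sprintf("%s:%d", gt, ps), sep = "\t")
  }

  lines <- character(0)
  # rs4795541: anchored at the last upstream base
  rcs <- c(h1$repeat_count, h2$repeat_count)
  alts <- unique(rcs[rcs != 16L])
  gt_idx <- vapply(rcs, function(k) if (k == 16L) 0L else match(k, alts),
                   integer(1))
  lines <- c(lines, rec(
    co$up, "rs4795541", substr(locus$upstream_flank, co$up, co$up),
    if (length(alts)) sprintf("<VNTR:%d>", alts) else character(0),
    sprintf("END=%d;REPEAT_COUNTS=%d,%d", co$up + co$vntr, rcs[1], rcs[2]),
    sprintf("%d|%d", gt_idx[1], gt_idx[2])))

  snv_rec <- function(pos, id, ref, b1, b2) {
    alt <- unique(c(b1, b2)[c(b1, b2) != ref])
    g <- vapply(c(b1, b2), function(b) if (b == ref) 0L else match(b, alt),
                integer(1))
    rec(pos, id, ref, alt, ".", sprintf("%d|%d", g[1], g[2]))
  }
  lines <- c(lines, snv_rec(co$rs25531, "rs25531", locus$rs25531_ref,
                            h1$rs25531, h2$rs25531))
  lines <- c(lines, snv_rec(co$rs25532, "rs25532", locus$rs25532_ref,
                            h1$rs25532, h2$rs25532))

  # extra flank variants, phased per haplotype
  evs <- unique(rbind(h1$extra_variants, h2$extra_variants))
  if (!is.null(evs) && nrow(evs)) {
    for (i in seq_len(nrow(evs))) {
      p <- evs$pos[i]
      pos <- if (p > 0) co$up + co$vntr + p else co$up + p + 1L
      has <- function(h) !is.null(h$extra_variants) &&
        any(h$extra_variants$pos == p & h$extra_variants$alt == evs$alt[i])
      g <- c(as.integer(has(h1)), as.integer(has(h2)))
      lines <- c(lines, rec(pos, sprintf("flank_%d", p), evs$ref[i],
                            evs$alt[i], ".", sprintf("%d|%d", g[1], g[2])))
    }
  }

  ord <- order(as.integer(vapply(strsplit(lines, "\t"), `[`, character(1), 2)))
  out <- c(hdr, lines[ord])
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Reconstruct a diplotype from an emitted VCF
#'
#' Parses VCF text produced by [emit_vcf()] and rebuilds the two phased
#' haplotypes, so `diplotype_name(read_diplotype_vcf(emit_vcf(call, locus)))`
#' round-trips the call.
#'
#' @param x character vector of VCF lines, or a file path.
#' @return a `promoter_diplotype`.
#' @export
read_diplotype_vcf <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  body <- lines[!startsWith(lines, "#")]
  fx <- strsplit(body, "\t")
  get <- function(id) fx[[which(vapply(fx, `[`, character(1), 3) == id)]]
  gt_pair <- function(f) as.integer(strsplit(strsplit(f[10], ":")[[1]][1],
                                             "|", fixed = TRUE)[[1]])

  r41 <- get("rs4795541")
  info <- r41[8]
  rcs <- as.integer(strsplit(sub(".*REPEAT_COUNTS=", "", info), ",")[[1]])
  alleles31 <- c(get("rs25531")[4],
                 if (get("rs25531")[5] != ".")
                   strsplit(get("rs25531")[5], ",")[[1]])
  g31 <- gt_pair(get("rs25531")) + 1L
  alleles32 <- c(get("rs25532")[4],
                 if (get("rs25532")[5] != ".")
                   strsplit(get("rs25532")[5], ",")[[1]])
  g32 <- gt_pair(get("rs25532")) + 1L
  h1 <- promoter_haplotype(rcs[1], alleles31[g31[1]], alleles32[g32[1]])
  h2 <- promoter_haplotype(rcs[2], alleles31[g31[2]], alleles32[g32[2]])
  canonical_diplotype(h1, h2)
}
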