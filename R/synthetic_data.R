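# Simulation of everything the wet lab produces: amplicons from the four
# primer sets, dual-barcoded pooled read libraries with long-read errors,
# and the equimolar pooling arithmetic.

#' Amplification primer sets
#'
#' The four overlapping primer sets that amplify the promoter region. All
#' share one forward primer; tagged primers are the universal tag followed by
#' the gene-specific part. Expected sizes are the gene-specific product
#' footprints on the 16-repeat L allele.
#'
#' @return data.frame with columns `id`, `fwd_tag`, `rev_tag`, `fwd_gene`,
#'   `rev_gene`, `expected_size`.
#' @export
primer_sets <- function() {
  data.frame(id = names(.REV_GENE),
             fwd_tag = .FWD_TAG, rev_tag = .REV_TAG,
             fwd_gene = .FWD_GENE, rev_gene = unname(.REV_GENE),
             expected_size = unname(.AMPLICON_SIZE),
             stringsAsFactors = FALSE)
}

#' Sanger confirmation primer pair
#'
#' The untagged pair used for orthogonal confirmation; its product footprint
#' (1026 bp on the L allele) coincides with the second tagged primer set.
#'
#' @return list with `fwd`, `rev`, `expected_size`.
#' @export
sanger_primers <- function() {
  list(fwd = .FWD_GENE, rev = "CCCAGCAGGAGCCTATTGTT", expected_size = 1026L)
}

#' Long-read error model
#'
#' Per-base error probabilities for circular-consensus-like reads. The
#' defaults are indel-dominant (0.2% substitution, 0.3% insertion, 0.3%
#' deletion), typical of amplicon CCS data.
#'
#' @param mismatch,insertion,deletion per-base probabilities (each >= 0, sum
#'   < 0.5).
#' @param seed optional RNG seed making simulation reproducible.
#' @return object of class `error_model`.
#' @export
error_model <- function(mismatch = 0.002, insertion = 0.003,
                        deletion = 0.003, seed = NULL) {
  rates <- c(mismatch, insertion, deletion)
  if (any(rates < 0)) stop("error rates must be non-negative")
  if (sum(rates) >= 0.5) stop("total error rate must be below 0.5")
  structure(list(mismatch = mismatch, insertion = insertion,
                 deletion = deletion, seed = seed), class = "error_model")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' In-silico PCR
#'
#' Finds products spanning a forward-strand match of the forward primer and
#' a reverse-complement match of the reverse primer, inclusive of both
#' primer footprints. Only the gene-specific primer portions are matched
#' (tags and barcodes are excluded by the caller). Matching is positional
#' with at most `max_mm` mismatches per primer and no indels.
#'
#' @param template DNA string.
#' @param fwd,rev gene-specific primer sequences (>= 15 nt).
#' @param max_mm maximum mismatches tolerated per primer.
#' @return data.frame with columns `start`, `end`, `length` (1-based,
#'   inclusive), sorted by start; zero rows if there is no product.
#' @examples
#' loc <- default_locus()
#' tmpl <- build_allele_sequence(loc, parse_haplotype_name("LAC"))
#' in_silico_pcr(tmpl, sanger_primers()$fwd, sanger_primers()$rev)
#' @export
in_silico_pcr <- function(template, fwd, rev, max_mm = 0L) {
  if (nchar(fwd) < 15L || nchar(rev) < 15L)
    stop("primers must be at least 15 nt")
  if (nchar(template) < max(nchar(fwd), nchar(rev)))
    stop("template shorter than the primers")
  f_starts <- cpp_scan(template, fwd, max_mm)
  r_starts <- cpp_scan(template, cpp_revcomp(rev), max_mm)
  out <- data.frame(start = integer(0), end = integer(0), length = integer(0))
  for (f in f_starts) {
    for (r in r_starts) {
      e <- r + nchar(rev) - 1L
      if (r > f + nchar(fwd) - 1L) {
        out <- rbind(out, data.frame(start = f, end = e, length = e - f + 1L))
      }
    }
  }
  out[order(out$start, out$end), , drop = FALSE]
}

#' Simulate error-bearing reads from one amplicon
#'
#' Each read is the amplicon passed through per-base substitution /
#' insertion / deletion sampling under the error model; about half of the
#' reads are reverse-complemented. Reproducible when the error model carries
#' a seed.
#'
#' @param amplicon DNA string.
#' @param n_reads number of reads (>= 1).
#' @param em an [error_model()].
#' @return data.frame with columns `seq` and `is_rc`.
#' @export
simulate_reads <- function(amplicon, n_reads, em = error_model()) {
  stopifnot(n_reads >= 1)
  gen <- function() {
    is_rc <- runif(n_reads) < 0.5
    seqs <- cpp_mutate(rep(amplicon, n_reads), em$mismatch, em$insertion,
                       em$deletion)
    if (any(is_rc)) seqs[is_rc] <- revcomp_chr(seqs[is_rc])
    data.frame(seq = seqs, is_rc = is_rc, stringsAsFactors = FALSE)
  }
  if (is.null(em$seed)) gen() else withr::with_seed(em$seed, gen())
}

#' Attach dual barcodes and universal tags to a read
#'
#' Forward layout: `barcode_fwd + fwd_tag + read + revcomp(rev_tag +
#' barcode_rev)`. For a reverse-complemented read the same molecule is
#' produced on the opposite strand (the layout is applied in the forward
#' frame and the whole product reverse-complemented), so demultiplexing is
#' orientation-symmetric.
#'
#' @param read DNA string (insert, forward frame unless
#'   `orientation = "reverse"`).
#' @param sample list or one-row data.frame with `barcode_fwd`,
#'   `barcode_rev`.
#' @param orientation `"forward"` or `"reverse"`.
#' @return barcoded read (character).
#' @export
attach_barcodes <- function(read, sample, orientation = "forward") {
  bcf <- as.character(sample$barcode_fwd)
  bcr <- as.character(sample$barcode_rev)
  if (!nzchar(bcf) || !nzchar(bcr))
    stop("invalid sample: barcodes must be non-empty")
  orientation <- match.arg(orientation, c("forward", "reverse"))
  fwd_frame <- if (orientation == "reverse") cpp_revcomp(read) else read
  out <- paste0(bcf, .FWD_TAG, fwd_frame, cpp_revcomp(paste0(.REV_TAG, bcr)))
  if (orientation == "reverse") cpp_revcomp(out) else out
}

#' Equimolar pooling volume
#'
#' Volume of amplicon i to pool so every sample contributes equal mass:
#' `V(i) = M / (n * C(i))`, where M is the total pooled mass (ng), n the
#' sample count and C(i) the amplicon concentration (ng/uL). The per-sample
#' mass contribution `V(i) * C(i) = M / n` is constant, so volumes sum to
#' mass M overall.
#'
#' @param total_mass M, total pooled mass in ng (> 0).
#' @param n_samples n, number of samples (> 0).
#' @param concentration C(i), amplicon concentration(s) in ng/uL; vectorized.
#' @return volume(s) in uL.
#' @examples
#' pooling_volume(4000, 120, 10)   # 3.333 uL
#' @export
pooling_volume <- function(total_mass, n_samples, concentration) {
  if (any(concentration == 0)) stop("division by zero: concentration is 0")
  if (total_mass <= 0 || n_samples <= 0 || any(concentration < 0))
    stop("all pooling arguments must be positive")
  total_mass / (n_samples * concentration)
}

#' Generate a dual-barcode sample sheet
#'
#' Draws barcode pairs of the requested length by seeded greedy search so
#' that every pair of barcodes in the pool differs by at least `min_dist`
#' edits (Levenshtein), giving headroom for mismatch-tolerant demultiplexing.
#'
#' @param n_samples number of samples.
#' @param seed RNG seed.
#' @param bc_length barcode length in nt.
#' @param min_dist minimum pairwise edit distance between any two barcodes.
#' @return data.frame of class `barcode_table` with columns `sample_id`,
#'   `barcode_fwd`, `barcode_rev`; the realized minimum pairwise distance is
#'   stored in attribute `min_pairwise_dist`.
#' @export
make_barcode_table <- function(n_samples, seed = 1L, bc_length = 16L,
                               min_dist = 5L) {
  stopifnot(n_samples >= 1)
  need <- 2L * n_samples
  bcs <- withr::with_seed(seed, {
    acc <- character(0)
    tries <- 0L
    while (length(acc) < need) {
      cand <- rand_dna(bc_length, gc = 0.5)
      tries <- tries + 1L
      if (tries > 200L * need) stop("barcode search did not converge")
      if (grepl("(A{5}|C{5}|G{5}|T{5})", cand)) next
      if (length(acc) == 0 || min(adist(cand, acc)) >= min_dist)
        acc <- c(acc, cand)
    }
    acc
  })
  tbl <- data.frame(sample_id = sprintf("S%03d", seq_len(n_samples)),
                    barcode_fwd = bcs[seq(1L, need, by = 2L)],
                    barcode_rev = bcs[seq(2L, need, by = 2L)],
                    stringsAsFactors = FALSE)
  attr(tbl, "min_pairwise_dist") <- min(adist(bcs)[upper.tri(diag(need))])
  class(tbl) <- c("barcode_table", "data.frame")
  tbl
}

# gene-specific amplicon insert for one haplotype (cached per call site)
amplicon_insert <- function(locus, hap, primer_set = "R4") {
  ps <- primer_sets()
  row <- ps[ps$id == primer_set, ]
  if (nrow(row) != 1L) stop("unknown primer set: ", primer_set)
  tmpl <- build_allele_sequence(locus, hap)
  prod <- in_silico_pcr(tmpl, row$fwd_gene, row$rev_gene, max_mm = 0L)
  if (nrow(prod) != 1L)
    stop("expected exactly one in-silico product for ", hap_label(hap))
  substr(tmpl, prod$start, prod$end)
}

#' Simulate one pooled, dual-barcoded read library
#'
#' For every sample, both allele amplicons (default: the longest primer-set
#' product, which spans all variant sites) are read `coverage` times through
#' the error model, barcoded, and pooled; about half of the final reads are
#' reverse-complemented.
#'
#' @param locus an `slc6a4_locus`.
#' @param samples data.frame with columns `sample_id`, `barcode_fwd`,
#'   `barcode_rev`, `hap1`, `hap2`, `rc1`, `rc2` (haplotype names and repeat
#'   counts).
#' @param coverage reads per allele.
#' @param em an [error_model()].
#' @param seed RNG seed.
#' @param primer_set which primer set's product to sequence.
#' @return named character vector of pooled reads (names are read ids).
#' @export
simulate_pool <- function(locus, samples, coverage = 100L,
                          em = error_model(), seed = 1L,
                          primer_set = "R4") {
  stopifnot(coverage >= 1)
  cache <- new.env(parent = emptyenv())
  get_insert <- function(nm, rc) {
    key <- paste0(nm, "_", rc)
    if (is.null(cache[[key]])) {
      hap <- parse_haplotype_name(nm, repeat_count = rc)
      cache[[key]] <- amplicon_insert(locus, hap, primer_set)
    }
    cache[[key]]
  }
  withr::with_seed(seed, {
    chunks <- vector("list", 2L * nrow(samples))
    k <- 0L
    for (i in seq_len(nrow(samples))) {
      smp <- samples[i, ]
      for (a in 1:2) {
        ins <- get_insert(smp[[paste0("hap", a)]], smp[[paste0("rc", a)]])
        reads <- cpp_mutate(rep(ins, coverage), em$mismatch, em$insertion,
                            em$deletion)
        reads <- vapply(reads, attach_barcodes, character(1),
                        sample = smp, USE.NAMES = FALSE)
        is_rc <- runif(coverage) < 0.5
        if (any(is_rc)) reads[is_rc] <- revcomp_chr(reads[is_rc])
        names(reads) <- sprintf("%s_a%d_r%04d", smp$sample_id, a,
                                seq_len(coverage))
        k <- k + 1L
        chunks[[k]] <- reads
      }
    }
    unlist(chunks)
  })
}

#' Simulate a diploid cohort and its pooled library
#'
#' Each sample draws two haplotypes i.i.d. from `hap_freqs` (which must sum
#' to 1), receives a dual-barcode pair, and contributes `coverage` reads per
#' allele to one pooled library. Haplotype names map to representative
#' repeat counts (XS 12, S 14, L 16, XL 17).
#'
#' @param locus an `slc6a4_locus`.
#' @param hap_freqs named numeric vector of haplotype frequencies.
#' @param n_samples cohort size.
#' @param coverage reads per allele.
#' @param em an [error_model()].
#' @param seed RNG seed.
#' @param out_dir optional directory; when given, writes `pool.fastq`,
#'   `truth.tsv`, `barcodes.tsv` and `locus_alleles.fasta` there.
#' @return list with `truth` (data.frame: sample_id, hap1, hap2, rc1, rc2),
#'   `barcodes` (a `barcode_table`), `reads` (named character vector) and
#'   `locus`.
#' @export
simulate_cohort <- function(locus, hap_freqs, n_samples, coverage = 100L,
                            em = error_model(), seed = 1L, out_dir = NULL) {
  if (abs(sum(hap_freqs) - 1) > 1e-9)
    stop("invalid config: haplotype frequencies must sum to 1")
  if (n_samples == 0L) {
    empty <- list(truth = data.frame(sample_id = character(0),
                                     hap1 = character(0), hap2 = character(0),
                                     rc1 = integer(0), rc2 = integer(0)),
                  barcodes = NULL, reads = character(0), locus = locus)
    return(empty)
  }
  barcodes <- make_barcode_table(n_samples, seed = seed)
  truth <- withr::with_seed(seed, {
    draws <- matrix(sample(names(hap_freqs), 2L * n_samples, replace = TRUE,
                           prob = hap_freqs), ncol = 2L)
    t(apply(draws, 1L, function(p) {
      d <- canonical_diplotype(parse_haplotype_name(p[1]),
                               parse_haplotype_name(p[2]))
      c(hap_label(d$hap1), hap_label(d$hap2),
        d$hap1$repeat_count, d$hap2$repeat_count)
    }))
  })
  truth <- data.frame(sample_id = barcodes$sample_id,
                      hap1 = truth[, 1], hap2 = truth[, 2],
                      rc1 = as.integer(truth[, 3]),
                      rc2 = as.integer(truth[, 4]),
                      stringsAsFactors = FALSE)
  samples <- cbind(barcodes, truth[, c("hap1", "hap2", "rc1", "rc2")])
  reads <- simulate_pool(locus, samples, coverage = coverage, em = em,
                         seed = seed + 1L)
  out <- list(truth = truth, barcodes = barcodes, reads = reads,
              locus = locus)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pooled_fastq(reads, file.path(out_dir, "pool.fastq"))
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(barcodes), file.path(out_dir, "barcodes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_allele_fasta(locus, file.path(out_dir, "locus_alleles.fasta"))
  }
  out
}

#' Write / read a pooled FASTQ
#'
#' Reads are written with constant Q30 placeholder qualities (no
#' quality-aware logic exists downstream).
#'
#' @param reads named character vector of reads.
#' @param path FASTQ path.
#' @return `write_pooled_fastq` returns `path` invisibly;
#'   `read_pooled_fastq` returns a named character vector.
#' @export
write_pooled_fastq <- function(reads, path) {
  dss <- Biostrings::DNAStringSet(unname(reads))
  names(dss) <- names(reads)
  quals <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep("?", n), character(1)))  # "?" = Phred Q30
  Biostrings::writeXStringSet(dss, filepath = path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' @rdname write_pooled_fastq
#' @export
read_pooled_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(dss), names(dss))
}
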