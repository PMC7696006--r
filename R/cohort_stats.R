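# Cohort-level summaries: haplotype frequency tables, per-variant minor
# allele frequencies, callset-vs-callset concordance, and the replicate
# precision (3:1:1) harness.

#' Haplotype counts observed in the 120-sample long-read reference cohort
#'
#' The six promoter haplotypes and their allele counts (240 alleles total)
#' reported for a 120-individual Coriell reference cohort resolved by
#' long-read amplicon sequencing. Useful as realistic frequency targets for
#' simulation and as a worked input for the frequency calculator.
#'
#' @return named integer vector of allele counts.
#' @export
reference_cohort_counts <- function() {
  c(LAC = 101L, SAC = 89L, LGC = 26L, SAT = 21L, XLAC = 2L, SGC = 1L)
}

hap_name_parts <- function(names) {
  cls <- sub("^\\(?([0-9]+\\)|XS|XL|S|L).*$", "\\1", names)
  cls <- sub("\\)$", "", cls)
  data.frame(name = names, class = cls,
             rs25531 = substr(names, nchar(names) - 1L, nchar(names) - 1L),
             rs25532 = substr(names, nchar(names), nchar(names)),
             stringsAsFactors = FALSE)
}

#' Haplotype frequency table
#'
#' @param x either a named vector of allele counts (one entry per haplotype
#'   name) or a calls table from [call_cohort()] (each called sample
#'   contributes its two haplotypes; no-calls are skipped).
#' @return data.frame of class `cohort_table` with columns `haplotype`,
#'   `count`, `frequency`, sorted by decreasing count; total allele count in
#'   attribute `total_alleles`.
#' @examples
#' haplotype_frequency_table(reference_cohort_counts())
#' @export
haplotype_frequency_table <- function(x) {
  if (is.data.frame(x)) {
    called <- x[!is.na(x$hap1) & !is.na(x$hap2), , drop = FALSE]
    counts <- table(c(called$hap1, called$hap2))
    x <- setNames(as.integer(counts), names(counts))
  }
  if (length(x) == 0L) {
    out <- data.frame(haplotype = character(0), count = integer(0),
                      frequency = numeric(0))
    attr(out, "total_alleles") <- 0L
    class(out) <- c("cohort_table", "data.frame")
    return(out)
  }
  total <- sum(x)
  out <- data.frame(haplotype = names(x), count = as.integer(x),
                    frequency = as.numeric(x) / total,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$haplotype), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_alleles") <- as.integer(total)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Per-variant minor allele frequencies
#'
#' Derives the three clinically reported MAFs from a haplotype count vector:
#' the short-class (S) fraction of rs4795541, the rs25531 G fraction and the
#' rs25532 T fraction.
#'
#' @param counts named vector of haplotype allele counts, or a
#'   `cohort_table`.
#' @return data.frame with columns `variant`, `allele`, `count`, `total`,
#'   `maf`.
#' @examples
#' variant_mafs(reference_cohort_counts())
#' @export
variant_mafs <- function(counts) {
  if (inherits(counts, "cohort_table"))
    counts <- setNames(counts$count, counts$haplotype)
  total <- sum(counts)
  parts <- hap_name_parts(names(counts))
  n_s <- sum(counts[parts$class == "S"])
  n_g <- sum(counts[parts$rs25531 == "G"])
  n_t <- sum(counts[parts$rs25532 == "T"])
  data.frame(variant = c("rs4795541", "rs25531", "rs25532"),
             allele = c("S", "G", "T"),
             count = as.integer(c(n_s, n_g, n_t)),
             total = as.integer(total),
             maf = c(n_s, n_g, n_t) / total,
             stringsAsFactors = FALSE)
}

#' Allele frequencies of a callset
#'
#' Counts each called haplotype occurrence (two per sample) and reports the
#' haplotype frequency table together with the per-variant MAFs.
#'
#' @param calls calls table from [call_cohort()] (or a named count vector).
#' @return list with `table` (a `cohort_table`) and `mafs`.
#' @export
allele_frequencies <- function(calls) {
  tbl <- haplotype_frequency_table(calls)
  list(table = tbl, mafs = variant_mafs(tbl))
}

#' @export
print.cohort_table <- function(x, ...) {
  total <- attr(x, "total_alleles")
  cat(sprintf("<cohort_table> %d alleles\n", total))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-6s %4d (%s)\n", x$haplotype[i], x$count[i],
                format(round(x$frequency[i], 3), nsmall = 3)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# concordance

row_genotypes <- function(row) {
  if (is.na(row$hap1) || is.na(row$hap2)) return(NULL)
  b <- function(h, k) substr(h, nchar(h) - 2L + k, nchar(h) - 2L + k)
  list(rs4795541 = sort(c(row$rc1, row$rc2)),
       rs25531 = sort(c(b(row$hap1, 1L), b(row$hap2, 1L))),
       rs25532 = sort(c(b(row$hap1, 2L), b(row$hap2, 2L))))
}

#' Concordance between two callsets
#'
#' For every shared sample, compares the three variant-site genotypes
#' (rs4795541 as the unordered repeat-count pair; rs25531 and rs25532 as
#' unordered base pairs) and the two canonically ordered haplotype names. A
#' no-call on either side counts as discordant and is itemized. Percentages
#' are always derived from the tallies, never stored.
#'
#' @param a,b calls tables (data.frames with `sample_id`, `hap1`, `hap2`,
#'   `rc1`, `rc2`), e.g. from [call_cohort()] or a truth table from
#'   [simulate_cohort()].
#' @return object of class `concordance_report` with fields
#'   `genotype_concordant`, `genotype_total`, `haplotype_concordant`,
#'   `haplotype_total` and a per-comparison `detail` data.frame.
#' @export
callset_concordance <- function(a, b) {
  shared <- intersect(a$sample_id, b$sample_id)
  if (length(shared) == 0L) stop("invalid input: no shared sample ids")
  detail <- list()
  g_conc <- 0L; g_tot <- 0L; h_conc <- 0L; h_tot <- 0L
  for (sid in shared) {
    ra <- a[a$sample_id == sid, ][1, ]
    rb <- b[b$sample_id == sid, ][1, ]
    ga <- row_genotypes(ra); gb <- row_genotypes(rb)
    for (site in c("rs4795541", "rs25531", "rs25532")) {
      ok <- !is.null(ga) && !is.null(gb) && identical(ga[[site]], gb[[site]])
      g_tot <- g_tot + 1L; g_conc <- g_conc + ok
      detail[[length(detail) + 1L]] <- data.frame(
        sample_id = sid, kind = "genotype", item = site,
        a = if (is.null(ga)) "NO_CALL" else paste(ga[[site]], collapse = "/"),
        b = if (is.null(gb)) "NO_CALL" else paste(gb[[site]], collapse = "/"),
        concordant = ok, stringsAsFactors = FALSE)
    }
    for (k in 1:2) {
      ha <- ra[[paste0("hap", k)]]; hb <- rb[[paste0("hap", k)]]
      ok <- !is.na(ha) && !is.na(hb) && ha == hb
      h_tot <- h_tot + 1L; h_conc <- h_conc + ok
      detail[[length(detail) + 1L]] <- data.frame(
        sample_id = sid, kind = "haplotype", item = paste0("hap", k),
        a = ifelse(is.na(ha), "NO_CALL", ha),
        b = ifelse(is.na(hb), "NO_CALL", hb),
        concordant = ok, stringsAsFactors = FALSE)
    }
  }
  structure(list(genotype_concordant = as.integer(g_conc),
                 genotype_total = g_tot,
                 haplotype_concordant = as.integer(h_conc),
                 haplotype_total = h_tot,
                 detail = do.call(rbind, detail)),
            class = "concordance_report")
}

#' Percentages of a concordance report
#'
#' @param report a `concordance_report` (or precision report).
#' @return list with `genotype`, `haplotype` and `combined` percentages.
#' @export
concordance_percent <- function(report) {
  list(genotype = 100 * report$genotype_concordant / report$genotype_total,
       haplotype = 100 * report$haplotype_concordant / report$haplotype_total,
       combined = 100 *
         (report$genotype_concordant + report$haplotype_concordant) /
         (report$genotype_total + report$haplotype_total))
}

#' @export
print.concordance_report <- function(x, ...) {
  p <- concordance_percent(x)
  cat(sprintf("<concordance_report> genotypes %d/%d (%.1f%%); haplotypes %d/%d (%.1f%%)\n",
              x$genotype_concordant, x$genotype_total, p$genotype,
              x$haplotype_concordant, x$haplotype_total, p$haplotype))
  invisible(x)
}

# ---------------------------------------------------------------------------
# precision (3:1:1) harness

#' Default precision panel
#'
#' Fifteen diploid reference-style samples that collectively carry every
#' observed promoter haplotype (LAC, SAC, LGC, SAT, XLAC, SGC), including
#' two distinct extra-long repeat counts.
#'
#' @return truth table data.frame (`sample_id`, `hap1`, `hap2`, `rc1`,
#'   `rc2`) in canonical order.
#' @export
default_precision_panel <- function() {
  spec <- list(
    list("LAC", "SAC"), list("LAC", "LGC"), list("LGC", "SAC"),
    list("LAC", "SAT"), list("SAC", "SAT"), list("SAT", "SAT"),
    list("LGC", "LGC"), list("SAC", "SAC"), list("LAC", c("XLAC", 17L)),
    list("SAC", c("XLAC", 20L)), list("LGC", "SAT"), list("LAC", "SGC"),
    list("SGC", "SAC"), list("SGC", "SAT"), list(c("XLAC", 17L), "SAT"))
  mk <- function(h) {
    if (length(h) == 2L)
      parse_haplotype_name(h[1], repeat_count = as.integer(h[2]))
    else parse_haplotype_name(h)
  }
  rows <- lapply(seq_along(spec), function(i) {
    d <- canonical_diplotype(mk(spec[[i]][[1]]), mk(spec[[i]][[2]]))
    data.frame(sample_id = sprintf("S%03d", i),
               hap1 = hap_label(d$hap1), hap2 = hap_label(d$hap2),
               rc1 = d$hap1$repeat_count, rc2 = d$hap2$repeat_count,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Replicate precision experiment (3:1:1 design)
#'
#' Simulates `n_replicates` independent barcoded libraries per sample
#' (distinct seeds; operationally three intra-run plus two inter-run
#' replicates when `n_replicates = 5`), runs the full
#' demultiplex/featurize/call pipeline on each, and tallies genotype
#' concordance against truth over samples x 3 sites x replicates and
#' haplotype concordance over samples x 2 x replicates. Replicate no-calls
#' count as discordant. Pairwise replicate-vs-replicate agreement is also
#' tallied.
#'
#' @param panel truth table (default [default_precision_panel()]).
#' @param n_replicates number of replicate libraries per sample (>= 2).
#' @param coverage reads per allele per replicate.
#' @param em an [error_model()].
#' @param cfg a [haplotyping_config()].
#' @param locus an `slc6a4_locus` (default [default_locus()]).
#' @param seed master seed; replicate seeds are derived from it.
#' @return object of class `precision_report`: the truth-referenced tallies
#'   (`genotype_concordant` of `genotype_total`, `haplotype_concordant` of
#'   `haplotype_total`), `pairwise` (summed replicate-pair tallies),
#'   `replicate_reports`, and `callsets`.
#' @export
precision_harness <- function(panel = default_precision_panel(),
                              n_replicates = 5L, coverage = 100L,
                              em = error_model(),
                              cfg = haplotyping_config(),
                              locus = default_locus(), seed = 1L) {
  stopifnot(n_replicates >= 2L)
  barcodes <- make_barcode_table(nrow(panel), seed = seed)
  samples <- cbind(barcodes, panel[, c("hap1", "hap2", "rc1", "rc2")])
  rep_seeds <- withr::with_seed(seed, sample.int(1e7L, n_replicates))
  callsets <- vector("list", n_replicates)
  reports <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    reads <- simulate_pool(locus, samples, coverage = coverage, em = em,
                           seed = rep_seeds[r])
    res <- genotype_pool(reads, barcodes, locus, cfg)
    callsets[[r]] <- res$table
    reports[[r]] <- callset_concordance(res$table, panel)
  }
  g_conc <- sum(vapply(reports, `[[`, integer(1), "genotype_concordant"))
  g_tot <- sum(vapply(reports, `[[`, integer(1), "genotype_total"))
  h_conc <- sum(vapply(reports, `[[`, integer(1), "haplotype_concordant"))
  h_tot <- sum(vapply(reports, `[[`, integer(1), "haplotype_total"))

  pw <- list(genotype_concordant = 0L, genotype_total = 0L,
             haplotype_concordant = 0L, haplotype_total = 0L)
  if (n_replicates >= 2L) {
    for (i in seq_len(n_replicates - 1L)) {
      for (j in seq(i + 1L, n_replicates)) {
        cc <- callset_concordance(callsets[[i]], callsets[[j]])
        pw$genotype_concordant <- pw$genotype_concordant + cc$genotype_concordant
        pw$genotype_total <- pw$genotype_total + cc$genotype_total
        pw$haplotype_concordant <- pw$haplotype_concordant + cc$haplotype_concordant
        pw$haplotype_total <- pw$haplotype_total + cc$haplotype_total
      }
    }
  }
  structure(list(genotype_concordant = g_conc, genotype_total = g_tot,
                 haplotype_concordant = h_conc, haplotype_total = h_tot,
                 pairwise = pw, replicate_reports = reports,
                 callsets = callsets, panel = panel),
            class = c("precision_report", "concordance_report"))
}

#' @export
print.precision_report <- function(x, ...) {
  p <- concordance_percent(x)
  cat(sprintf("<precision_report> %d samples x %d replicates\n",
              nrow(x$panel), length(x$callsets)))
  cat(sprintf("  vs truth: genotypes %d/%d (%.1f%%); haplotypes %d/%d (%.1f%%)\n",
              x$genotype_concordant, x$genotype_total, p$genotype,
              x$haplotype_concordant, x$haplotype_total, p$haplotype))
  pp <- concordance_percent(x$pairwise)
  cat(sprintf("  replicate pairs: genotypes %d/%d (%.1f%%); haplotypes %d/%d (%.1f%%)\n",
              x$pairwise$genotype_concordant, x$pairwise$genotype_total,
              pp$genotype, x$pairwise$haplotype_concordant,
              x$pairwise$haplotype_total, pp$haplotype))
  invisible(x)
}
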