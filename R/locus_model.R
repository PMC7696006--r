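# Parametric model of the SLC6A4 promoter: flanks, repeat-unit library,
# allele structures and the haplotype/diplotype nomenclature.

# length-class symbols in canonical diplotype order
.CLASS_RANK <- c(L = 1L, S = 2L, XL = 3L, XS = 4L, UNCLASSIFIED = 5L)

# representative repeat counts used when a haplotype is built from its name
.CLASS_COUNT <- c(XS = 12L, S = 14L, L = 16L, XL = 17L)

#' Classify a 5-HTTLPR repeat count into a promoter length class
#'
#' The common alleles are long (L; 16 repeats) and short (S; 14 repeats);
#' rarer extra-long (XL; 17--24 repeats) and extra-short (XS; 11--13 repeats)
#' alleles also occur. The class table has a gap at 15 repeats: counts of 15,
#' and anything outside 11--24, are reported as `"UNCLASSIFIED"` rather than
#' silently binned.
#'
#' @param n integer vector of repeat counts (each between 1 and 50).
#' @return character vector of classes: `"XS"`, `"S"`, `"L"`, `"XL"` or
#'   `"UNCLASSIFIED"`.
#' @examples
#' classify_repeat_count(c(14, 16, 18, 15))
#' @export
classify_repeat_count <- function(n) {
  if (length(n) == 0L || !is.numeric(n) || anyNA(n))
    stop("repeat count must be numeric and non-missing")
  if (any(n != as.integer(n)))
    stop("repeat count must be a whole number")
  if (any(n < 1 | n > 50))
    stop("repeat count must be between 1 and 50")
  n <- as.integer(n)
  cls <- rep("UNCLASSIFIED", length(n))
  cls[n >= 11L & n <= 13L] <- "XS"
  cls[n == 14L] <- "S"
  cls[n == 16L] <- "L"
  cls[n >= 17L & n <= 24L] <- "XL"
  cls
}

#' Construct a promoter haplotype
#'
#' A haplotype is the phased combination of the 5-HTTLPR repeat count (hence
#' its length class), the rs25531 base (A/G) and the rs25532 base (C/T), plus
#' any additional flanking substitutions. Flank variant positions use
#' VNTR-relative flank coordinates: positive p is the p-th base of the
#' downstream flank, negative p counts back from the VNTR start (-1 is the
#' last upstream base).
#'
#' @param repeat_count integer number of repeat units (1--50).
#' @param rs25531 `"A"` (reference) or `"G"`.
#' @param rs25532 `"C"` (reference) or `"T"`.
#' @param extra_variants optional data.frame with columns `pos` (flank
#'   coordinate), `ref`, `alt`.
#' @return object of class `promoter_haplotype`.
#' @examples
#' promoter_haplotype(16, "G", "C")   # the "LGC" haplotype
#' @export
promoter_haplotype <- function(repeat_count, rs25531 = "A", rs25532 = "C",
                               extra_variants = NULL) {
  if (!rs25531 %in% c("A", "G")) stop("rs25531 base must be A or G")
  if (!rs25532 %in% c("C", "T")) stop("rs25532 base must be C or T")
  cls <- classify_repeat_count(repeat_count)
  if (!is.null(extra_variants)) {
    stopifnot(is.data.frame(extra_variants),
              all(c("pos", "ref", "alt") %in% names(extra_variants)))
  }
  structure(list(length_class = cls,
                 repeat_count = as.integer(repeat_count),
                 rs25531 = rs25531, rs25532 = rs25532,
                 extra_variants = extra_variants),
            class = "promoter_haplotype")
}

#' Name a promoter haplotype
#'
#' Concatenates the length-class symbol with the rs25531 and rs25532 bases,
#' e.g. 16 repeats + A + C renders `"LAC"`. Unclassifiable repeat counts
#' (15, or outside 11--24) cannot be named and raise an error of class
#' `httlpr_unnamable` carrying the raw count.
#'
#' @param h a [promoter_haplotype()].
#' @return single character name such as `"LAC"`, `"SGC"`, `"XLAC"`.
#' @export
haplotype_name <- function(h) {
  stopifnot(inherits(h, "promoter_haplotype"))
  if (h$length_class == "UNCLASSIFIED") {
    cond <- structure(
      class = c("httlpr_unnamable", "error", "condition"),
      list(message = sprintf(
             "repeat count %d has no length class and cannot be named",
             h$repeat_count),
           call = sys.call(-1), repeat_count = h$repeat_count))
    stop(cond)
  }
  paste0(h$length_class, h$rs25531, h$rs25532)
}

# tolerant label used in reports: unclassified counts render as "(15)AC"
hap_label <- function(h) {
  if (h$length_class == "UNCLASSIFIED")
    paste0("(", h$repeat_count, ")", h$rs25531, h$rs25532)
  else haplotype_name(h)
}

#' Parse a haplotype name into a promoter haplotype
#'
#' Inverse of [haplotype_name()] over the 16 nameable class/base
#' combinations. Length classes map to representative repeat counts
#' (XS 12, S 14, L 16, XL 17) unless `repeat_count` is supplied.
#'
#' @param name haplotype name such as `"LAC"` or `"XLGC"`.
#' @param repeat_count optional explicit repeat count overriding the class
#'   representative (must belong to the named class).
#' @return a [promoter_haplotype()].
#' @export
parse_haplotype_name <- function(name, repeat_count = NULL) {
  m <- regmatches(name, regexec("^(XS|XL|S|L)([AG])([CT])$", name))[[1]]
  if (length(m) != 4L) stop("not a valid haplotype name: ", name)
  cls <- m[2]
  rc <- if (is.null(repeat_count)) .CLASS_COUNT[[cls]] else as.integer(repeat_count)
  if (classify_repeat_count(rc) != cls)
    stop(sprintf("repeat count %d is not in length class %s", rc, cls))
  promoter_haplotype(rc, m[3], m[4])
}

# total order over haplotypes: class rank L < S < XL < XS, then rs25531 A < G,
# then rs25532 C < T, then repeat count
hap_order_key <- function(h) {
  c(.CLASS_RANK[[h$length_class]],
    match(h$rs25531, c("A", "G")),
    match(h$rs25532, c("C", "T")),
    h$repeat_count)
}

#' Canonically ordered diplotype
#'
#' Orders a pair of haplotypes into the conventional report order
#' (class rank L < S < XL < XS, ties broken on rs25531 A < G, then rs25532
#' C < T, then repeat count), matching printed exemplars such as "LGC/SAC"
#' and "SAC/XLAC". The ordering is total and idempotent, and independent of
#' argument order.
#'
#' @param a,b [promoter_haplotype()] objects.
#' @return object of class `promoter_diplotype` with fields `hap1`, `hap2`.
#' @examples
#' d <- canonical_diplotype(parse_haplotype_name("SAC"),
#'                          parse_haplotype_name("LGC"))
#' diplotype_name(d)   # "LGC/SAC"
#' @export
canonical_diplotype <- function(a, b) {
  stopifnot(inherits(a, "promoter_haplotype"), inherits(b, "promoter_haplotype"))
  ka <- hap_order_key(a); kb <- hap_order_key(b)
  swap <- FALSE
  for (i in seq_along(ka)) {
    if (ka[i] != kb[i]) { swap <- ka[i] > kb[i]; break }
  }
  if (swap) { tmp <- a; a <- b; b <- tmp }
  structure(list(hap1 = a, hap2 = b), class = "promoter_diplotype")
}

#' Render a diplotype name
#'
#' @param d a `promoter_diplotype`.
#' @return character like `"LGC/SAC"`; unclassified haplotypes render with
#'   their raw repeat count, e.g. `"(15)AC"`.
#' @export
diplotype_name <- function(d) {
  stopifnot(inherits(d, "promoter_diplotype"))
  paste0(hap_label(d$hap1), "/", hap_label(d$hap2))
}

#' @export
print.promoter_haplotype <- function(x, ...) {
  cat(sprintf("<promoter_haplotype> %s (%d repeats, rs25531=%s, rs25532=%s)\n",
              hap_label(x), x$repeat_count, x$rs25531, x$rs25532))
  if (!is.null(x$extra_variants) && nrow(x$extra_variants))
    cat("  extra flank variants:",
        paste(sprintf("%d:%s>%s", x$extra_variants$pos, x$extra_variants$ref,
                      x$extra_variants$alt), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.promoter_diplotype <- function(x, ...) {
  cat("<promoter_diplotype>", diplotype_name(x), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# locus construction

# fixed unit lengths (bp) of the 16-unit library; units 15 + 16 sum to 43 so
# that the S allele (units 1..14) is exactly 43 bp shorter than L (1..16)
.UNIT_LENGTHS <- c(22L, 21L, 23L, 22L, 20L, 22L, 24L, 21L,
                   22L, 23L, 20L, 22L, 21L, 22L, 21L, 22L)

.FWD_GENE <- "CTTTGCGTTTTCTGTTGCCCT"
.REV_GENE <- c(R1 = "GAGGGACTGAGCTGGACAACCAC",
               R2 = "CCCAGCAGGAGCCTATTGTT",
               R3 = "TCTCTTGACCTCGGACACCT",
               R4 = "GAAAGAAACGTGGGTTCGAGG")
.AMPLICON_SIZE <- c(R1 = 699L, R2 = 1026L, R3 = 1536L, R4 = 2096L)
.FWD_TAG <- "ATGGGTTCCAGAGTCAATC"
.REV_TAG <- "GAAAGGTCTGGAGTCTTGAT"

rand_dna <- function(n, gc = 0.55) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

`substr_set` <- function(x, at, value) {
  substr(x, at, at + nchar(value) - 1L) <- value
  x
}

#' Build the default synthetic promoter locus
#'
#' Constructs a parametric promoter with the documented architecture: a
#' unique upstream flank, a VNTR of up to 24 highly homologous 20--24 bp
#' units, rs25531 anchored inside the sixth unit, and a downstream flank
#' whose mu element carries rs25532. Units 15 and 16 together span exactly
#' 43 bp, so the 16-unit L allele is 43 bp longer than the 14-unit S allele.
#' XL alleles (17--24 units) append extra copies of unit 3 distally, leaving
#' the unit 1--6 prefix (and hence the rs25531 anchor) invariant.
#'
#' The gene-specific amplification primer sites are embedded in the flanks so
#' that the four primer sets yield 699 / 1026 / 1536 / 2096 bp products on
#' the L allele. Unit sequences derive from a common consensus with at most
#' one substitution each, keeping pairwise identity at or above the homology
#' floor.
#'
#' @param seed RNG seed for flank/unit sequence generation.
#' @param homology_floor minimum pairwise identity between repeat units.
#' @return object of class `slc6a4_locus`.
#' @examples
#' loc <- default_locus()
#' nchar(build_allele_sequence(loc, parse_haplotype_name("LAC"))) -
#'   nchar(build_allele_sequence(loc, parse_haplotype_name("SAC")))  # 43
#' @export
default_locus <- function(seed = 7L, homology_floor = 0.75) {
  withr::with_seed(seed, {
    up_len <- 400L
    down_len <- 1650L

    # consensus unit of 24 bp (longest unit) with the rs25531 reference base A
    # at 0-based offset 10
    consensus <- rand_dna(24)
    consensus <- substr_set(consensus, 11L, "A")

    units <- character(16L)
    for (i in 1:16) {
      u <- substr(consensus, 1L, .UNIT_LENGTHS[i])
      # one unit-specific substitution, never at the rs25531 anchor offset
      p <- (i * 3L) %% 17L + 2L
      if (p == 11L) p <- 12L
      base <- substr(u, p, p)
      alt <- setdiff(c("A", "C", "G", "T"), base)[(i %% 3L) + 1L]
      units[i] <- substr_set(u, p, alt)
    }

    upstream <- rand_dna(up_len)
    # forward gene-specific primer starts 150 bp before the VNTR
    upstream <- substr_set(upstream, up_len - 150L + 1L, .FWD_GENE)

    downstream <- rand_dna(down_len)
    # reverse primer sites end at offsets giving the designed L-allele sizes
    vntr_L <- sum(.UNIT_LENGTHS)
    for (k in names(.REV_GENE)) {
      d_end <- .AMPLICON_SIZE[[k]] - 150L - vntr_L
      site <- cpp_revcomp(.REV_GENE[[k]])
      downstream <- substr_set(downstream, d_end - nchar(site) + 1L, site)
    }
    # rs25532 reference base C at 0-based offset 107, inside the mu element
    downstream <- substr_set(downstream, 108L, "C")
  })

  structures <- lapply(setNames(11:24, 11:24), function(n) {
    if (n <= 16L) seq_len(n) else c(1:16, rep(3L, n - 16L))
  })

  loc <- structure(list(
    upstream_flank = upstream,
    downstream_flank = downstream,
    unit_library = units,
    unit_consensus = substr(consensus, 1L, 22L),
    allele_structures = structures,
    rs25531_unit_index = 6L,
    rs25531_offset_in_unit = 10L,   # 0-based
    rs25531_ref = "A",
    rs25532_offset = 107L,          # 0-based in downstream flank
    rs25532_ref = "C",
    rs25532_distance = 150L,        # reported rs25531->rs25532 spacing (metadata)
    mu_element = c(95L, 135L),      # 0-based half-open interval, downstream flank
    homology_floor = homology_floor,
    genome_anchor = "17:28563658-28564683",
    seed = seed), class = "slc6a4_locus")
  validate_locus(loc)
  loc
}

#' Check locus invariants
#'
#' Verifies that every repeat unit is 20--24 bp, that all unit pairs meet the
#' homology floor (identity = 1 - edit distance / longer length), that the
#' rs25531 anchor falls inside the designated unit for every allele with at
#' least that many units, that rs25532 lies in the downstream flank (outside
#' the VNTR), and that the L allele is exactly 43 bp longer than S.
#'
#' @param locus an `slc6a4_locus`.
#' @return the locus, invisibly; errors if an invariant fails.
#' @export
validate_locus <- function(locus) {
  stopifnot(inherits(locus, "slc6a4_locus"))
  lens <- nchar(locus$unit_library)
  if (any(lens < 20L | lens > 24L))
    stop("repeat units must be 20-24 bp")
  d <- adist(locus$unit_library)
  mx <- outer(lens, lens, pmax)
  id <- 1 - d / mx
  if (any(id[upper.tri(id)] < locus$homology_floor))
    stop("repeat-unit pairwise identity below the homology floor")
  if (locus$rs25531_offset_in_unit < 0L ||
      locus$rs25531_offset_in_unit >=
        nchar(locus$unit_library[locus$rs25531_unit_index]))
    stop("rs25531 offset falls outside its repeat unit")
  for (st in locus$allele_structures) {
    if (length(st) >= locus$rs25531_unit_index &&
        st[locus$rs25531_unit_index] != locus$rs25531_unit_index)
      stop("allele structure does not keep the rs25531 unit in place")
  }
  if (locus$rs25532_offset < 0L ||
      locus$rs25532_offset >= nchar(locus$downstream_flank))
    stop("rs25532 must lie in the downstream flank")
  dl <- vntr_length(locus, 16L) - vntr_length(locus, 14L)
  if (dl != 43L)
    stop("L allele must be exactly 43 bp longer than S (got ", dl, ")")
  invisible(locus)
}

#' VNTR length of an allele
#' @param locus an `slc6a4_locus`.
#' @param repeat_count allele repeat count (must have a structure entry).
#' @return total VNTR length in bp.
#' @export
vntr_length <- function(locus, repeat_count) {
  st <- locus$allele_structures[[as.character(repeat_count)]]
  if (is.null(st))
    stop("no allele structure for repeat count ", repeat_count)
  sum(nchar(locus$unit_library[st]))
}

# VNTR length summed over the first k units of an allele structure
vntr_prefix_length <- function(locus, k) {
  sum(nchar(locus$unit_library[seq_len(k)]))
}

#' Render the full sequence of one promoter allele
#'
#' Concatenates the upstream flank, the allele's ordered repeat units (with
#' the haplotype's rs25531 base substituted at the anchored offset of the
#' sixth unit) and the downstream flank (with the rs25532 base substituted
#' and any extra flank variants applied). Deterministic for a fixed locus.
#'
#' @param locus an `slc6a4_locus`.
#' @param h a [promoter_haplotype()] whose repeat count has a structure entry.
#' @return single DNA string.
#' @export
build_allele_sequence <- function(locus, h) {
  stopifnot(inherits(locus, "slc6a4_locus"), inherits(h, "promoter_haplotype"))
  st <- locus$allele_structures[[as.character(h$repeat_count)]]
  if (is.null(st))
    stop("unknown allele: no structure for repeat count ", h$repeat_count)
  units <- locus$unit_library[st]
  ui <- locus$rs25531_unit_index
  if (length(units) >= ui)
    units[ui] <- substr_set(units[ui], locus$rs25531_offset_in_unit + 1L,
                            h$rs25531)
  down <- substr_set(locus$downstream_flank, locus$rs25532_offset + 1L,
                     h$rs25532)
  up <- locus$upstream_flank
  if (!is.null(h$extra_variants) && nrow(h$extra_variants)) {
    for (i in seq_len(nrow(h$extra_variants))) {
      p <- h$extra_variants$pos[i]
      alt <- h$extra_variants$alt[i]
      if (p > 0) down <- substr_set(down, p, alt)
      else up <- substr_set(up, nchar(up) + p + 1L, alt)
    }
  }
  paste0(up, paste(units, collapse = ""), down)
}

#' @export
print.slc6a4_locus <- function(x, ...) {
  cat("<slc6a4_locus>\n")
  cat(sprintf("  flanks: %d bp upstream / %d bp downstream\n",
              nchar(x$upstream_flank), nchar(x$downstream_flank)))
  cat(sprintf("  unit library: %d units (%d-%d bp), alleles %s-%s repeats\n",
              length(x$unit_library), min(nchar(x$unit_library)),
              max(nchar(x$unit_library)),
              min(as.integer(names(x$allele_structures))),
              max(as.integer(names(x$allele_structures)))))
  cat(sprintf("  rs25531: unit %d offset %d; rs25532: downstream offset %d\n",
              x$rs25531_unit_index, x$rs25531_offset_in_unit, x$rs25532_offset))
  cat("  genome anchor:", x$genome_anchor, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# serialization

#' Write / read a locus definition as JSON
#'
#' @param locus an `slc6a4_locus`.
#' @param path file path.
#' @return `write_locus_json` returns `path` invisibly; `read_locus_json`
#'   returns the reconstructed `slc6a4_locus`.
#' @export
write_locus_json <- function(locus, path) {
  stopifnot(inherits(locus, "slc6a4_locus"))
  x <- unclass(locus)
  x$allele_structures <- lapply(x$allele_structures, as.integer)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_locus_json
#' @export
read_locus_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$allele_structures <- lapply(x$allele_structures, as.integer)
  ints <- c("rs25531_unit_index", "rs25531_offset_in_unit", "rs25532_offset",
            "rs25532_distance", "mu_element", "seed")
  for (f in ints) if (!is.null(x[[f]])) x[[f]] <- as.integer(x[[f]])
  loc <- structure(x, class = "slc6a4_locus")
  validate_locus(loc)
  loc
}

#' Write allele sequences to FASTA
#'
#' One record per haplotype, with the haplotype name as record id.
#'
#' @param locus an `slc6a4_locus`.
#' @param path output FASTA path.
#' @param haplotypes character vector of haplotype names (default: the six
#'   canonical observed haplotypes).
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(locus, path,
                               haplotypes = c("LAC", "SAC", "LGC",
                                              "SAT", "XLAC", "SGC")) {
  seqs <- vapply(haplotypes, function(nm)
    build_allele_sequence(locus, parse_haplotype_name(nm)), character(1))
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- haplotypes
  Biostrings::writeXStringSet(dss, filepath = path)
  invisible(path)
}
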