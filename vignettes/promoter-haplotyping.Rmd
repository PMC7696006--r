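---
title: "Phased haplotyping of the SLC6A4 promoter from long amplicon reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phased haplotyping of the SLC6A4 promoter from long amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(httlpr)
```

## The locus and why short reads fail on it

The *SLC6A4* promoter contains a GC-rich variable number tandem repeat
(5-HTTLPR) of 11--24 units, each 20--24 bp and highly homologous to the
others. The two common alleles -- long (L; 16 repeats) and short (S; 14
repeats) -- differ by a 43 bp insertion/deletion (rs4795541); rarer
extra-long (XL; 17--24) and extra-short (XS; 11--13) alleles also occur,
and the class table has a deliberate gap at 15 repeats. Two promoter SNVs
modulate expression jointly with the repeat class: rs25531 (A>G), which
sits *inside* the sixth repeat unit, and rs25532 (C>T) in the downstream µ
regulatory element. Clinically the three variants are interpreted as a
phased haplotype -- `LAC`, `LGC`, `SAT`, and so on -- because, for
example, the G allele of rs25531 on an L background behaves like an S
allele.

Short reads can neither span the VNTR (so the L/S indel is invisible or
miscalled) nor phase variants across it. A single long amplicon read, in
contrast, covers the whole promoter: every read carries the complete
haplotype, so phasing reduces to clustering reads within a sample. That
observation is the design center of this package.

## The pipeline

1. **Locus model** (`default_locus()`): a parametric promoter with a unique
   upstream flank, a library of 16 homologous repeat units, allele
   structures for 11--24 repeats, and anchored variant sites. Units 15 and
   16 together span exactly 43 bp and the S allele is the L allele minus
   those two units, reproducing the indel arithmetic by construction.
2. **Simulation** (`simulate_pool()`, `simulate_cohort()`): in-silico PCR
   of each allele with the gene-specific primer footprints, per-base
   substitution/insertion/deletion errors, dual barcoding with universal
   tags, and pooling.
3. **Demultiplexing** (`demux_pool()`): fixed-position Hamming matching of
   both barcodes in both orientations; a read is assigned only when exactly
   one sample matches, and ties are reported as ambiguous.
4. **Feature extraction** (`featurize_reads()`): per read, semi-global
   alignment of 30 bp flank anchors brackets the VNTR; the repeat count is
   estimated from the segment length and refined by greedy tandem alignment
   of the unit consensus; the rs25531/rs25532 bases are read off windowed
   context alignments.
5. **Diplotyping** (`call_diplotype()`): reads are grouped by their exact
   (repeat count, rs25531, rs25532) tuple; singleton noise groups merge
   into the nearest major group; the top two groups form a heterozygous
   call when the minor one is sufficiently supported, otherwise the call is
   homozygous. Consensus haplotypes are named (`LGC/SAC`, ...) and can be
   emitted as a phased VCF against the L-allele reference.
6. **Cohort statistics** (`haplotype_frequency_table()`,
   `callset_concordance()`, `precision_harness()`): frequency and MAF
   tables, callset agreement, and the replicate precision experiment.

## Worked example

```{r example, eval = FALSE}
loc <- default_locus()
cohort <- simulate_cohort(
  loc, hap_freqs = reference_cohort_counts() / 240,
  n_samples = 24, coverage = 60, seed = 1)
res <- genotype_pool(cohort$reads, cohort$barcodes, loc)
head(res$table)
allele_frequencies(res$table)$mafs
```

## What the generator emulates, and what it does not

The generator reproduces the study conditions: diploid samples whose
alleles are drawn from the six observed haplotypes (`LAC` 101/240, `SAC`
89/240, `LGC` 26/240, `SAT` 21/240, `XLAC` 2/240, `SGC` 1/240), four
primer sets with a common forward primer giving 699/1026/1536/2096 bp
products on the L allele, 16 nt dual barcodes, and indel-dominant
long-read noise. Defaults that the source material does not specify were
fixed once at field-realistic values and are not tuned:

* **Error model**: 0.2% substitution, 0.3% insertion, 0.3% deletion per
  base -- circular-consensus-like, indel-dominant.
* **Coverage**: 100 reads per allele per sample.
* **Barcodes**: 16 nt, pairwise edit distance at least 5, found by seeded
  greedy search (the real barcode sheet is not published).
* **Unit sequences**: derived from a common consensus with at most one
  substitution each, keeping pairwise identity at or above the 0.75
  homology floor (real unit sequences are not published; any locus with
  the stated structure is acceptable, and nothing downstream depends on
  the specific bases).

Features of real data that are *not* modeled: polymerase slippage
(stutter) that changes the repeat count during PCR, chimeric molecules,
barcode-region sequencing errors (errors are injected into the insert
after which barcodes/tags are attached intact -- which is why
fixed-position Hamming demultiplexing with one mismatch suffices here),
base-quality variation (qualities are constant Q30 placeholders), and
instrument-specific artifacts. Passing tests therefore demonstrate the
correctness and internal consistency of the algorithms under realistic
noise, not performance on a specific instrument's raw data.

## Parameters that matter

All thresholds live in `haplotyping_config()`:

| parameter | default | role |
|---|---|---|
| `anchor_length` | 30 bp | flank anchor length bracketing the VNTR |
| `anchor_min_identity` | 0.80 | below this an anchor is "not found" |
| `site_min_identity` | 0.80 | below this a site base is missing |
| `unit_min_identity` | 0.70 | acceptance of one tandem unit alignment |
| `min_total_reads` | 20 | fewer usable reads gives a no-call |
| `min_reads_per_hap` | 10 | minimum support of the minor cluster |
| `min_minor_fraction` | 0.20 | minimum minor-cluster fraction |
| `max_mm_barcode` | 1 | demultiplexing mismatch tolerance |

The identity thresholds were chosen for the default error model (~0.8%
total per-base error: a 30 bp anchor expects < 1 error, so 80% identity
separates true anchors from random sequence by a wide margin; repeat units
differ from the consensus by at most ~15%, so 70% accepts true units while
rejecting flank sequence). The calling thresholds (20/10/0.2) are
conventional amplicon-consensus floors; all are configurable.

## Numerical and design choices

* **Repeat counting.** The primary estimate,
  `round(segment length / mean unit length)`, is already robust: with a
  0.6% indel rate a ~350 bp VNTR accumulates ~2 indels, far from the ~11
  bp needed to shift the rounded count. The refinement -- greedy
  prefix-anchored alignment of the unit consensus along the segment,
  counting accepted units -- is the returned value; both are logged per
  read. This is deliberately *not* a full read-to-reference alignment:
  unit homology makes global alignments ambiguous, while unit-by-unit
  consumption is local, fast, and testable against an independent aligner.
* **Alignment kernel.** Anchor location, site extraction and tandem
  counting run on one small semi-global dynamic-programming kernel
  (match +1, mismatch -1, gap -2, free subject overhangs) implemented in
  C++ for throughput. The identity threshold operates on
  matches/pattern-length, not on score. Tests cross-check the kernel
  score-for-score against `Biostrings::pairwiseAlignment`.
* **Sixth repeat unit.** Units are numbered 5'→3' in the promoter's
  transcriptional orientation; the rs25531 anchor is the 11th base of unit
  6. XL alleles append extra copies of unit 3 *after* unit 16, so the
  unit 1--6 prefix (and the anchor) is invariant across all alleles.
  Users applying the method to real data must verify the counting
  direction of "sixth unit" on their reference.
* **15-repeat alleles** are reported as `UNCLASSIFIED` with the raw count
  (`(15)AC`) and flagged in QC -- never silently binned into S or L.
* **Canonical diplotype order** is class rank L < S < XL < XS, then
  rs25531 A < G, then rs25532 C < T, then repeat count. This matches every
  printed exemplar of the nomenclature (e.g. `LGC/SAC`, `LAC/XLAC`,
  `SAC/XLAC`) and makes ordering total, idempotent and
  argument-order-free.
* **Tie-breaks in clustering** are fully specified (merge singletons to
  the group with fewest differing fields, then larger support, then tuple
  order; clusters ranked by support then tuple order), so identical inputs
  always produce identical calls.
* **Amplicon sizes** are gene-specific footprints excluding the universal
  tags: the untagged confirmation pair reports the same 1026 bp as the
  tagged second primer set, which is only consistent if printed sizes
  exclude tags.
* **Coordinates** are 0-based half-open internally; emitted VCF is
  1-based with phased `GT` and a shared `PS` phase set, and represents the
  repeat polymorphism as a symbolic `<VNTR:k>` allele with both called
  repeat counts in `INFO/REPEAT_COUNTS`.
* **rs25532 placement.** The site sits at downstream-flank offset 107,
  inside the µ element interval and within all four amplicons. The
  conventionally quoted "~150 bp from rs25531" spacing is kept as locus
  metadata only: it is not geometrically compatible with an anchor inside
  unit 6 of a 16-unit VNTR plus a downstream µ element, so it is not
  enforced as a coordinate.
* **Reported S-allele frequency.** From the haplotype table the S-class
  count is 89 + 21 + 1 = 111/240 = 0.4625. The separately quoted 112/240
  (0.467) is internally inconsistent with that table; the package computes
  the table-derived value and documents the discrepancy rather than
  targeting 0.467.

## Precision experiment

`precision_harness()` operationalizes the 3:1:1 validation design as five
replicate libraries per sample (three intra-run plus two inter-run), each
simulated with its own seed and pushed through the full pipeline.
Concordance is tallied against truth over samples × 3 sites × replicates
(genotypes) and samples × 2 × replicates (haplotypes) -- denominators
225 and 150 for the default 15-sample panel -- and additionally over all
replicate pairs. A replicate no-call counts as discordant.

The default panel of 15 diploid samples covers all six observed
haplotypes, including two distinct XL repeat counts (17 and 20).

## Problem sizes

The test suite and the acceptance script run the precision experiment at
its full design size (15 samples × 5 replicates × 2 × 100 reads = 15,000
reads), the cohort recovery analysis at 120 samples × 2 × 30 reads, and
the per-class recovery checks at 80--100 reads per allele class. These
sizes keep each analysis in the range of a couple of minutes on one core
while leaving the statistical checks (exact binomial 99% CIs, modal count
recovery) well powered.

## Known limitations

* Clustering keys on the (repeat count, rs25531, rs25532) tuple; two
  haplotypes that differ *only* in an extra flank variant are not split,
  and a 50%-supported flank variant is dropped from the consensus (the
  flank-variant detector is intended for variants on a distinguishable
  haplotype background, and is off by default).
* Fixed-position Hamming demultiplexing assumes error-free barcode
  regions, which matches the simulator but not raw instrument reads; an
  indel-tolerant matcher would be required upstream of this package for
  real data.
* rs25531 on alleles with fewer than six units is reported missing with a
  QC flag; no such allele occurs in the modeled range (11--24 units).
* Reproducing published short-read discordance rates requires external
  sequencing datasets and is out of scope; `callset_concordance()` accepts
  any two callset tables should users wish to make such comparisons
  themselves.
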