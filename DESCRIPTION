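Package: httlpr
Title: Phased Haplotyping of the Serotonin Transporter Promoter from
    Long Amplicon Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genotypes and phases the polymorphic SLC6A4 promoter from
    long amplicon sequencing reads. The promoter contains a variable
    number tandem repeat (5-HTTLPR, 11-24 highly homologous 20-24 bp
    units) whose long (L, 16 repeats) and short (S, 14 repeats) alleles
    differ by a 43 bp insertion/deletion (rs4795541), plus the rs25531
    (A>G) and rs25532 (C>T) single-nucleotide variants that are
    clinically interpreted as a haplotype with the repeat length class.
    The package provides a parametric locus model, a simulator for
    dual-barcoded pooled amplicon libraries with indel-dominant
    long-read errors, barcode demultiplexing, per-read repeat-unit
    counting and variant-site extraction, read clustering into phased
    consensus diplotypes with VCF output, and cohort summaries
    (haplotype frequencies, minor allele frequencies, replicate
    concordance and precision experiments).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
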