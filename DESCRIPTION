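Package: hlaB5801
Title: Sanger-Based HLA-B*58:01 Typing via Diagnostic Nucleotide Panels
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for typing the HLA-B*58:01 allele from Sanger consensus
    sequences using a two-stage diagnostic nucleotide panel (exon-3 screen,
    exon-2 confirmation) with IUPAC ambiguity codes representing diploid
    heterozygotes, and for typing the PSORS1C1 tag SNP rs9263726 from the
    same kind of input. Includes panel discovery and verification against
    allele reference alignments, cohort genotype and allele frequency
    reports with Wilson confidence intervals, two-locus haplotype frequency
    estimation by EM with linkage-disequilibrium measures (D, D', r2),
    exact Hardy-Weinberg tests, surrogate-marker performance metrics
    (sensitivity, specificity, PPV, NPV), clinical association summaries
    (correlation screens and genotype-group comparisons), and a fully
    seeded synthetic-data generator producing allele databases, diploid
    consensus FASTA files and paraclinical tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    MASS,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'allele-reference.R'
    'utils.R'
    'clinical-assoc.R'
    'cohort-stats.R'
    'genotype-calling.R'
    'hlaB5801-package.R'
    'synthetic-data.R'
    'pipeline.R'
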