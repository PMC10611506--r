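Package: novelHLA
Title: Characterization, Impact Scoring, and Submission of Novel HLA Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the clinical management of novel HLA alleles detected by
    sequence-based typing. Represents annotated HLA gene models (UTR, exon, and
    intron intervals with a signal-peptide leader), maps genomic positions to
    mature-protein codon numbers with negative leader numbering, detects and
    classifies single-nucleotide novelties against a reference allele
    (missense, silent, nonsense, frameshift), scores missense novelties with a
    four-criterion physicochemical/epitope impact score, generates
    submission-ready FASTA and five-column feature-table files, and summarizes
    detection cohorts. A synthetic gene-model generator with induced mutations
    of controlled class supports fully offline testing, alongside bundled
    reference tables from an 18-month clinical detection cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Genetics, SequenceMatching, Annotation, VariantAnnotation
RoxygenNote: 7.3.3
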