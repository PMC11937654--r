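Package: artemisdx
Title: Cas12a-Targetable SNV Discovery and CRISPR Diagnostics Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide discovery of single-nucleotide variants (SNVs) that
    fall in the Cas12a seed region adjacent to a TTTV protospacer adjacent
    motif (PAM), in the style of the ARTEMIS approach to CRISPR-based
    diagnostics (CRISPRdx). Scans a reference genome (FASTA) against a
    variant call set (VCF) on both strands, annotates targetable hits with
    PAM location, seed offset and allele-specific protospacer sequences,
    and excludes PAM sites disrupted by common population variants. A
    design layer turns hits into orderable molecules: allele-specific
    LbCas12a crRNAs carrying synthetic seed mismatches (homopair rule),
    synthetic double-stranded oligonucleotide test targets, and validated
    short-amplicon primer pairs. Companion utilities compute C1V1 = C2V2
    reaction-recipe volumes with water fill, and normalize plate-reader
    kinetic fluorescence tables into replicate-aggregated endpoint ratios.
    Includes a seeded synthetic-data generator with a brute-force scan
    oracle so the whole pipeline is testable without external downloads,
    plus an 'artemis' command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    vcfR,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
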