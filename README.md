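# artemisdx

Cas12a-targetable SNV discovery and CRISPR diagnostics (CRISPRdx) design
in R.

LbCas12a detects double-stranded DNA adjacent to a TTTV PAM and reports
recognition through collateral cleavage of a quenched fluorescent ssDNA
reporter — but it tolerates single mismatches, so single-nucleotide
variants (SNVs) are only reliably discriminated when (i) the SNV falls in
the **seed region**, the 5-nt stretch of the protospacer immediately 3' of
the PAM, and (ii) the crRNA carries an additional **synthetic mismatch**
elsewhere in the seed, so that the off-allele faces two seed mismatches
while the on-allele faces one.

`artemisdx` is for molecular diagnostics developers who want to go from "a
VCF of candidate variants" to "sequences I can order and a plate I can
analyze":

* **Scan** — find every SNV with a TTTV PAM whose seed window (offsets
  1..5, both strands) covers it: `artemis_scan(genome, variants, scan_config())`.
  Hits are emitted as VCF with INFO keys `ARTEMIS_PAM`, `ARTEMIS_SEED`,
  `ARTEMIS_STRAND`, `ARTEMIS_GRNA_REF`, `ARTEMIS_GRNA_ALT`. PAM motif
  (`pamregex`), seed size and spacer length (default 21 nt) are
  configurable; PAM sites disrupted by common population variants
  (AF ≥ 0.01 by default) can be excluded, and hits filtered by annotation
  keywords (e.g. `cancer`, `melanoma`).
* **Design** — allele-specific crRNAs (`UAAUUUCUACUAAGUGUAGAU` LbCas12a
  scaffold + spacer) with homopair synthetic mismatches (G·G, A·A, U·T,
  C·C), 55-nt synthetic duplex test targets
  (`[≥15 nt]-[PAM]-[protospacer]-[≥15 nt]`), and primer-pair validation
  (60–120 bp amplicons that contain but never overlap the target).
* **Bench math** — C1V1 = C2V2 recipe volumes with exact water fill
  (`crisprdx_mastermix()`, `pcr_recipe()`, `rpa_recipe()`,
  `annealing_recipe()`, or any custom `build_recipe()`).
* **Kinetics** — parse wells-as-columns plate-reader exports, remove
  baselines, and compute replicate-aggregated endpoint fluorescence ratios
  with propagated SD.
* **Fixtures** — a seeded toy-genome generator with planted ground truth
  and an independent brute-force oracle, so everything is testable offline.

## Worked example

```r
library(artemisdx)

genome <- structure(c(chr_toy = "GGTTTACGATCGATCGATCGATCGATCGATCG"),
                    class = "genome_map")   # or read_fasta("ref.fa")
snv <- data.frame(contig = "chr_toy", pos = 9L, id = "BRAF_like",
                  ref = "A", alt = "G", qual = ".", filter = ".",
                  info = "CLNDN=Melanoma", af = NA_real_, is_snv = TRUE)

hit <- artemis_scan(genome, snv)
hit[, c("id","pos","pam_start","pam_end","strand","seed_pos",
        "spacer_ref","spacer_alt")]
#>          id pos pam_start pam_end strand seed_pos            spacer_ref
#> 1 BRAF_like   9         2       6      +        3 CGATCGATCGATCGATCGATC
#>              spacer_alt
#> 1 CGGTCGATCGATCGATCGATC
```

The SNV at position 9 sits 3 nt 3' of the TTTA PAM at 0-based [2,6) —
seed position 3 — and the alternate-allele protospacer differs from the
reference one exactly there. Four mutant-specific crRNAs are then possible,
one homopair mismatch per remaining seed position (never at the SNV):

```r
enumerate_synthetic_mismatches(hit[1, ], allele = "alt", mode = "homopair")
#>                 name sm_pos sm_base wobble            spacer_rna
#> 1 BRAF_like_alt_sm1G      1       G  FALSE GGGUCGAUCGAUCGAUCGAUC
#> 2 BRAF_like_alt_sm2C      2       C  FALSE CCGUCGAUCGAUCGAUCGAUC
#> 3 BRAF_like_alt_sm4A      4       A  FALSE CGGACGAUCGAUCGAUCGAUC
#> 4 BRAF_like_alt_sm5G      5       G  FALSE CGGUGGAUCGAUCGAUCGAUC
```

and the bench work starts from the shipped 20-µL mastermix:

```r
crisprdx_mastermix()
#> Reaction recipe (20 uL per reaction)
#>          Reagent Stock  Final uL/rxn
#>  CutSmart Buffer  10 x    1 x   2.00
#>     FAM reporter 10 uM 100 nM   0.20
#>            crRNA 10 uM  50 nM   0.10
#>   EnGen LbCas12a 10 uM  40 nM   0.08
#>       target DNA     -      -   2.00
#>            Water     -      -  15.62
```

## Command line

```sh
artemis=$(Rscript -e 'cat(system.file("exec","artemis",package="artemisdx"))')
Rscript $artemis fixtures --out fx --seed 3          # toy genome + VCF + truth
Rscript $artemis fx/toy_genome.fa fx/toy_variants.vcf > cas12targetable.vcf
Rscript $artemis design fx/toy_genome.fa fx/toy_variants.vcf --keywords cancer,melanoma
Rscript $artemis mix --recipe rpa
Rscript $artemis kinetics plate.csv --layout layout.csv --num mut --den wt
```

Subcommands: `scan` (implicit with two positional files), `design`,
`oligos`, `primers`, `mix`, `kinetics`, `fixtures`; results go to standard
output or `-o FILE`, logs to standard error.

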