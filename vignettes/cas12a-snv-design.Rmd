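---
title: "Designing allele-specific Cas12a CRISPR diagnostics with artemisdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing allele-specific Cas12a CRISPR diagnostics with artemisdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artemisdx)
```

## The problem

LbCas12a recognizes double-stranded DNA next to a T-rich PAM (TTTV; V = A,
C or G) and, once activated, unleashes collateral single-stranded DNase
activity that is read out with a quenched fluorescent reporter. This makes
it a detector for nucleic acids — but a mismatch-tolerant one: a single
nucleotide difference between a crRNA and its target does not by itself
switch the enzyme off. Two facts rescue single-nucleotide fidelity:

1. **The seed region.** Mismatches in the PAM-proximal stretch of the
   spacer:protospacer duplex (here modelled as the 5 nt immediately 3' of
   the PAM) impair activation far more than distal mismatches. An SNV is
   therefore *targetable* when it falls inside this seed window.
2. **A synthetic mismatch.** Deliberately adding a second mismatch
   elsewhere in the seed leaves the matched allele with one weak mismatch
   but the other allele with two, amplifying discrimination.

`artemisdx` operationalizes this: it scans a reference genome plus a VCF
for SNVs sitting 1–5 nt 3' of a TTTV PAM on either strand, annotates them,
and designs the molecules needed to build and analyze a fluorescence
CRISPRdx assay around any hit.

## Scan geometry and coordinates

VCF positions are 1-based; internally every interval is 0-based half-open,
converted exactly once at the I/O boundary. For a forward PAM occupying
`[s, e)`, seed position `p` (1 = PAM-proximal) sits at 0-based coordinate
`e + p - 1`; for a reverse-strand PAM the protospacer runs leftwards and
seed position `p` sits at `s - p`. Both strands are scanned by default
(reverse TTTV appears as BAAA in the forward text). Each (SNV, PAM) pair
with a valid seed offset yields one hit — an SNV flanked by several PAMs is
reported once per PAM — and output order is deterministic: contig,
position, `+` before `-`, PAM start.

```{r}
genome <- structure(c(chr_toy = "GGTTTACGATCGATCGATCGATCGATCGATCG"),
                    class = "genome_map")
snv <- data.frame(contig = "chr_toy", pos = 9L, id = "v1", ref = "A",
                  alt = "G", qual = ".", filter = ".", info = ".",
                  af = NA_real_, is_snv = TRUE)
hit <- artemis_scan(genome, snv)
hit[, c("pos", "pam_start", "pam_end", "strand", "seed_pos",
        "spacer_ref", "spacer_alt")]
```

Hits are written as VCF with five INFO keys (`ARTEMIS_PAM`, `ARTEMIS_SEED`,
`ARTEMIS_STRAND`, `ARTEMIS_GRNA_REF`, `ARTEMIS_GRNA_ALT`). These key names
are this package's own: the upstream tool's field names are not published,
so we declare ours explicitly in the emitted header. `ARTEMIS_PAM` is the
signed offset of the 0-based PAM start relative to the 0-based SNV position
on the reference strand.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `pam_pattern` | `TTTV` | IUPAC motif (or raw regex) for the PAM, PAM-strand orientation |
| `seed_size` | 5 nt | seed window 3' of the PAM; offsets 1..`seed_size` are targetable |
| `spacer_length` | 21 nt | protospacer/spacer length |
| `af_threshold` | 0.01 | population allele frequency at which a PAM-overlapping variant excludes a hit |
| `both_strands` | `TRUE` | scan reverse-strand PAMs |
| oligo `flank` | 15 nt (minimum 15) | genomic flank on each side of PAM + protospacer |
| amplicon `bounds` | 60–120 bp | usable amplicon length for fragmented (cell-free) DNA |

The seed window is deliberately strict: enlarging `seed_size` only ever
adds hits (monotonicity, property-tested), so a user wanting a permissive
scan can raise it without losing anything. The common-variant exclusion
applies to PAM bases only by default — a population variant that destroys
the PAM destroys the assay, whereas a seed variant merely perturbs it —
with `include_seed = TRUE` available for the stricter reading. A variant
with *unknown* allele frequency never excludes a hit: absence of evidence
of commonness is not evidence of commonness.

## crRNA design: the homopair rule

The crRNA is `scaffold + spacer` (5'→3'), scaffold
`r LBCAS12A_SCAFFOLD` for LbCas12a. The spacer equals the protospacer
(PAM-strand) sequence with T→U, because the spacer hybridizes the *target*
strand. A synthetic mismatch at seed position `p` replaces the crRNA base
with the RNA form of the target-strand base at `p` — i.e. the complement of
the protospacer base — producing an identical-base pair (G·G, A·A, U·T,
C·C) in the heteroduplex. The SNV's own seed position is never used: the
mismatch there is the one that recognizes the allele. With the default
5-nt seed this yields 4 candidate designs per hit; the package enumerates,
it does not rank — which position works best is an empirical question
answered by testing, and no published rule decides it a priori.

```{r}
enumerate_synthetic_mismatches(hit[1, ], allele = "alt",
                               mode = "homopair")[, 1:6]
```

`mode = "all"` emits all three mismatching bases per position for
screening; pairs that would form semi-stable wobble geometry with the
target strand (crRNA G over T, crRNA U over G) are flagged via `wobble`
rather than forbidden, since the avoidance guidance is advisory.

## Test oligos and primers

Synthetic duplex targets are laid out on the PAM-containing strand as
`[flank]-[PAM]-[protospacer]-[flank]` (55 nt per strand at defaults), the
mutant duplex differing from wild type at exactly the SNV base; both
strands are emitted for ordering as complementary ssDNA. Synthetic
mismatches are *never* designed into the DNA targets, only into crRNAs.

Primer validation encodes two assay-specific constraints: primer footprints
must not intersect the PAM + protospacer span (free primer ends can
otherwise activate Cas12a), and the amplicon — defined inclusive of both
primers — should fall in 60–120 bp so that it plausibly fits on a single
nucleosomal cfDNA fragment (~160 nt). Melting temperature, GC content and
dimer thermodynamics are out of scope; dedicated primer tools do that
better.

## Recipes

All reaction mixes are plain C1V1 = C2V2 arithmetic with a water fill.
Component volumes are rounded to 2 decimals half-up — the convention that
reproduces every printed per-reaction volume of the shipped presets — and
the water line absorbs the rounding residue so volumes sum *exactly* to the
total. (In the RPA preset the components sum to 13.99 µL, so the computed
water fill is 1.01 µL.) `replicates` and `surplus` scale a mastermix
linearly (e.g. 3 replicates + 10% surplus).

```{r}
crisprdx_mastermix()
```

## Kinetics

Plate readers export kinetics wells-as-columns × timepoints-as-rows (here,
5-min intervals over ≥3 h). `parse_kinetic_table()` tidies that into
(well, group, time, value) rows using an explicit well→group layout map —
replicate-adjacency conventions differ between instrument softwares, so
adjacency is never inferred. Baseline removal either anchors every trace at
its own t0 or subtracts a negative-control mean trace timepoint-wise.
`endpoint_ratio()` reports mean(numerator)/mean(denominator) at the last
common timepoint (or an explicit time), with the standard deviation
propagated by the first-order quotient formula
`|r|·sqrt((s_n/m_n)² + (s_d/m_d)²)`; the ratio is scale-invariant by
construction. Endpoint (not area-under-curve) aggregation is used; plateau
detection is left to the experimenter.

## The synthetic-data generator, and what passing tests mean

`generate_toy_genome()` builds a random contig scrubbed of all PAM motifs,
plants a requested number of TTTV sites on random strands, then places SNVs
at known seed offsets (hits) and decoys (offsets beyond the window, inside
the PAM, far from any PAM, and indels). Expected hits are derived by
`brute_force_scan()` — an independent oracle that tests motifs base by
base against IUPAC sets, enumerates seed coordinates explicitly and slices
spacers with its own complement table, sharing no matching machinery with
the scanner — and a layout is accepted only when oracle output equals the
planted truth. Generation is byte-deterministic per seed.

The generator emulates the *geometry* of the problem, not the statistics of
a human genome: uniform base composition, motif-free background, isolated
well-separated sites. Passing tests therefore demonstrate coordinate and
strand correctness of the scan and designs, not performance on ClinVar-
scale inputs, where PAM density, overlapping records and annotation
richness differ. Genome-scale hit catalogs also depend on the database
snapshot used, so no test asserts any genome-wide count.

Problem sizes used by the verification suite and acceptance script — 100
seeded random genomes of 2 kb with 50 SNVs each for oracle equivalence,
plus smaller planted fixtures — were chosen as the smallest sizes that
exercise both strands, all seed offsets and every decoy class many times
over.

## Numerical and degenerate-input choices

* IUPAC ambiguity codes other than N in the reference collapse to N with a
  warning; N never matches any PAM base.
* Contig names must match exactly between FASTA and VCF; mismatch is a hard
  error listing both name sets ("chr" reconciliation only behind
  `fix_chr_prefix`).
* A variant whose REF disagrees with the reference sequence is dropped with
  a warning and counted, as is a hit whose spacer window would leave the
  contig.
* Multi-allelic VCF records split into one record per ALT; allele
  frequencies are matched per allele.
* Rounding is half-up at 2 decimals (with a small epsilon guard against
  binary representation), chosen to reproduce the shipped recipes' printed
  volumes; totals stay exact because water absorbs the residue.
* Sample standard deviations with n = 1 contribute 0 to ratio error
  propagation; a zero denominator mean is an error, not an `Inf`.

## Known limitations

* Only reference-strand PAMs are considered: SNVs that create or destroy a
  PAM are out of scope.
* No off-target search, cleavage-efficiency prediction, or mismatch-
  position ranking.
* No primer thermodynamics (Tm/GC/dimers) and no FASTQ/BAM handling.
* The kinetics layer deliberately stops at replicate-aggregated ratios;
  significance testing (e.g. two-way ANOVA) is left to general-purpose
  statistics tools.
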