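#' LbCas12a direct-repeat scaffold (5' of the spacer)
#'
#' The constant crRNA scaffold compatible with LbCas12a; the full crRNA is
#' `scaffold + spacer`, 5' to 3'.
#' @export
LBCAS12A_SCAFFOLD <- "UAAUUUCUACUAAGUGUAGAU"

dna_to_rna <- function(x) chartr("T", "U", toupper(x))
# RNA base read by the crRNA at a protospacer position when pairing
# Watson-Crick with the target strand: identical to the protospacer base.
# The *target-strand* base is the DNA complement of the protospacer base;
# its RNA form is what a homopair mismatch writes into the crRNA.
target_strand_rna <- function(protospacer_base) {
  chartr("ACGT", "UGCA", toupper(protospacer_base))
}

new_crrna_df <- function(name, allele, sm_pos, sm_base, wobble, spacer_rna,
                         scaffold = LBCAS12A_SCAFFOLD) {
  data.frame(name = name, allele = allele, sm_pos = sm_pos, sm_base = sm_base,
             wobble = wobble, spacer_rna = spacer_rna, scaffold = scaffold,
             full_rna = paste0(scaffold, spacer_rna),
             stringsAsFactors = FALSE)
}

#' Convert a protospacer DNA sequence into a crRNA design
#'
#' The crRNA spacer carries the protospacer (PAM-strand) sequence with T
#' replaced by U, since the spacer hybridizes the target strand. The LbCas12a
#' scaffold is prepended; no synthetic mismatch is introduced.
#'
#' @param spacer_dna Protospacer DNA, 5' to 3' starting at the first base 3'
#'   of the PAM.
#' @param allele `"ref"` or `"alt"`: which allele the spacer carries.
#' @param spacer_length Expected length (default 21); a different input
#'   length is an error.
#' @param name Design name (default derived from allele).
#' @param scaffold Scaffold RNA (default [LBCAS12A_SCAFFOLD]).
#' @return One-row `data.frame` of class `crrna_designs` with columns
#'   `name`, `allele`, `sm_pos`, `sm_base`, `wobble`, `spacer_rna`,
#'   `scaffold`, `full_rna`.
#' @examples
#' spacer_to_crrna("CGATCGATCGATCGATCGATC", "ref")
#' @export
spacer_to_crrna <- function(spacer_dna, allele = c("alt", "ref"),
                            spacer_length = 21L, name = NULL,
                            scaffold = LBCAS12A_SCAFFOLD) {
  allele <- match.arg(allele)
  spacer_dna <- toupper(spacer_dna)
  if (grepl("[^ACGT]", spacer_dna)) {
    stop("spacer contains non-DNA characters: ", spacer_dna)
  }
  if (nchar(spacer_dna) != spacer_length) {
    stop("spacer length is ", nchar(spacer_dna), ", expected ", spacer_length)
  }
  if (is.null(name)) name <- paste0("crRNA_", allele)
  out <- new_crrna_df(name, allele, NA_integer_, NA_character_, FALSE,
                      dna_to_rna(spacer_dna), scaffold)
  class(out) <- c("crrna_designs", class(out))
  out
}

#' Enumerate synthetic-mismatch crRNA designs for one hit
#'
#' Places one synthetic mismatch per eligible seed position. The SNV seed
#' position itself is never used (the mismatch there is what recognizes the
#' allele), so `homopair` mode yields `seed_size - 1` designs. The homopair
#' rule writes, at the mismatch position, the RNA form of the target-strand
#' base (the complement of the protospacer base), producing identical-base
#' pairs in the crRNA:target heteroduplex (G.G, A.A, U.T, C.C). In `all`
#' mode every mismatching base is emitted and crRNA:target wobble pairs
#' (G.T, U.G) are flagged, not forbidden.
#'
#' @param hit One row of an `artemis_hits` data.frame.
#' @param allele `"alt"` (mutant-specific crRNA, default) or `"ref"`
#'   (wild-type control).
#' @param mode `"homopair"` (default) or `"all"`.
#' @param config A [scan_config()] supplying `seed_size` and
#'   `spacer_length`.
#' @param scaffold Scaffold RNA (default [LBCAS12A_SCAFFOLD]).
#' @return `data.frame` of class `crrna_designs`, one row per design.
#' @export
enumerate_synthetic_mismatches <- function(hit, allele = c("alt", "ref"),
                                           mode = c("homopair", "all"),
                                           config = scan_config(),
                                           scaffold = LBCAS12A_SCAFFOLD) {
  allele <- match.arg(allele)
  mode <- match.arg(mode)
  if (config$seed_size < 2L) {
    stop("seed_size < 2 leaves no legal synthetic-mismatch position")
  }
  spacer_dna <- if (allele == "alt") hit$spacer_alt else hit$spacer_ref
  spacer_dna <- toupper(spacer_dna)
  base_rna <- dna_to_rna(spacer_dna)
  snv_pos <- as.integer(hit$seed_pos)
  label <- if (!is.null(hit$id) && !hit$id %in% c(".", "")) hit$id
           else paste0(hit$contig, ":", hit$pos)
  rows <- list()
  for (p in seq_len(config$seed_size)) {
    if (p == snv_pos) next
    proto <- substr(spacer_dna, p, p)
    current <- substr(base_rna, p, p)
    if (mode == "homopair") {
      bases <- target_strand_rna(proto)
    } else {
      bases <- setdiff(c("A", "C", "G", "U"), current)
    }
    for (b in bases) {
      # crRNA base b pairs the target-strand base (DNA complement of proto);
      # wobble iff crRNA G over target T, or crRNA U over target G.
      target_dna <- DNA_COMP[[proto]]
      wobble <- (b == "G" && target_dna == "T") ||
                (b == "U" && target_dna == "G")
      rows[[length(rows) + 1L]] <- new_crrna_df(
        name = paste0(label, "_", allele, "_sm", p, b),
        allele = allele, sm_pos = p, sm_base = b, wobble = wobble,
        spacer_rna = subst_at(base_rna, p, b), scaffold = scaffold)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("crrna_designs", class(out))
  out
}

#' Design the synthetic double-stranded test-target pair for a hit
#'
#' Builds the wild-type and mutant duplex oligonucleotides used to evaluate
#' crRNA specificity in vitro. The top strand is laid out on the
#' PAM-containing strand as `[flank5]-[PAM]-[protospacer]-[flank3]`, taken
#' from the reference genome (the alternate allele substituted at the SNV
#' for the mutant oligo); the bottom strand is its reverse complement. With
#' the defaults (15-nt flanks, 4-nt PAM, 21-nt spacer) each strand is 55 nt.
#'
#' @param genome A `genome_map`.
#' @param hit One row of an `artemis_hits` data.frame.
#' @param flank Flank length on each side (default 15).
#' @param min_flank Enforced minimum flank (default 15); set lower only for
#'   toy inputs.
#' @return `data.frame` of class `oligo_targets`, two rows (ref and alt),
#'   columns `name`, `allele`, `top_strand`, `bottom_strand`, `flank5`,
#'   `flank3`.
#' @export
design_oligo_targets <- function(genome, hit, flank = 15L, min_flank = 15L) {
  flank <- as.integer(flank)
  if (flank < min_flank) {
    stop("flank of ", flank, " nt is below the ", min_flank,
         "-nt minimum required on each side of the PAM/target")
  }
  s <- genome[[as.character(hit$contig)]]
  if (is.null(s)) stop("contig not in genome: ", hit$contig)
  n <- nchar(s)
  sp_len <- nchar(hit$spacer_ref)
  pos0 <- hit$pos - 1L
  if (hit$strand == "+") {
    lo <- hit$pam_start - flank               # 0-based inclusive
    hi <- hit$pam_end + sp_len + flank        # 0-based exclusive
  } else {
    lo <- hit$pam_start - sp_len - flank
    hi <- hit$pam_end + flank
  }
  if (lo < 0L || hi > n) {
    deficit <- max(0L - lo, hi - n)
    stop("flank of ", flank, " nt leaves the contig by ", deficit,
         " base(s); shrink the flank or extend the reference")
  }
  window <- substring(s, lo + 1L, hi)
  if (hit$strand == "+") {
    top_ref <- window
    i_snv <- pos0 - lo + 1L
    alt_base <- hit$alt
  } else {
    top_ref <- revcomp(window)
    i_snv <- hi - pos0                        # 1-based index in the rc window
    alt_base <- DNA_COMP[[hit$alt]]
  }
  top_alt <- subst_at(top_ref, i_snv, alt_base)
  label <- if (!is.null(hit$id) && !hit$id %in% c(".", "")) hit$id
           else paste0(hit$contig, ":", hit$pos)
  out <- data.frame(
    name = paste0(label, c("_ref", "_alt")),
    allele = c("ref", "alt"),
    top_strand = c(top_ref, top_alt),
    bottom_strand = c(revcomp(top_ref), revcomp(top_alt)),
    flank5 = flank, flank3 = flank,
    stringsAsFactors = FALSE)
  class(out) <- c("oligo_targets", class(out))
  out
}

locate_unique <- function(template, probe, what) {
  m <- gregexpr(probe, template, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) stop(what, " not found on the template: ", probe)
  if (length(m) > 1L) stop(what, " maps ", length(m),
                           " times on the template (ambiguous): ", probe)
  as.integer(m[1L]) - 1L                      # 0-based start
}

#' Validate a primer pair against a template and protected target span
#'
#' Locates the forward primer on the forward strand and the reverse primer as
#' its reverse complement, computes the amplicon (inclusive of both primers)
#' and checks the diagnostic constraints: neither primer footprint may
#' intersect the target span (PAM + protospacer; primers overlapping it can
#' falsely activate Cas12a), the amplicon must contain the target span, the
#' primers must be convergent, and the amplicon length must lie within
#' `bounds` (default 60-120 bp, suited to fragmented cell-free DNA).
#'
#' @param template Template DNA string.
#' @param target_span Integer pair, 0-based half-open span of PAM +
#'   protospacer on the template.
#' @param fwd,rev Primer sequences, each 5' to 3' on its own strand.
#' @param bounds Amplicon length bounds in bp (default `c(60, 120)`).
#' @return A list of class `amplicon_check`: primer footprints, amplicon
#'   interval/length, the individual checks, `pass`, and `reasons` for any
#'   failure. Each primer must map exactly once; zero or multiple matches
#'   are errors.
#' @export
validate_primer_pair <- function(template, target_span, fwd, rev,
                                 bounds = c(60L, 120L)) {
  template <- toupper(template)
  fwd <- toupper(fwd); rev <- toupper(rev)
  t0 <- as.integer(target_span[1L]); t1 <- as.integer(target_span[2L])
  if (t0 < 0L || t1 > nchar(template) || t0 >= t1) {
    stop("target_span must be a nonempty 0-based half-open interval on the template")
  }
  f0 <- locate_unique(template, fwd, "forward primer")
  r0 <- locate_unique(template, revcomp(rev), "reverse primer (as revcomp)")
  f_end <- f0 + nchar(fwd)
  r_end <- r0 + nchar(rev)
  convergent <- f_end <= r0
  amp_start <- f0; amp_end <- r_end
  amp_len <- amp_end - amp_start
  overlaps <- function(a0, a1) a0 < t1 && t0 < a1
  overlaps_target <- overlaps(f0, f_end) || overlaps(r0, r_end)
  within_bounds <- amp_len >= bounds[1L] && amp_len <= bounds[2L]
  contains_target <- amp_start <= t0 && t1 <= amp_end
  reasons <- character()
  if (!convergent) reasons <- c(reasons, "primers are not convergent")
  if (overlaps_target) reasons <- c(reasons, "primer overlaps the target sequence")
  if (!within_bounds) reasons <- c(reasons, sprintf(
    "amplicon length %d bp outside [%d, %d]", amp_len, bounds[1L], bounds[2L]))
  if (!contains_target) reasons <- c(reasons, "amplicon does not contain the target span")
  structure(list(
    fwd_primer = fwd, rev_primer = rev,
    fwd_start = f0, fwd_end = f_end, rev_start = r0, rev_end = r_end,
    amplicon_start = amp_start, amplicon_end = amp_end,
    amplicon_length = amp_len,
    overlaps_target = overlaps_target, within_bounds = within_bounds,
    contains_target = contains_target, convergent = convergent,
    pass = convergent && !overlaps_target && within_bounds && contains_target,
    reasons = reasons), class = "amplicon_check")
}

#' @export
print.amplicon_check <- function(x, ...) {
  cat("Amplicon check: ", if (x$pass) "PASS" else "FAIL", "\n",
      "  amplicon: [", x$amplicon_start, ", ", x$amplicon_end, ")  ",
      x$amplicon_length, " bp\n", sep = "")
  if (length(x$reasons)) cat(paste0("  - ", x$reasons, collapse = "\n"), "\n")
  invisible(x)
}

#' Export crRNA designs as TSV
#' @param designs A `crrna_designs` data.frame.
#' @param path Output path or `""` for standard output.
#' @return Invisibly, `designs`.
#' @export
write_crrna_tsv <- function(designs, path = "") {
  utils::write.table(
    designs[, c("name", "allele", "sm_pos", "sm_base", "wobble",
                "spacer_rna", "full_rna")],
    file = path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(designs)
}

write_fasta_records <- function(names, seqs, path = "") {
  con <- if (identical(path, "")) stdout() else file(path, "w")
  if (!identical(path, "")) on.exit(close(con))
  writeLines(paste0(">", names, "\n", seqs), con)
  invisible(NULL)
}

#' Export crRNA designs as FASTA (full crRNA sequences)
#' @inheritParams write_crrna_tsv
#' @return Invisibly, `designs`.
#' @export
write_crrna_fasta <- function(designs, path = "") {
  write_fasta_records(designs$name, designs$full_rna, path)
  invisible(designs)
}

#' Export oligo target duplexes as FASTA (two records per duplex)
#' @param oligos An `oligo_targets` data.frame.
#' @param path Output path or `""` for standard output.
#' @return Invisibly, `oligos`.
#' @export
write_oligo_fasta <- function(oligos, path = "") {
  write_fasta_records(
    c(rbind(paste0(oligos$name, "_top"), paste0(oligos$name, "_bottom"))),
    c(rbind(oligos$top_strand, oligos$bottom_strand)), path)
  invisible(oligos)
}
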