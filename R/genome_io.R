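# Coordinate convention: VCF positions are 1-based; everything internal is
# 0-based half-open. The conversion happens exactly once, at the I/O boundary
# (read_vcf subtracts nothing -- `pos` stays 1-based in VariantRecord tables,
# and consumers derive pos0 = pos - 1L when they enter interval arithmetic).

IUPAC_AMBIGUITY <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Normalize a nucleotide string to the A,C,G,T,N alphabet
#'
#' Uppercases the input, maps IUPAC ambiguity codes other than N to N (with a
#' warning), and rejects anything else. U is rejected: reference sequences are
#' DNA.
#'
#' @param x Character vector of nucleotide strings.
#' @param what Label used in error messages (e.g. the contig id).
#' @return Character vector over A,C,G,T,N.
#' @keywords internal
normalize_sequence <- function(x, what = "sequence") {
  x <- toupper(x)
  if (any(grepl("U", x, fixed = TRUE))) {
    stop("'", what, "' contains U: RNA is not a valid reference alphabet (DNA expected)")
  }
  has_amb <- grepl(paste0("[", paste(IUPAC_AMBIGUITY, collapse = ""), "]"), x)
  if (any(has_amb)) {
    warning("IUPAC ambiguity codes other than N in '", what,
            "' were replaced by N (N never matches a PAM base)")
    x <- chartr(paste(IUPAC_AMBIGUITY, collapse = ""),
                strrep("N", length(IUPAC_AMBIGUITY)), x)
  }
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("'", what, "' contains non-nucleotide characters: ",
         paste(unique(unlist(strsplit(gsub("[ACGTN]", "", x[bad]), ""))), collapse = ", "))
  }
  x
}

#' Read a reference genome from a FASTA file
#'
#' Wraps [Biostrings::readDNAStringSet()] and returns a plain named character
#' vector of uppercase sequences, one element per contig. Contig ids are the
#' first whitespace-delimited token of each FASTA header. IUPAC ambiguity
#' codes other than N are collapsed to N with a warning; N never matches any
#' PAM base downstream.
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @return Named character vector of class `genome_map`; names are contig
#'   ids, values are sequences over A,C,G,T,N.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr_toy", "GGTTTACGATCGATCGATCGATCGATCGATCG"), fa)
#' gm <- read_fasta(fa)
#' nchar(gm[["chr_toy"]])
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate contig id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L)) {
    stop("zero-length sequence for contig(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  seqs <- vapply(seq_along(seqs), function(i) normalize_sequence(seqs[[i]], ids[[i]]),
                 character(1))
  names(seqs) <- ids
  class(seqs) <- c("genome_map", class(seqs))
  seqs
}

#' Read SNVs (and optionally other variants) from a VCF file
#'
#' Wraps [vcfR::read.vcfR()]. Multi-allelic records are split into one row per
#' ALT allele, preserving file order. Each row carries the raw INFO string;
#' the allele frequency is pulled from the INFO key named by `af_key`
#' (comma-separated per-allele values are matched to the split allele).
#' An absent AF is `NA` (unknown), never 0.
#'
#' @param path Path to a VCF file (plain or bgzipped/gzipped).
#' @param require_snv If `TRUE`, rows whose REF/ALT are not a single-base
#'   substitution are dropped; the number of dropped source records is
#'   available as `attr(x, "skipped_non_snv")`.
#' @param af_key INFO key holding the allele frequency (default `"AF"`).
#' @return A `data.frame` of class `variant_records` with columns
#'   `contig`, `pos` (1-based), `id`, `ref`, `alt`, `qual`, `filter`,
#'   `info`, `af`, `is_snv`. The source header (all `##` lines) is attached
#'   as `attr(x, "header")`.
#' @export
read_vcf <- function(path, require_snv = FALSE, af_key = "AF") {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- v@fix
  meta <- v@meta
  if (nrow(fix) == 0L) {
    out <- data.frame(contig = character(), pos = integer(), id = character(),
                      ref = character(), alt = character(), qual = character(),
                      filter = character(), info = character(), af = numeric(),
                      is_snv = logical(), stringsAsFactors = FALSE)
    attr(out, "header") <- meta
    attr(out, "skipped_non_snv") <- 0L
    class(out) <- c("variant_records", class(out))
    return(out)
  }
  fix[is.na(fix)] <- "."
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  alt_rank <- unlist(lapply(n_alt, seq_len), use.names = FALSE)

  info <- fix[idx, "INFO"]
  af_all <- info_field(fix[, "INFO"], af_key)
  af <- vapply(seq_along(idx), function(k) {
    vals <- af_all[[idx[k]]]
    if (is.null(vals)) return(NA_real_)
    v1 <- if (length(vals) >= alt_rank[k]) vals[alt_rank[k]] else vals[1L]
    suppressWarnings(as.numeric(v1))
  }, numeric(1))

  out <- data.frame(
    contig = fix[idx, "CHROM"],
    pos    = as.integer(fix[idx, "POS"]),
    id     = fix[idx, "ID"],
    ref    = fix[idx, "REF"],
    alt    = unlist(alts, use.names = FALSE),
    qual   = fix[idx, "QUAL"],
    filter = fix[idx, "FILTER"],
    info   = info,
    af     = af,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out$is_snv <- nchar(out$ref) == 1L & nchar(out$alt) == 1L &
    out$ref %in% c("A", "C", "G", "T") & out$alt %in% c("A", "C", "G", "T") &
    out$ref != out$alt
  skipped <- 0L
  if (require_snv) {
    skipped <- sum(!out$is_snv)
    out <- out[out$is_snv, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "header") <- meta
  attr(out, "skipped_non_snv") <- skipped
  class(out) <- c("variant_records", class(out))
  out
}

# Parse one INFO key out of raw INFO strings; returns a list of character
# vectors (comma-split values), NULL where the key is absent.
info_field <- function(info, key) {
  lapply(strsplit(info, ";", fixed = TRUE), function(kv) {
    hit <- grep(paste0("^", key, "="), kv, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    strsplit(sub(paste0("^", key, "="), "", hit[1L]), ",", fixed = TRUE)[[1L]]
  })
}

# All INFO values of one raw INFO string (flags contribute their name).
info_values <- function(info) {
  kv <- strsplit(info, ";", fixed = TRUE)[[1L]]
  sub("^[^=]*=", "", kv)
}

ARTEMIS_INFO_HEADER <- c(
  '##INFO=<ID=ARTEMIS_PAM,Number=1,Type=Integer,Description="Signed offset of the PAM start (0-based) relative to the SNV position on the reference strand">',
  '##INFO=<ID=ARTEMIS_SEED,Number=1,Type=Integer,Description="Seed position of the SNV, counted 1..seedsize from the first base 3prime of the PAM">',
  '##INFO=<ID=ARTEMIS_STRAND,Number=1,Type=Character,Description="Strand carrying the PAM (+ or -)">',
  '##INFO=<ID=ARTEMIS_GRNA_REF,Number=1,Type=String,Description="Reference-allele protospacer (DNA, PAM-strand orientation)">',
  '##INFO=<ID=ARTEMIS_GRNA_ALT,Number=1,Type=String,Description="Alternate-allele protospacer (DNA, PAM-strand orientation)">'
)

#' Write scan hits as an annotated VCF
#'
#' Each hit becomes one VCF data line carrying the source record's fields plus
#' five INFO keys: `ARTEMIS_PAM` (signed offset of the 0-based PAM start
#' relative to the 0-based SNV position on the reference strand),
#' `ARTEMIS_SEED` (seed position, 1 = PAM-proximal), `ARTEMIS_STRAND` (+/-),
#' and `ARTEMIS_GRNA_REF`/`ARTEMIS_GRNA_ALT` (protospacer-orientation DNA
#' spacer targets). These key names are this package's own; they are declared
#' in the emitted header. Writing then reading back through [read_vcf()]
#' preserves all fields.
#'
#' @param hits An `artemis_hits` data.frame from [artemis_scan()].
#' @param header Character vector of `##` header lines from the source VCF
#'   (e.g. `attr(variants, "header")`); a minimal header is generated when
#'   `NULL`.
#' @param path Output file path, or `""` for standard output.
#' @return Invisibly, the lines written.
#' @export
write_hits_vcf <- function(hits, header = NULL, path = "") {
  if (is.null(header) || length(header) == 0L) header <- "##fileformat=VCFv4.2"
  header <- header[!grepl("^##INFO=<ID=ARTEMIS_", header)]
  header <- header[!grepl("^#CHROM", header)]
  lines <- c(header, ARTEMIS_INFO_HEADER,
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   sep = "\t"))
  if (!is.null(hits) && nrow(hits) > 0L) {
    pam_off <- hits$pam_start - (hits$pos - 1L)
    extra <- paste0("ARTEMIS_PAM=", pam_off,
                    ";ARTEMIS_SEED=", hits$seed_pos,
                    ";ARTEMIS_STRAND=", hits$strand,
                    ";ARTEMIS_GRNA_REF=", hits$spacer_ref,
                    ";ARTEMIS_GRNA_ALT=", hits$spacer_alt)
    info <- ifelse(hits$info == "." | hits$info == "", extra,
                   paste0(hits$info, ";", extra))
    lines <- c(lines, paste(hits$contig, hits$pos, hits$id, hits$ref, hits$alt,
                            hits$qual, hits$filter, info, sep = "\t"))
  }
  con <- if (identical(path, "")) stdout() else file(path, "w")
  if (!identical(path, "")) on.exit(close(con))
  writeLines(lines, con)
  invisible(lines)
}

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of DNA or RNA sequences
#'
#' DNA in, DNA out (`A<->T`); RNA in, RNA out (`A<->U`). The alphabet is
#' inferred from the sequence: a string containing both T and U is rejected.
#' `revcomp` is an involution: `revcomp(revcomp(x)) == x`.
#'
#' @param seq Character vector of sequences over A,C,G,T,N or A,C,G,U,N.
#' @return Character vector of reverse complements, same lengths.
#' @examples
#' revcomp("GGTTTACGA")  # "TCGTAAACC"
#' @export
revcomp <- function(seq) {
  out <- vapply(seq, function(s) {
    s <- toupper(s)
    has_t <- grepl("T", s, fixed = TRUE)
    has_u <- grepl("U", s, fixed = TRUE)
    if (has_t && has_u) stop("sequence mixes T and U: cannot infer DNA vs RNA")
    if (has_u) {
      if (grepl("[^ACGUN]", s)) stop("invalid RNA characters in sequence")
      comp <- chartr("ACGUN", "UGCAN", s)
    } else {
      if (grepl("[^ACGTN]", s)) stop("invalid DNA characters in sequence")
      comp <- chartr("ACGTN", "TGCAN", s)
    }
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  out
}
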