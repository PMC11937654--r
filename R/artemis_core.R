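# The scan geometry, in 0-based half-open coordinates on the forward text:
#
#   forward PAM [s,e):  seed bases occupy e .. e+seed_size-1, protospacer is
#     [e, e+spacer_length); an SNV at pos0 has seed offset pos0 - e + 1.
#   reverse PAM [s,e):  the PAM strand reads revcomp(text[s,e)); seed bases
#     occupy s-1 .. s-seed_size (walking leftwards), protospacer window is
#     [s-spacer_length, s) reverse-complemented; seed offset is s - pos0.
#
# Seed offset 1 is always the PAM-proximal base of the protospacer.

IUPAC_CLASS <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

# Compile an IUPAC motif (e.g. TTTV) to a regex; pass through anything that
# contains non-IUPAC characters as a raw regex (the `pamregex` escape hatch).
pam_to_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  if (all(chars %in% names(IUPAC_CLASS))) {
    paste(IUPAC_CLASS[chars], collapse = "")
  } else {
    pattern
  }
}

#' Scan configuration for the targetable-SNV search
#'
#' Bundles the tunable parameters of the scan. Defaults follow the canonical
#' LbCas12a geometry: a TTTV PAM, a 5-nt seed region immediately 3' of the
#' PAM, and 21-nt spacers. `pam_pattern` accepts either an IUPAC motif
#' (compiled to a regular expression internally) or a raw regular expression;
#' a genome N never matches any PAM base.
#'
#' @param pam_pattern IUPAC motif or regex for the PAM on its own strand
#'   (default `"TTTV"`).
#' @param seed_size Number of seed bases 3' of the PAM (default 5).
#' @param spacer_length Protospacer/spacer length in nt (default 21).
#' @param af_threshold Allele frequency at or above which a common variant
#'   overlapping a PAM excludes the hit (default 0.01).
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(pam_pattern = "TTTV", seed_size = 5L,
                        spacer_length = 21L, af_threshold = 0.01,
                        both_strands = TRUE) {
  seed_size <- as.integer(seed_size)
  spacer_length <- as.integer(spacer_length)
  if (seed_size < 1L) stop("seed_size must be >= 1")
  if (spacer_length < 1L) stop("spacer_length must be >= 1")
  if (seed_size > spacer_length) stop("seed_size must be <= spacer_length")
  if (af_threshold < 0 || af_threshold > 1) stop("af_threshold must be in [0,1]")
  rx <- pam_to_regex(pam_pattern)
  ok <- tryCatch({ grepl(rx, "ACGT", perl = TRUE); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("invalid PAM pattern/regex: ", pam_pattern)
  structure(list(pam_pattern = pam_pattern, pam_regex = rx,
                 seed_size = seed_size, spacer_length = spacer_length,
                 af_threshold = af_threshold, both_strands = both_strands),
            class = "scan_config")
}

#' @export
print.scan_config <- function(x, ...) {
  cat("Cas12a scan configuration\n",
      "  PAM pattern:    ", x$pam_pattern, "\n",
      "  seed size:      ", x$seed_size, " nt\n",
      "  spacer length:  ", x$spacer_length, " nt\n",
      "  AF threshold:   ", x$af_threshold, "\n",
      "  both strands:   ", x$both_strands, "\n", sep = "")
  invisible(x)
}

# All (possibly overlapping) matches of a fixed-or-variable-length regex in
# `s`, via a zero-width lookahead with a capture group.
regex_hits <- function(s, rx) {
  m <- gregexpr(paste0("(?=(", rx, "))"), s, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(data.frame(start1 = integer(), len = integer()))
  cs <- attr(m, "capture.start")[, 1L]
  cl <- attr(m, "capture.length")[, 1L]
  keep <- cl > 0L
  data.frame(start1 = as.integer(cs[keep]), len = as.integer(cl[keep]))
}

#' Find PAM sites in a genome
#'
#' Reports every occurrence of the PAM motif on the forward strand and, when
#' `config$both_strands`, every window whose reverse complement matches on
#' the reverse strand. Overlapping occurrences are all reported. Coordinates
#' are 0-based half-open on the forward text; `motif` is the matched word in
#' PAM orientation (reverse-complemented for `-` sites).
#'
#' @param genome A `genome_map` (see [read_fasta()]) or a single named
#'   character sequence.
#' @param config A [scan_config()].
#' @return `data.frame` with columns `contig`, `start`, `end`, `strand`,
#'   `motif`, ordered by (contig, start, strand with + first).
#' @export
find_pam_sites <- function(genome, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  if (is.null(names(genome)) || any(names(genome) == "")) {
    stop("genome sequences must be named by contig id")
  }
  res <- lapply(names(genome), function(ctg) {
    s <- genome[[ctg]]
    n <- nchar(s)
    fwd <- regex_hits(s, config$pam_regex)
    out <- data.frame(contig = character(), start = integer(), end = integer(),
                      strand = character(), motif = character())
    if (nrow(fwd)) {
      out <- rbind(out, data.frame(
        contig = ctg, start = fwd$start1 - 1L, end = fwd$start1 - 1L + fwd$len,
        strand = "+",
        motif = substring(s, fwd$start1, fwd$start1 + fwd$len - 1L)))
    }
    if (isTRUE(config$both_strands)) {
      rc <- revcomp(s)
      rev <- regex_hits(rc, config$pam_regex)
      if (nrow(rev)) {
        start0 <- n - (rev$start1 - 1L) - rev$len
        out <- rbind(out, data.frame(
          contig = ctg, start = start0, end = start0 + rev$len,
          strand = "-",
          motif = substring(rc, rev$start1, rev$start1 + rev$len - 1L)))
      }
    }
    out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Seed offset of an SNV relative to one PAM site
#'
#' Returns the 1-based seed position (1 = PAM-proximal protospacer base) of
#' the variant when it lies inside the seed window of the PAM, otherwise
#' `NA`. A variant inside the PAM itself is not in the seed.
#'
#' @param pam One row of [find_pam_sites()] output (or a list with `contig`,
#'   `start`, `end`, `strand`).
#' @param variant One row of [read_vcf()] output (needs `contig`, `pos`).
#' @param config A [scan_config()].
#' @return Integer seed position in `[1, seed_size]`, or `NA_integer_`.
#' @export
seed_offset <- function(pam, variant, config = scan_config()) {
  if (!identical(as.character(pam$contig), as.character(variant$contig))) {
    stop("contig mismatch between PAM site (", pam$contig,
         ") and variant (", variant$contig, ")")
  }
  pos0 <- as.integer(variant$pos) - 1L
  if (pam$strand == "+") {
    off <- pos0 - as.integer(pam$end) + 1L
  } else {
    off <- as.integer(pam$start) - pos0
  }
  if (off >= 1L && off <= config$seed_size) off else NA_integer_
}

subst_at <- function(s, i, base) {
  substr(s, i, i) <- base
  s
}

#' Scan a genome and variant set for Cas12a-targetable SNVs
#'
#' The central operation: for every SNV whose position falls in the seed
#' window of a PAM site, emits one hit per (SNV, PAM) pair carrying the seed
#' offset and the reference/alternate protospacer sequences in PAM-strand
#' (protospacer) orientation. Reverse-strand hits are extracted by reverse
#' complementation, with the alleles complemented accordingly. Hits whose
#' full spacer window would leave the contig are dropped and counted in
#' `attr(x, "dropped_boundary")`; SNVs whose REF disagrees with the genome
#' are dropped and counted in `attr(x, "dropped_ref_mismatch")` with a
#' warning.
#'
#' Contig names must match exactly between genome and variants; a variant
#' contig absent from the genome is a hard error listing both name sets
#' (set `fix_chr_prefix = TRUE` to attempt adding/removing a "chr" prefix).
#'
#' @param genome A `genome_map` from [read_fasta()].
#' @param variants A `variant_records` data.frame from [read_vcf()];
#'   non-SNV rows are ignored.
#' @param config A [scan_config()].
#' @param fix_chr_prefix Attempt "chr" prefix reconciliation instead of
#'   erroring (default `FALSE`).
#' @return `data.frame` of class `artemis_hits`: the variant columns plus
#'   `pam_start`, `pam_end`, `strand`, `motif`, `seed_pos`, `spacer_ref`,
#'   `spacer_alt`; sorted by (contig, pos, strand + before -, pam_start).
#' @examples
#' gm <- structure(c(chr_toy = "GGTTTACGATCGATCGATCGATCGATCGATCG"),
#'                 class = "genome_map")
#' v <- data.frame(contig = "chr_toy", pos = 9L, id = "v1", ref = "A",
#'                 alt = "G", qual = ".", filter = ".", info = ".",
#'                 af = NA_real_, is_snv = TRUE)
#' artemis_scan(gm, v)
#' @export
artemis_scan <- function(genome, variants, config = scan_config(),
                         fix_chr_prefix = FALSE) {
  stopifnot(inherits(config, "scan_config"))
  vars <- variants[variants$is_snv, , drop = FALSE]
  missing_ctg <- setdiff(unique(vars$contig), names(genome))
  if (length(missing_ctg) && fix_chr_prefix) {
    remap <- ifelse(paste0("chr", vars$contig) %in% names(genome),
                    paste0("chr", vars$contig),
                    ifelse(sub("^chr", "", vars$contig) %in% names(genome),
                           sub("^chr", "", vars$contig), vars$contig))
    vars$contig <- remap
    missing_ctg <- setdiff(unique(vars$contig), names(genome))
  }
  if (length(missing_ctg)) {
    stop("contig name mismatch between variants and reference.\n",
         "  variant contigs: ", paste(unique(variants$contig), collapse = ", "), "\n",
         "  genome contigs:  ", paste(names(genome), collapse = ", "), "\n",
         "  unresolved:      ", paste(missing_ctg, collapse = ", "),
         "\nGenome builds and contig names must match between the inputs.")
  }
  sites_all <- find_pam_sites(genome, config)
  sp <- config$spacer_length
  dropped_boundary <- 0L
  dropped_ref <- 0L
  rows <- vector("list", nrow(vars))
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    v$pos <- as.integer(v$pos)
    s <- genome[[v$contig]]
    n <- nchar(s)
    pos0 <- v$pos - 1L
    if (pos0 < 0L || pos0 >= n) next
    ref_base <- substr(s, v$pos, v$pos)
    if (ref_base != v$ref) {
      dropped_ref <- dropped_ref + 1L
      next
    }
    sites <- sites_all[sites_all$contig == v$contig, , drop = FALSE]
    fwd <- sites[sites$strand == "+" &
                 pos0 - sites$end + 1L >= 1L &
                 pos0 - sites$end + 1L <= config$seed_size, , drop = FALSE]
    rev <- sites[sites$strand == "-" &
                 sites$start - pos0 >= 1L &
                 sites$start - pos0 <= config$seed_size, , drop = FALSE]
    acc <- list()
    if (nrow(fwd)) for (j in seq_len(nrow(fwd))) {
      e <- as.integer(fwd$end[j])
      if (e + sp > n) { dropped_boundary <- dropped_boundary + 1L; next }
      spacer <- substring(s, e + 1L, e + sp)
      off <- pos0 - e + 1L
      acc[[length(acc) + 1L]] <- data.frame(
        v, pam_start = fwd$start[j], pam_end = e, strand = "+",
        motif = fwd$motif[j], seed_pos = off,
        spacer_ref = spacer, spacer_alt = subst_at(spacer, off, v$alt),
        stringsAsFactors = FALSE)
    }
    if (nrow(rev)) for (j in seq_len(nrow(rev))) {
      st <- as.integer(rev$start[j])
      if (st - sp < 0L) { dropped_boundary <- dropped_boundary + 1L; next }
      spacer <- revcomp(substring(s, st - sp + 1L, st))
      off <- st - pos0
      acc[[length(acc) + 1L]] <- data.frame(
        v, pam_start = st, pam_end = rev$end[j], strand = "-",
        motif = rev$motif[j], seed_pos = off,
        spacer_ref = spacer,
        spacer_alt = subst_at(spacer, off, DNA_COMP[[v$alt]]),
        stringsAsFactors = FALSE)
    }
    if (length(acc)) rows[[i]] <- do.call(rbind, acc)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- cbind(vars[0, , drop = FALSE],
                 data.frame(pam_start = integer(), pam_end = integer(),
                            strand = character(), motif = character(),
                            seed_pos = integer(), spacer_ref = character(),
                            spacer_alt = character()))
  }
  out <- out[order(out$contig, out$pos, match(out$strand, c("+", "-")),
                   out$pam_start), , drop = FALSE]
  rownames(out) <- NULL
  if (dropped_ref > 0L) {
    warning(dropped_ref,
            " variant(s) dropped: REF allele disagrees with the reference genome")
  }
  attr(out, "dropped_boundary") <- dropped_boundary
  attr(out, "dropped_ref_mismatch") <- dropped_ref
  attr(out, "config") <- config
  class(out) <- c("artemis_hits", class(out))
  out
}

#' Exclude hits whose PAM overlaps a common population variant
#'
#' A hit is removed iff some common variant with known allele frequency
#' `>= config$af_threshold` overlaps any PAM base (`[pam_start, pam_end)`).
#' Variants with unknown AF never exclude. Removed hits and the offending
#' variants are reported in `attr(x, "excluded")`. Optionally the rule is
#' extended to the seed bases.
#'
#' @param hits An `artemis_hits` data.frame.
#' @param common A `variant_records` data.frame of population variants with
#'   an `af` column.
#' @param config A [scan_config()] (supplies `af_threshold`).
#' @param include_seed Also exclude on seed-base overlap (default `FALSE`:
#'   PAM bases only).
#' @return The retained hits, same class; excluded rows in
#'   `attr(x, "excluded")`.
#' @export
exclude_common_pam <- function(hits, common, config = scan_config(),
                               include_seed = FALSE) {
  if (nrow(hits) == 0L || is.null(common) || nrow(common) == 0L) {
    attr(hits, "excluded") <- hits[0, , drop = FALSE]
    return(hits)
  }
  com <- common[!is.na(common$af) & common$af >= config$af_threshold, ,
                drop = FALSE]
  offender <- character(nrow(hits))
  drop <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    lo <- h$pam_start; hi <- h$pam_end        # [lo, hi)
    if (include_seed) {
      if (h$strand == "+") hi <- h$pam_end + config$seed_size
      else lo <- h$pam_start - config$seed_size
    }
    ov <- com$contig == h$contig & (com$pos - 1L) >= lo & (com$pos - 1L) < hi
    if (any(ov)) {
      drop[i] <- TRUE
      offender[i] <- paste(com$id[ov], collapse = ",")
    }
  }
  excluded <- hits[drop, , drop = FALSE]
  if (nrow(excluded)) excluded$excluded_by <- offender[drop]
  out <- hits[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "config") <- attr(hits, "config")
  class(out) <- unique(c("artemis_hits", class(out)))
  out
}

#' Keep hits whose INFO annotations match any keyword
#'
#' Case-insensitive substring match of each keyword against every INFO value
#' of the underlying variant (e.g. a ClinVar-style `CLNDN` disease name).
#' An empty keyword list keeps everything.
#'
#' @param hits An `artemis_hits` data.frame.
#' @param keywords Character vector of keywords (e.g.
#'   `c("cancer", "melanoma", "carcinoma")`).
#' @return The filtered hits, same class.
#' @export
keyword_filter <- function(hits, keywords) {
  if (length(keywords) == 0L || nrow(hits) == 0L) return(hits)
  keep <- vapply(hits$info, function(info) {
    vals <- info_values(info)
    any(vapply(keywords, function(k) any(grepl(k, vals, ignore.case = TRUE,
                                               fixed = FALSE)), logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- attr(hits, "config")
  class(out) <- unique(c("artemis_hits", class(out)))
  out
}
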