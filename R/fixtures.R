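# Synthetic toy genomes with planted ground truth, plus a brute-force scan
# oracle. The oracle deliberately shares no matching machinery with
# artemis_scan(): motifs are tested base by base against IUPAC allowed-sets
# (no regular expressions), seed membership is tested by enumerating the
# seed coordinates, and spacers are assembled by direct slicing with a local
# complement table.

BF_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
BF_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

bf_pattern_sets <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  if (!all(chars %in% names(BF_IUPAC))) {
    stop("brute-force oracle only supports IUPAC motifs, got: ", pattern)
  }
  lapply(chars, function(ch) BF_IUPAC[[ch]])
}

bf_revcomp <- function(chars) rev(unname(BF_COMP[chars]))

# 0-based starts of all motif windows, by direct per-base set membership.
bf_match_starts <- function(chars, sets, reverse = FALSE) {
  L <- length(sets)
  n <- length(chars)
  if (n < L) return(integer())
  cand <- seq_len(n - L + 1L)
  for (k in seq_len(L)) {
    allowed <- if (reverse) unname(BF_COMP[sets[[k]]]) else sets[[k]]
    pos <- if (reverse) cand + L - k else cand + k - 1L
    cand <- cand[chars[pos] %in% allowed]
    if (length(cand) == 0L) break
  }
  cand - 1L
}

#' Brute-force scan oracle
#'
#' Independent re-derivation of [artemis_scan()] results for small inputs:
#' every window on both strands is tested against the PAM motif base by
#' base, seed membership is decided by enumerating the seed coordinates of
#' every site, and spacers are sliced and complemented with a local lookup
#' table. Intended as a cross-check, not for production-scale inputs.
#'
#' @param genome A `genome_map`.
#' @param variants A `variant_records` data.frame (non-SNVs ignored).
#' @param config A [scan_config()] (IUPAC motifs only).
#' @return `data.frame` with the same columns and ordering as
#'   [artemis_scan()].
#' @export
brute_force_scan <- function(genome, variants, config = scan_config()) {
  sets <- bf_pattern_sets(config$pam_pattern)
  L <- length(sets)
  sp <- config$spacer_length
  vars <- variants[variants$is_snv, , drop = FALSE]
  rows <- list()
  for (ctg in names(genome)) {
    chars <- strsplit(genome[[ctg]], "", fixed = TRUE)[[1L]]
    n <- length(chars)
    fwd_starts <- bf_match_starts(chars, sets)
    rev_starts <- if (isTRUE(config$both_strands)) {
      bf_match_starts(chars, sets, reverse = TRUE)
    } else integer()
    vc <- vars[vars$contig == ctg, , drop = FALSE]
    for (i in seq_len(nrow(vc))) {
      v <- vc[i, ]
      v$pos <- as.integer(v$pos)
      pos0 <- v$pos - 1L
      if (pos0 < 0L || pos0 >= n) next
      if (chars[pos0 + 1L] != v$ref) next
      for (s0 in fwd_starts) {
        e0 <- s0 + L
        for (p in seq_len(config$seed_size)) {      # explicit seed coords
          if (e0 + p - 1L == pos0) {
            if (e0 + sp > n) next
            spacer_chars <- chars[(e0 + 1L):(e0 + sp)]
            alt_chars <- spacer_chars
            alt_chars[p] <- v$alt
            rows[[length(rows) + 1L]] <- data.frame(
              v, pam_start = s0, pam_end = e0, strand = "+",
              motif = paste(chars[(s0 + 1L):e0], collapse = ""),
              seed_pos = p,
              spacer_ref = paste(spacer_chars, collapse = ""),
              spacer_alt = paste(alt_chars, collapse = ""),
              stringsAsFactors = FALSE)
          }
        }
      }
      for (s0 in rev_starts) {
        e0 <- s0 + L
        for (p in seq_len(config$seed_size)) {
          if (s0 - p == pos0) {
            if (s0 - sp < 0L) next
            window <- chars[(s0 - sp + 1L):s0]
            spacer_chars <- bf_revcomp(window)
            alt_chars <- spacer_chars
            alt_chars[p] <- BF_COMP[[v$alt]]
            rows[[length(rows) + 1L]] <- data.frame(
              v, pam_start = s0, pam_end = e0, strand = "-",
              motif = paste(bf_revcomp(chars[(s0 + 1L):e0]), collapse = ""),
              seed_pos = p,
              spacer_ref = paste(spacer_chars, collapse = ""),
              spacer_alt = paste(alt_chars, collapse = ""),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
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
  out
}

sample_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# Mutate a free (unprotected) base of every motif occurrence that is not a
# planted site, until the text carries no motif besides the planted ones.
# Returns NULL when an occurrence has no free base to break (caller retries
# with a fresh layout).
scrub_motifs <- function(chars, sets, protect, planted_starts = integer(),
                         max_iter = 200L) {
  L <- length(sets)
  for (it in seq_len(max_iter)) {
    occ <- unique(c(bf_match_starts(chars, sets),
                    bf_match_starts(chars, sets, reverse = TRUE)))
    occ <- setdiff(occ, planted_starts)
    if (length(occ) == 0L) return(chars)
    for (s0 in occ) {
      free <- which(!protect[(s0 + 1L):(s0 + L)])
      if (length(free) == 0L) return(NULL)
      k <- free[sample.int(length(free), 1L)]
      i <- s0 + k
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
  }
  NULL
}

FIXTURE_DISEASES <- c("Melanoma", "Lung carcinoma", "Pancreatic cancer",
                      "Cystic fibrosis", "Hereditary deafness")

#' Generate a toy genome with planted Cas12a-targetable SNVs
#'
#' Builds a single random contig that is free of PAM motifs except for
#' `n_pams` planted TTTV sites (random strand), plants `n_seed_snvs` SNVs at
#' known seed offsets 1..seed_size of those sites (the expected hits) and
#' `n_decoy_snvs` decoy variants that must not be hits (classes cycle
#' through: `offset_out` at seed offsets just beyond the window, `in_PAM`
#' inside a PAM, `no_PAM` far from any PAM, and `indel`). Regeneration with
#' the same seed is byte-identical. The expected hit set is derived with
#' [brute_force_scan()] and checked against the planted positions; layouts
#' where the two disagree are regenerated.
#'
#' @param length Contig length in bp (default 2000).
#' @param n_pams Number of planted PAM sites (default 5).
#' @param n_seed_snvs Number of planted seed SNVs (= expected hits).
#' @param n_decoy_snvs Number of decoy variants.
#' @param seed Integer random seed.
#' @param config A [scan_config()] (IUPAC motif required).
#' @param dir If non-`NULL`, FASTA/VCF/truth-TSV files are written there.
#' @return A list of class `planted_truth`: `genome` (a `genome_map`),
#'   `variants` (a `variant_records` data.frame), `expected_hits`, `truth`
#'   (per-variant class labels), `seed`, and (when `dir` is given) `paths`.
#' @export
generate_toy_genome <- function(length = 2000L, n_pams = 5L, n_seed_snvs = 5L,
                                n_decoy_snvs = 5L, seed = 1L,
                                config = scan_config(), dir = NULL) {
  length <- as.integer(length)
  sets <- bf_pattern_sets(config$pam_pattern)
  L <- length(sets)
  sp <- config$spacer_length
  margin <- sp + 20L
  slot <- 2L * (sp + config$seed_size + L)
  if (length < 2L * margin + n_pams * slot) {
    stop("contig of ", length, " bp is too short to place ", n_pams,
         " well-separated PAM sites; need >= ", 2L * margin + n_pams * slot)
  }
  for (attempt in seq_len(10L)) {
    set.seed(seed * 1000L + attempt)
    res <- try(plant_layout(length, n_pams, n_seed_snvs, n_decoy_snvs,
                            config, sets, L, sp, margin, slot), silent = TRUE)
    if (!inherits(res, "try-error") && !is.null(res)) {
      res$seed <- seed
      class(res) <- "planted_truth"
      if (!is.null(dir)) res$paths <- write_fixture_files(res, dir)
      return(res)
    }
  }
  stop("could not place the requested features after bounded retries; ",
       "use a longer contig or fewer features")
}

plant_layout <- function(length, n_pams, n_seed_snvs, n_decoy_snvs,
                         config, sets, L, sp, margin, slot) {
  chars <- sample_bases(length)
  protect <- rep(FALSE, length)
  chars <- scrub_motifs(chars, sets, protect)
  if (is.null(chars)) return(NULL)

  # evenly-spaced anchors with random jitter keep sites well separated
  anchors <- margin + as.integer(round((seq_len(n_pams) - 0.5) / n_pams *
                                         (length - 2L * margin))) +
    sample.int(11L, n_pams, replace = TRUE) - 6L
  strands <- sample(c("+", "-"), n_pams, replace = TRUE)
  pam <- data.frame(start = integer(n_pams), end = integer(n_pams),
                    strand = strands)
  for (i in seq_len(n_pams)) {
    word <- vapply(sets, function(set) set[sample.int(length(set), 1L)],
                   character(1))                       # PAM-orientation word
    s0 <- anchors[i]
    fwd_word <- if (strands[i] == "+") word else bf_revcomp(word)
    chars[(s0 + 1L):(s0 + L)] <- fwd_word
    pam$start[i] <- s0
    pam$end[i] <- s0 + L
    lo <- max(1L, s0 - sp - 16L); hi <- min(length, s0 + L + sp + 16L)
    protect[lo:hi] <- TRUE
  }
  chars <- scrub_motifs(chars, sets, protect, planted_starts = pam$start)
  if (is.null(chars)) return(NULL)

  seed_coord <- function(i, off) {
    if (pam$strand[i] == "+") pam$end[i] + off - 1L else pam$start[i] - off
  }
  used <- new.env()
  claim <- function(pos0) {
    key <- as.character(pos0)
    if (!is.null(used[[key]])) return(FALSE)
    used[[key]] <- TRUE
    TRUE
  }
  vrows <- list()
  add_var <- function(pos0, ref, alt, class, info) {
    vrows[[length(vrows) + 1L]] <<- data.frame(
      contig = "chr_toy", pos = pos0 + 1L, id = sprintf("v%03d", length(vrows) + 1L),
      ref = ref, alt = alt, qual = ".", filter = ".", info = info,
      af = NA_real_, is_snv = nchar(ref) == 1L && nchar(alt) == 1L,
      class = class, stringsAsFactors = FALSE)
  }
  # planted hits: cycle PAMs, cycle offsets 1..seed_size
  for (k in seq_len(n_seed_snvs)) {
    i <- (k - 1L) %% n_pams + 1L
    off <- (k - 1L) %% config$seed_size + 1L
    pos0 <- seed_coord(i, off)
    if (!claim(pos0)) return(NULL)
    ref <- chars[pos0 + 1L]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    dis <- FIXTURE_DISEASES[(k - 1L) %% length(FIXTURE_DISEASES) + 1L]
    add_var(pos0, ref, alt, "seed_hit", paste0("CLNDN=", gsub(" ", "_", dis)))
  }
  # decoys
  decoy_classes <- rep(c("offset_out", "in_PAM", "no_PAM", "indel"),
                       length.out = n_decoy_snvs)
  far_from_pam <- function() {
    for (tr in seq_len(200L)) {
      pos0 <- sample(seq(margin, length - margin), 1L)
      d <- pmin(abs(pos0 - pam$start), abs(pos0 - pam$end))
      if (min(d) > sp + config$seed_size + L && claim(pos0)) return(pos0)
    }
    NULL
  }
  for (k in seq_along(decoy_classes)) {
    cls <- decoy_classes[k]
    i <- (k - 1L) %% n_pams + 1L
    if (cls == "offset_out") {
      off <- config$seed_size + (k - 1L) %% 3L + 1L   # seed_size+1 .. +3
      pos0 <- seed_coord(i, off)
      if (!claim(pos0)) return(NULL)
      ref <- chars[pos0 + 1L]
      add_var(pos0, ref, sample(setdiff(c("A", "C", "G", "T"), ref), 1L),
              cls, "CLNDN=Decoy_beyond_seed")
    } else if (cls == "in_PAM") {
      pos0 <- pam$start[i] + (k - 1L) %% L
      if (!claim(pos0)) return(NULL)
      ref <- chars[pos0 + 1L]
      add_var(pos0, ref, sample(setdiff(c("A", "C", "G", "T"), ref), 1L),
              cls, "CLNDN=Decoy_in_PAM")
    } else if (cls == "no_PAM") {
      pos0 <- far_from_pam()
      if (is.null(pos0)) return(NULL)
      ref <- chars[pos0 + 1L]
      add_var(pos0, ref, sample(setdiff(c("A", "C", "G", "T"), ref), 1L),
              cls, "CLNDN=Decoy_no_PAM")
    } else {
      pos0 <- far_from_pam()
      if (is.null(pos0)) return(NULL)
      ref <- paste0(chars[pos0 + 1L], chars[pos0 + 2L])
      add_var(pos0, ref, chars[pos0 + 1L], cls, "CLNDN=Decoy_indel")
    }
  }
  variants <- do.call(rbind, vrows)
  variants <- variants[order(variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  truth <- variants[, c("contig", "pos", "id", "class")]
  vr <- variants[, setdiff(names(variants), "class"), drop = FALSE]
  attr(vr, "header") <- fixture_vcf_header()
  attr(vr, "skipped_non_snv") <- 0L
  class(vr) <- c("variant_records", class(vr))
  genome <- structure(paste(chars, collapse = ""), .Names = "chr_toy")
  class(genome) <- c("genome_map", class(genome))
  expected <- brute_force_scan(genome, vr, config)
  # planted truth must coincide with the oracle, else the layout is invalid
  planted <- truth[truth$class == "seed_hit", ]
  if (nrow(expected) != nrow(planted) ||
      !setequal(paste(expected$contig, expected$pos),
                paste(planted$contig, planted$pos))) {
    return(NULL)
  }
  list(genome = genome, variants = vr, expected_hits = expected,
       truth = truth)
}

fixture_vcf_header <- function() c(
  "##fileformat=VCFv4.2",
  "##source=artemisdx_fixture_generator",
  "##contig=<ID=chr_toy>",
  '##INFO=<ID=CLNDN,Number=1,Type=String,Description="Synthetic disease annotation">')

#' Write fixture files (FASTA, VCF, truth TSV) for a planted truth
#'
#' @param truth A `planted_truth` from [generate_toy_genome()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths (`fasta`, `vcf`, `truth`).
#' @export
write_fixture_files <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "toy_genome.fa")
  vcf <- file.path(dir, "toy_variants.vcf")
  tsv <- file.path(dir, "toy_truth.tsv")
  seqs <- unclass(truth$genome)
  lines <- unlist(lapply(names(seqs), function(ctg) {
    s <- seqs[[ctg]]
    c(paste0(">", ctg),
      substring(s, seq(1L, nchar(s), 60L),
                pmin(seq(1L, nchar(s), 60L) + 59L, nchar(s))))
  }))
  writeLines(lines, fasta)
  v <- truth$variants
  writeLines(c(fixture_vcf_header(),
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               paste(v$contig, v$pos, v$id, v$ref, v$alt, v$qual, v$filter,
                     v$info, sep = "\t")), vcf)
  utils::write.table(truth$truth, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta = fasta, vcf = vcf, truth = tsv)
}

#' Random scan test case (genome + random SNVs, no planting)
#'
#' A purely random contig with random SNVs (reference alleles taken from the
#' genome), used for oracle-equivalence and symmetry property checks.
#'
#' @param length Contig length in bp.
#' @param n_variants Number of random SNVs.
#' @param seed Integer random seed.
#' @return List with `genome` (a `genome_map`) and `variants` (a
#'   `variant_records` data.frame).
#' @export
random_scan_case <- function(length = 2000L, n_variants = 50L, seed = 1L) {
  set.seed(seed)
  chars <- sample_bases(length)
  pos0 <- sample.int(length, min(n_variants, length)) - 1L
  ref <- chars[pos0 + 1L]
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                character(1), USE.NAMES = FALSE)
  v <- data.frame(contig = "chr_rand", pos = pos0 + 1L,
                  id = sprintf("r%03d", seq_along(pos0)),
                  ref = ref, alt = alt, qual = ".", filter = ".",
                  info = ".", af = NA_real_, is_snv = TRUE,
                  stringsAsFactors = FALSE)
  v <- v[order(v$pos), , drop = FALSE]
  rownames(v) <- NULL
  class(v) <- c("variant_records", class(v))
  genome <- structure(paste(chars, collapse = ""), .Names = "chr_rand")
  class(genome) <- c("genome_map", class(genome))
  list(genome = genome, variants = v)
}
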