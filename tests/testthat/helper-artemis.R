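# Shared toy inputs. The 32-bp contig carries one forward TTTA PAM at
# 0-based [2,6); its 5-nt seed window covers 1-based positions 7..11.
TOY_SEQ <- "GGTTTACGATCGATCGATCGATCGATCGATCG"

toy_genome <- function(seq = TOY_SEQ, contig = "chr_toy") {
  structure(stats::setNames(seq, contig), class = c("genome_map", "character"))
}

make_variants <- function(contig, pos, ref, alt, id = NULL, info = ".",
                          af = NA_real_) {
  n <- length(pos)
  if (is.null(id)) id <- sprintf("v%02d", seq_len(n))
  out <- data.frame(contig = rep_len(contig, n), pos = as.integer(pos),
                    id = id, ref = ref, alt = alt, qual = ".", filter = ".",
                    info = rep_len(info, n), af = rep_len(af, n),
                    stringsAsFactors = FALSE)
  out$is_snv <- nchar(out$ref) == 1L & nchar(out$alt) == 1L & out$ref != out$alt
  class(out) <- c("variant_records", class(out))
  out
}

toy_variant <- function() make_variants("chr_toy", 9L, "A", "G")

toy_hit <- function() artemis_scan(toy_genome(), toy_variant())[1, ]

# Column-wise equality of two hit tables, ignoring bookkeeping attributes.
strip_hits <- function(d) {
  d <- as.data.frame(d)
  attributes(d) <- attributes(d)[c("names", "row.names")]
  class(d) <- "data.frame"
  rownames(d) <- NULL
  d
}

expect_same_hits <- function(a, b) {
  expect_identical(strip_hits(a), strip_hits(b))
}

write_toy_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
             path)
  path
}

write_toy_vcf <- function(variants, path = tempfile(fileext = ".vcf"),
                          header = c("##fileformat=VCFv4.2",
                                     "##contig=<ID=chr_toy>")) {
  body <- paste(variants$contig, variants$pos, variants$id, variants$ref,
                variants$alt, variants$qual, variants$filter, variants$info,
                sep = "\t")
  writeLines(c(header,
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"), body), path)
  path
}

# Independent per-base complement for property checks (kept separate from
# the package's tables on purpose).
ref_complement <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
           U = "A")
  paste(rev(map[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
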