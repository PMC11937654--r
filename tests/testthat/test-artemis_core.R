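test_that("find_pam_sites finds forward and reverse TTTV occurrences", {
  sites <- find_pam_sites(toy_genome())
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$start, 2L)
  expect_identical(sites$end, 6L)
  expect_identical(sites$strand, "+")
  expect_identical(sites$motif, "TTTA")

  rev <- find_pam_sites(toy_genome("GCAAAT", "x"))
  expect_identical(rev$start, 1L)
  expect_identical(rev$end, 5L)
  expect_identical(rev$strand, "-")
  expect_identical(rev$motif, "TTTG")                 # revcomp of CAAA

  expect_identical(nrow(find_pam_sites(toy_genome("GGGGGG", "x"))), 0L)

  # overlapping occurrences (here across strands) are all reported
  ov <- find_pam_sites(toy_genome("TTTAAA", "x"))
  expect_identical(ov$start[ov$strand == "+"], 0L)      # TTTA
  expect_identical(ov$start[ov$strand == "-"], 2L)      # TAAA = revcomp TTTA

  # forward-only configuration drops the reverse site
  fwd_only <- find_pam_sites(toy_genome("GCAAAT", "x"),
                             scan_config(both_strands = FALSE))
  expect_identical(nrow(fwd_only), 0L)
})

test_that("seed_offset maps variants into the seed window and rejects others", {
  pam <- list(contig = "chr_toy", start = 2L, end = 6L, strand = "+")
  cfg <- scan_config()
  off <- function(pos) seed_offset(pam, list(contig = "chr_toy", pos = pos), cfg)
  expect_identical(off(9L), 3L)
  expect_identical(off(7L), 1L)
  expect_identical(off(11L), 5L)
  expect_true(is.na(off(12L)))                        # offset 6: outside
  expect_true(is.na(off(4L)))                         # inside the PAM
  rpam <- list(contig = "chr_toy", start = 10L, end = 14L, strand = "-")
  roff <- function(pos) seed_offset(rpam, list(contig = "chr_toy", pos = pos), cfg)
  expect_identical(roff(10L), 1L)                     # pos0 9 = start-1
  expect_identical(roff(6L), 5L)
  expect_true(is.na(roff(5L)))
  expect_error(off_bad <- seed_offset(pam, list(contig = "other", pos = 9L), cfg),
               "contig mismatch")
})

test_that("artemis_scan reproduces the worked toy example", {
  hits <- artemis_scan(toy_genome(), toy_variant())
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$pam_start, 2L)
  expect_identical(hits$pam_end, 6L)
  expect_identical(hits$strand, "+")
  expect_identical(hits$seed_pos, 3L)
  expect_identical(hits$spacer_ref, "CGATCGATCGATCGATCGATC")
  expect_identical(hits$spacer_alt, "CGGTCGATCGATCGATCGATC")

  # spacer pair differs exactly at seed_pos
  d <- which(strsplit(hits$spacer_ref, "")[[1]] != strsplit(hits$spacer_alt, "")[[1]])
  expect_identical(d, hits$seed_pos)

  # SNV left of the PAM: no window contains it
  expect_identical(nrow(artemis_scan(toy_genome(),
                                     make_variants("chr_toy", 2L, "G", "A"))), 0L)
})

test_that("artemis_scan errors hard on contig mismatch, with opt-in repair", {
  v <- make_variants("toy", 9L, "A", "G")              # name differs
  expect_error(artemis_scan(toy_genome(), v), "contig name mismatch")
  v2 <- make_variants("1", 9L, "A", "G")
  gm <- toy_genome(TOY_SEQ, "chr1")
  expect_error(artemis_scan(gm, v2), "contig name mismatch")
  expect_identical(nrow(artemis_scan(gm, v2, fix_chr_prefix = TRUE)), 1L)
})

test_that("hits whose spacer window leaves the contig are dropped and counted", {
  # PAM at [2,6) but contig too short for a 21-nt spacer
  gm <- toy_genome(substr(TOY_SEQ, 1, 15), "chr_toy")
  h <- artemis_scan(gm, toy_variant())
  expect_identical(nrow(h), 0L)
  expect_identical(attr(h, "dropped_boundary"), 1L)
})

test_that("scan equals the brute-force oracle on random toy genomes", {
  for (i in 1:25) {
    cs <- random_scan_case(1500, 40, seed = 100 + i)
    expect_same_hits(artemis_scan(cs$genome, cs$variants),
                     brute_force_scan(cs$genome, cs$variants))
  }
  # and under a non-default geometry
  cfg <- scan_config(pam_pattern = "TTTN", seed_size = 4L, spacer_length = 18L)
  for (i in 1:5) {
    cs <- random_scan_case(1200, 30, seed = 300 + i)
    expect_same_hits(artemis_scan(cs$genome, cs$variants, cfg),
                     brute_force_scan(cs$genome, cs$variants, cfg))
  }
})

test_that("reverse-complementing the genome mirrors + hits to - hits", {
  for (i in 1:10) {
    cs <- random_scan_case(1500, 40, seed = 200 + i)
    n <- nchar(cs$genome[[1]])
    rc <- toy_genome(revcomp(cs$genome[[1]]), names(cs$genome))
    v2 <- cs$variants
    v2$pos <- n - cs$variants$pos + 1L
    v2$ref <- vapply(cs$variants$ref, function(b) revcomp(b), "", USE.NAMES = FALSE)
    v2$alt <- vapply(cs$variants$alt, function(b) revcomp(b), "", USE.NAMES = FALSE)
    h1 <- artemis_scan(cs$genome, cs$variants)
    h2 <- artemis_scan(rc, v2)
    expect_identical(nrow(h1), nrow(h2))
    k1 <- paste(h1$pos, h1$strand, h1$seed_pos, h1$spacer_ref, h1$spacer_alt)
    flip <- c("+" = "-", "-" = "+")
    k2 <- paste(n - h2$pos + 1L, flip[h2$strand], h2$seed_pos,
                h2$spacer_ref, h2$spacer_alt)
    expect_setequal(k1, k2)
  }
})

test_that("seed window and AF threshold behave monotonically", {
  cs <- random_scan_case(2000, 60, seed = 11)
  h5 <- artemis_scan(cs$genome, cs$variants, scan_config(seed_size = 5))
  h7 <- artemis_scan(cs$genome, cs$variants, scan_config(seed_size = 7))
  key <- function(h) paste(h$pos, h$strand, h$pam_start)
  expect_true(all(key(h5) %in% key(h7)))               # enlarging keeps hits

  hits <- artemis_scan(toy_genome(), toy_variant())
  common <- make_variants("chr_toy", 4L, "T", "C", af = 0.3)
  kept_low <- exclude_common_pam(hits, common, scan_config(af_threshold = 0.01))
  kept_high <- exclude_common_pam(hits, common, scan_config(af_threshold = 0.5))
  expect_true(all(paste(kept_low$pos, kept_low$pam_start) %in%
                  paste(kept_high$pos, kept_high$pam_start)))
})

test_that("exclude_common_pam removes only PAM-overlapping common variants", {
  hits <- artemis_scan(toy_genome(), toy_variant())   # PAM [2,6)
  cfg <- scan_config()

  in_pam <- make_variants("chr_toy", 4L, "T", "C", af = 0.30)
  expect_identical(nrow(exclude_common_pam(hits, in_pam, cfg)), 0L)
  expect_identical(attr(exclude_common_pam(hits, in_pam, cfg), "excluded")$excluded_by,
                   "v01")

  rare <- make_variants("chr_toy", 4L, "T", "C", af = 0.001)
  expect_identical(nrow(exclude_common_pam(hits, rare, cfg)), 1L)

  in_seed <- make_variants("chr_toy", 9L, "A", "T", af = 0.30)
  expect_identical(nrow(exclude_common_pam(hits, in_seed, cfg)), 1L)  # PAM-only rule
  expect_identical(nrow(exclude_common_pam(hits, in_seed, cfg,
                                           include_seed = TRUE)), 0L)

  unknown <- make_variants("chr_toy", 4L, "T", "C", af = NA_real_)
  expect_identical(nrow(exclude_common_pam(hits, unknown, cfg)), 1L)  # unknown AF keeps

  expect_identical(nrow(exclude_common_pam(hits, unknown[0, ], cfg)), 1L)
})

test_that("keyword_filter matches INFO values case-insensitively", {
  v <- make_variants("chr_toy", 9L, "A", "G", info = "CLNDN=Melanoma")
  hits <- artemis_scan(toy_genome(), v)
  expect_identical(nrow(keyword_filter(hits, "melanoma")), 1L)
  expect_identical(nrow(keyword_filter(hits, c("carcinoma", "MELANOMA"))), 1L)
  expect_identical(nrow(keyword_filter(hits, "carcinoma")), 0L)
  expect_identical(nrow(keyword_filter(hits, character())), 1L)   # vacuous
})
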