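test_that("spacer_to_crrna maps DNA protospacer to scaffold + RNA spacer", {
  d <- spacer_to_crrna("CGATCGATCGATCGATCGATC", "ref")
  expect_identical(d$spacer_rna, "CGAUCGAUCGAUCGAUCGAUC")
  expect_identical(d$scaffold, "UAAUUUCUACUAAGUGUAGAU")
  expect_identical(nchar(d$full_rna), 42L)
  expect_true(startsWith(d$full_rna, d$scaffold))
  expect_true(is.na(d$sm_pos))

  expect_error(spacer_to_crrna("ACGTACGTACGTACGTACGT", "ref"), "length")
  expect_error(spacer_to_crrna(paste(rep("X", 21), collapse = ""), "ref"),
               "non-DNA")
  allA <- strrep("A", 21)
  expect_identical(spacer_to_crrna(allA, "alt")$spacer_rna, allA)
})

test_that("homopair mismatches cover every seed position except the SNV", {
  hit <- toy_hit()                                    # seed_pos 3
  designs <- enumerate_synthetic_mismatches(hit, "alt", "homopair")
  expect_identical(nrow(designs), 4L)                 # seed_size - 1
  expect_setequal(designs$sm_pos, c(1L, 2L, 4L, 5L))
  expect_false(any(designs$sm_pos == hit$seed_pos))
  expect_false(any(designs$wobble))                   # homopairs never wobble

  base <- spacer_to_crrna(hit$spacer_alt, "alt")$spacer_rna
  for (i in seq_len(nrow(designs))) {
    d <- designs[i, ]
    diffs <- which(strsplit(d$spacer_rna, "")[[1]] != strsplit(base, "")[[1]])
    expect_identical(diffs, d$sm_pos)                 # exactly one change
    # homopair rule: crRNA base = RNA(target-strand base) = RNA complement
    proto <- substr(hit$spacer_alt, d$sm_pos, d$sm_pos)
    expect_identical(d$sm_base,
                     chartr("T", "U", ref_complement(proto)))
  }

  # spacer with C at position 1 -> sm_base G (G.G); A -> U (U.T)
  h2 <- toy_hit()
  h2$spacer_alt <- "CAGTCGATCGATCGATCGATC"
  d2 <- enumerate_synthetic_mismatches(h2, "alt", "homopair")
  expect_identical(d2$sm_base[d2$sm_pos == 1L], "G")
  expect_identical(d2$sm_base[d2$sm_pos == 2L], "U")

  expect_error(enumerate_synthetic_mismatches(hit, "alt",
                                              config = scan_config(seed_size = 1)),
               "no legal")
})

test_that("mode='all' emits every mismatching base and flags wobble pairs", {
  hit <- toy_hit()
  designs <- enumerate_synthetic_mismatches(hit, "alt", "all")
  expect_identical(nrow(designs), 12L)                # 4 positions x 3 bases
  # wobble iff crRNA G over target T (protospacer A) or U over target G (C)
  for (i in seq_len(nrow(designs))) {
    d <- designs[i, ]
    proto <- substr(hit$spacer_alt, d$sm_pos, d$sm_pos)
    expect_identical(d$wobble,
                     (d$sm_base == "G" && proto == "A") ||
                     (d$sm_base == "U" && proto == "C"))
  }
})

test_that("homopair rule holds on random hits (property)", {
  for (i in 1:20) {
    cs <- random_scan_case(1500, 40, seed = 400 + i)
    hits <- artemis_scan(cs$genome, cs$variants)
    if (nrow(hits) == 0) next
    h <- hits[1, ]
    for (allele in c("ref", "alt")) {
      spacer <- if (allele == "alt") h$spacer_alt else h$spacer_ref
      ds <- enumerate_synthetic_mismatches(h, allele, "homopair")
      expect_identical(nrow(ds), 4L)
      for (j in seq_len(nrow(ds))) {
        proto <- substr(spacer, ds$sm_pos[j], ds$sm_pos[j])
        expect_identical(ds$sm_base[j], chartr("T", "U", ref_complement(proto)))
      }
    }
  }
})

test_that("oligo targets assemble [flank]-[PAM]-[protospacer]-[flank] duplexes", {
  gm <- toy_genome(paste0(strrep("A", 14), TOY_SEQ, strrep("C", 14)))
  v <- make_variants("chr_toy", 9L + 14L, "A", "G")
  hit <- artemis_scan(gm, v)[1, ]
  oligos <- design_oligo_targets(gm, hit, flank = 15)
  expect_identical(nrow(oligos), 2L)
  expect_identical(unique(nchar(oligos$top_strand)), 55L)   # 15+4+21+15
  expect_identical(oligos$bottom_strand, vapply(oligos$top_strand, revcomp,
                                                "", USE.NAMES = FALSE))
  cmp <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                oligos$top_strand[1], oligos$top_strand[2])
  expect_identical(unname(cmp), 1L)                          # ref/alt distance 1
  # layout: PAM at flank+1..flank+4, protospacer right after
  expect_identical(substr(oligos$top_strand[1], 16, 19), hit$motif)
  expect_identical(substr(oligos$top_strand[1], 20, 40), hit$spacer_ref)
  expect_identical(substr(oligos$top_strand[2], 20, 40), hit$spacer_alt)

  expect_error(design_oligo_targets(gm, hit, flank = 3), "minimum")
  expect_error(design_oligo_targets(toy_genome(), artemis_scan(
    toy_genome(), toy_variant())[1, ], flank = 15), "leaves the contig")
})

test_that("reverse-strand oligos are laid out on the PAM-containing strand", {
  fwd_gm <- toy_genome(paste0(strrep("A", 14), TOY_SEQ, strrep("C", 14)))
  rc_gm <- toy_genome(revcomp(fwd_gm[[1]]))
  n <- nchar(fwd_gm[[1]])
  v_f <- make_variants("chr_toy", 23L, "A", "G")
  v_r <- make_variants("chr_toy", n - 23L + 1L, "T", "C")
  h_f <- artemis_scan(fwd_gm, v_f)[1, ]
  h_r <- artemis_scan(rc_gm, v_r)[1, ]
  expect_identical(h_r$strand, "-")
  o_f <- design_oligo_targets(fwd_gm, h_f)
  o_r <- design_oligo_targets(rc_gm, h_r)
  expect_identical(o_r$top_strand, o_f$top_strand)   # same PAM-strand layout
})

test_that("validate_primer_pair enforces overlap, bounds and containment", {
  set.seed(5)
  template <- paste0(random_dna(40), "TTTA", random_dna(21), random_dna(40))
  target <- c(40L, 40L + 4L + 21L)                   # PAM + protospacer
  fwd <- substr(template, 11, 30)
  rev <- revcomp(substr(template, 76, 95))
  chk <- validate_primer_pair(template, target, fwd, rev)
  expect_true(chk$pass)
  expect_identical(chk$amplicon_length, 85L)
  expect_false(chk$overlaps_target)
  expect_true(chk$within_bounds)

  # forward primer ending 2 nt inside the protospacer -> overlap failure
  fwd_bad <- substr(template, 27, 46)
  chk2 <- validate_primer_pair(template, target, fwd_bad, rev)
  expect_false(chk2$pass)
  expect_true(chk2$overlaps_target)

  # amplicon longer than the 120-bp default upper bound
  template3 <- paste0(random_dna(60), "TTTA", random_dna(21), random_dna(60))
  target3 <- c(60L, 85L)
  chk3 <- validate_primer_pair(template3, target3,
                               substr(template3, 1, 20),
                               revcomp(substr(template3, 126, 145)))
  expect_identical(chk3$amplicon_length, 145L)
  expect_false(chk3$within_bounds)
  expect_false(chk3$pass)

  expect_error(validate_primer_pair(template, target, "GGGGGGGGGG", rev),
               "not found")
  tdup <- paste0(template, substr(template, 11, 30))
  expect_error(validate_primer_pair(tdup, target, fwd, rev), "ambiguous")
})

test_that("primer validation is orientation-symmetric", {
  set.seed(6)
  template <- paste0(random_dna(40), "TTTA", random_dna(21), random_dna(40))
  target <- c(40L, 65L)
  fwd <- substr(template, 11, 30)
  rev <- revcomp(substr(template, 76, 95))
  a <- validate_primer_pair(template, target, fwd, rev)
  n <- nchar(template)
  b <- validate_primer_pair(revcomp(template), c(n - target[2], n - target[1]),
                            rev, fwd)
  expect_identical(a$amplicon_length, b$amplicon_length)
  expect_identical(a$pass, b$pass)
})
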