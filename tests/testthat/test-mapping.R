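set.seed(41)
ref <- setNames(random_dna(20000, 0.6), "chrT")
ref_idx <- ref_word_index(ref)

plant <- function(len = 37, at = 5000) substr(ref, at + 1, at + len)

test_that("a perfectly planted spacer maps with full identity", {
  sp <- plant(37, 5000)
  hits <- align_spacer(sp, ref, index = ref_idx)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 5000)
  expect_equal(hits$end, 5037)
  expect_equal(hits$strand, "+")
  expect_equal(hits$percent_identity, 100)
  expect_equal(hits$n_mismatches, 0)
  expect_equal(hits$raw_score, 37)
  expect_error(align_spacer(sp, character(0)))
})

test_that("substitutions shift identity as expected for a 37-mer", {
  sp1 <- plant(37, 7000)
  substr(sp1, 15, 15) <- chartr("ACGT", "GTAC", substr(sp1, 15, 15))
  h1 <- filter_hits(align_spacer(sp1, ref, index = ref_idx), 37)
  h1 <- h1[h1$start == 7000, ]
  expect_equal(h1$n_mismatches, 1)
  expect_equal(h1$percent_identity, 100 * 36 / 37, tolerance = 1e-9)
  expect_equal(h1$status, "pass")   # 97.30% > 95%

  # 2 substitutions placed away from the ends: identity 35/37 fails > 95%
  sp2 <- plant(37, 9000)
  substr(sp2, 10, 10) <- chartr("ACGT", "GTAC", substr(sp2, 10, 10))
  substr(sp2, 20, 20) <- chartr("ACGT", "GTAC", substr(sp2, 20, 20))
  h2 <- filter_hits(align_spacer(sp2, ref, index = ref_idx), 37)
  full <- h2[h2$alignment_length == 37, ]
  if (nrow(full)) {
    expect_equal(full$percent_identity, 100 * 35 / 37, tolerance = 1e-9)
    expect_equal(full$status, "filtered_out")
  }
  res2 <- resolve_best(h2)
  expect_equal(res2$status, "unmapped")
})

test_that("filter_hits enforces all four strict criteria", {
  mk <- function(alen, nmis, ident) data.frame(
    replicon = "chrT", start = 0, end = alen, strand = "+",
    alignment_length = alen, n_mismatches = nmis, n_gaps = 0,
    percent_identity = ident, raw_score = alen - 4 * nmis)
  # 33/37 = 0.892 fails the >0.9 span ratio
  expect_equal(filter_hits(mk(33, 0, 100), 37)$status, "filtered_out")
  # 35/37 = 0.946 passes ratio and |35-37| = 2 < 3 passes
  expect_equal(filter_hits(mk(35, 0, 100), 37)$status, "pass")
  # boundary: identity exactly 95 fails (strict)
  expect_equal(filter_hits(mk(37, 0, 95), 37)$status, "filtered_out")
  # mismatches exactly 4 fails (strict <4)
  expect_equal(filter_hits(mk(37, 4, 96), 37)$status, "filtered_out")
  expect_equal(filter_hits(mk(37, 3, 96), 37)$status, "pass")
})

test_that("resolve_best keeps the top score and flags ties", {
  h <- data.frame(replicon = "chrT", start = c(100, 700), end = c(137, 737),
                  strand = "+", alignment_length = 37,
                  n_mismatches = c(0, 2), n_gaps = 0,
                  percent_identity = c(100, 94.6),
                  raw_score = c(37, 29), status = "pass")
  r <- resolve_best(h)
  expect_equal(r$status, "best")
  expect_equal(r$hit$start, 100)
  h$raw_score <- c(37, 37)
  expect_equal(resolve_best(h)$status, "ambiguous_tie")
  h$status <- "filtered_out"
  expect_equal(resolve_best(h)$status, "unmapped")
})

test_that("a spacer planted at two identical loci is an ambiguous tie", {
  dupref <- ref
  seg <- substr(ref, 3001, 3037)
  # copy the segment to a second locus
  substr(dupref, 15001, 15037) <- seg
  mp <- map_spacers(setNames(seg, "s1"), dupref)
  expect_equal(mp$status, "ambiguous_tie")
})

test_that("PAM extraction reads the protospacer strand", {
  # plant TTC upstream on + strand
  r2 <- setNames(paste0(random_dna(60, 0.6), "TTC",
                        random_dna(37, 0.6), random_dna(60, 0.6)), "mini")
  # replicons must be >= word length of the mapper only; extract directly
  hit <- data.frame(replicon = "mini", start = 63, end = 100, strand = "+")
  expect_equal(extract_pam(hit, r2), unname(substr(r2, 61, 63)))
  expect_equal(extract_pam(hit, r2), "TTC")
  # the same protospacer interval on the minus strand reads the other flank
  hitm <- data.frame(replicon = "mini", start = 63, end = 100, strand = "-")
  expect_equal(extract_pam(hitm, r2),
               revcomp(unname(substr(r2, 101, 103))))
  # off the end -> NA
  edge <- data.frame(replicon = "mini", start = 1, end = 38, strand = "+")
  expect_true(is.na(extract_pam(edge, r2)))
  edge_m <- data.frame(replicon = "mini", start = 123, end = 160,
                       strand = "-")
  expect_true(is.na(extract_pam(edge_m, r2)))
  bad <- data.frame(replicon = "mini", start = -1, end = 36, strand = "+")
  expect_error(extract_pam(bad, r2))
})

test_that("mapping is reverse-complement invariant; PAM follows the locus strand", {
  fx <- assay_fixture(seed = 42, n_reads = 200, acquisition_rate = 0.3,
                      error_rate = 0)
  tr <- fx$truth$acquisitions[1:10, ]
  for (i in seq_len(nrow(tr))) {
    m1 <- map_spacers(setNames(tr$spacer_sequence[i], "f"),
                      fx$genome$replicons)
    m2 <- map_spacers(setNames(revcomp(tr$spacer_sequence[i]), "r"),
                      fx$genome$replicons)
    expect_equal(m1$status, "best")
    expect_equal(m2$status, "best")
    expect_equal(m1$start, m2$start)
    expect_equal(m1$end, m2$end)
    expect_false(m1$strand == m2$strand)
    # the spacer was planted in protospacer-strand orientation, so its own
    # mapping reports the planted PAM directly
    expect_equal(m1$strand, tr$source_strand[i])
    expect_identical(m1$pam, "TTC")
    # PAM is a function of (locus, strand): re-reading the flipped hit on
    # the planted strand recovers the same motif
    h2 <- data.frame(replicon = m2$replicon, start = m2$start, end = m2$end,
                     strand = tr$source_strand[i])
    expect_identical(extract_pam(h2, fx$genome$replicons), "TTC")
  }
})

test_that("seed-and-extend agrees with the brute-force scan oracle", {
  set.seed(43)
  oref <- setNames(random_dna(20000, 0.6), "chrO")
  oidx <- ref_word_index(oref)
  for (i in 1:25) {
    len <- sample(34:40, 1)
    at <- sample(1000:18000, 1)
    nmut <- sample(0:3, 1)
    sp <- mutate_n(substr(oref, at + 1, at + len), nmut, seed = i)
    if (i %% 2 == 0) sp <- revcomp(sp)
    impl <- map_spacers(setNames(sp, "q"), oref, word_size = 7)
    oracle <- brute_force_best(sp, oref)
    expect_equal(impl$status, oracle$status, info = paste("case", i))
    if (impl$status == "best") {
      expect_equal(impl$start, oracle$hit$start, info = paste("case", i))
      expect_equal(impl$end, oracle$hit$end, info = paste("case", i))
      expect_equal(impl$strand, oracle$hit$strand, info = paste("case", i))
      expect_equal(impl$n_mismatches, oracle$hit$n_mismatches)
      expect_equal(impl$percent_identity, oracle$hit$percent_identity,
                   tolerance = 1e-9)
    }
  }
})

test_that("pam_summary counts motifs with reference background", {
  hits <- data.frame(status = c("best", "best", "best", "unmapped"),
                     pam = c("TTC", "TTC", "GGA", NA))
  ps <- pam_summary(hits, ref)
  expect_equal(ps$top_motif, "TTC")
  expect_equal(ps$top_fraction, 2 / 3)
  expect_equal(sum(ps$counts), 3)
  expect_equal(sum(ps$background), 1, tolerance = 1e-9)
  expect_warning(pam_summary(data.frame(status = "unmapped",
                                        pam = NA_character_)))
})

test_that("locus distribution bins conserve counts and find the top locus", {
  hits <- data.frame(status = "best", replicon = "chrT",
                     start = c(1200, 1300, 1800, 9000),
                     end = c(1237, 1337, 1837, 9037))
  ld <- locus_distribution(hits, ref, bin_size = 1000)
  expect_equal(sum(ld$bins$count), 4)
  expect_equal(ld$top_locus$replicon, "chrT")
  expect_equal(ld$top_locus$start, 1000)
  expect_equal(ld$top_locus$fraction, 0.75)
})
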