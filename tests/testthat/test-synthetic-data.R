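test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(gc_fraction = 1.5))
  expect_error(sim_config(acquisition_rate = -0.1))
  expect_error(sim_config(genome_lengths = 0))
  expect_error(sim_config(duplication_mutation_distribution = c("0" = 0.5)))
  expect_error(sim_config(duplication_mutation_distribution =
                            setNames(0.5, NULL)))
})

test_that("gen_genome constructs replicons with the planted element recorded", {
  cfg <- sim_config(seed = 1, genome_lengths = 50000, element_length = 5000,
                    element_mode = "integrated")
  g <- gen_genome(cfg)
  expect_equal(nchar(g$replicons[["chr1"]]), 55000)
  el <- g$truth$element
  expect_true(el$start >= 0 && el$end <= nchar(g$replicons[[el$replicon]]))
  expect_equal(el$end - el$start, 5000)
  expect_null(g$element_seq)
  expect_error(gen_genome(sim_config(genome_lengths = 5000)))
})

test_that("gen_genome is byte-identical for a fixed seed", {
  cfg <- sim_config(seed = 42)
  expect_identical(gen_genome(cfg), gen_genome(cfg))
})

test_that("element_mode both emits an embedded copy and the circular sequence", {
  cfg <- sim_config(seed = 3, element_mode = "both", element_length = 5000)
  g <- gen_genome(cfg)
  el <- g$truth$element
  expect_equal(el$replicon, "chr1")
  embedded <- substr(g$replicons[["chr1"]], el$start + 1, el$end)
  expect_identical(embedded, g$element_seq)
  # circular-only mode: standalone replicon instead
  g2 <- gen_genome(sim_config(seed = 3, element_mode = "circular",
                              element_length = 5000))
  expect_true("element_circular" %in% names(g2$replicons))
  expect_equal(g2$truth$element$replicon, "element_circular")
})

test_that("gen_array builds a leader-proximal-first array", {
  a <- gen_array(seed = 5, n_spacers = 3, repeat_length = 30,
                 spacer_length_range = c(37, 37), leader_length = 60)
  expect_length(a$spacers, 3)
  expect_true(all(nchar(a$spacers) == 37))
  expect_equal(nchar(a$repeat_seq), 30)
  expect_false(anyDuplicated(a$spacers) > 0)
  # baseline amplicon = leader + (R + S) x 3
  expect_identical(amplicon_baseline(a),
                   paste0(a$leader, a$repeat_seq, a$spacers[1],
                          a$repeat_seq, a$spacers[2],
                          a$repeat_seq, a$spacers[3]))
  expect_error(gen_array(seed = 1, n_spacers = 2))
  expect_warning(gen_array(seed = 1, spacer_length_range = c(50, 55)))
})

test_that("arrays from different seeds have disjoint spacer sets", {
  a <- gen_array(seed = 1, n_spacers = 20)
  b <- gen_array(seed = 2, n_spacers = 20)
  expect_length(intersect(a$spacers, b$spacers), 0)
})

test_that("acquisition_rate 0 yields only baseline reads", {
  fx <- assay_fixture(seed = 9, n_reads = 50, acquisition_rate = 0,
                      duplication_rate = 0)
  base_f <- amplicon_baseline(fx$array)
  expect_true(all(fx$reads %in% c(base_f, revcomp(base_f))))
  expect_equal(nrow(fx$truth$acquisitions), 0)
  expect_equal(nrow(fx$truth$duplications), 0)
})

test_that("truth records exactly cover the non-baseline reads", {
  fx <- assay_fixture(seed = 10, n_reads = 400, acquisition_rate = 0.05,
                      duplication_rate = 0.1, offtarget_rate = 0.02)
  base_f <- amplicon_baseline(fx$array)
  n_nonbase <- sum(!(fx$reads %in% c(base_f, revcomp(base_f))))
  n_truth <- nrow(fx$truth$acquisitions) + nrow(fx$truth$duplications) +
    nrow(fx$truth$offtargets)
  expect_equal(n_nonbase, n_truth)
})

test_that("planted PAM invariant holds for every acquisition record", {
  fx <- assay_fixture(seed = 11, n_reads = 400, acquisition_rate = 0.2)
  tr <- fx$truth$acquisitions
  expect_gt(nrow(tr), 0)
  for (i in seq_len(nrow(tr))) {
    seq <- fx$genome$replicons[[tr$source_replicon[i]]]
    if (tr$source_strand[i] == "+") {
      pam <- substr(seq, tr$source_start[i] - 2, tr$source_start[i])
      proto <- substr(seq, tr$source_start[i] + 1, tr$source_end[i])
    } else {
      pam <- revcomp(substr(seq, tr$source_end[i] + 1, tr$source_end[i] + 3))
      proto <- revcomp(substr(seq, tr$source_start[i] + 1, tr$source_end[i]))
    }
    expect_identical(pam, fx$cfg$pam_motif)
    expect_identical(proto, tr$spacer_sequence[i])
  }
})

test_that("amplicon simulation is deterministic given config", {
  cfg <- sim_config(seed = 12, n_amplicon_reads = 100,
                    acquisition_rate = 0.1)
  g <- gen_genome(cfg)
  a <- gen_array(seed = 12)
  s1 <- simulate_acquisition_reads(a, g, cfg)
  s2 <- simulate_acquisition_reads(a, g, cfg)
  expect_identical(s1, s2)
})

test_that("wgs depth is uniform at copy number 1 and enriched at 20", {
  cfg <- sim_config(seed = 13, genome_lengths = 30000, element_length = 5000,
                    element_copy_number = 1, element_mode = "integrated",
                    wgs_depth = 30, per_base_error_rate = 0)
  g <- gen_genome(cfg)
  reads <- simulate_wgs(g, cfg)
  al <- map_reads(reads, g$replicons)
  prof <- depth_profile(al, g$replicons)
  inner <- prof[prof$start >= 1000 & prof$end <= 34000, ]
  expect_true(all(abs(inner$enrichment - 1) < 0.35))

  cfg20 <- sim_config(seed = 13, genome_lengths = 30000,
                      element_length = 5000, element_copy_number = 20,
                      element_mode = "integrated", wgs_depth = 30,
                      per_base_error_rate = 0)
  g20 <- gen_genome(cfg20)
  r20 <- simulate_wgs(g20, cfg20)
  al20 <- map_reads(r20, g20$replicons)
  p20 <- depth_profile(al20, g20$replicons)
  el <- g20$truth$element
  interior <- p20[p20$start >= el$start + 500 & p20$end <= el$end - 500, ]
  expect_gt(nrow(interior), 0)
  # binomial sampling error on a 500 bp window at ~600x is ~ +/-2.3 (3 SE)
  expect_true(abs(median(interior$enrichment) - 20) < 2)
})

test_that("circular mode emits junction-spanning reads", {
  cfg <- sim_config(seed = 14, genome_lengths = 20000, element_length = 5000,
                    element_copy_number = 5, element_mode = "circular",
                    wgs_depth = 20, per_base_error_rate = 0)
  g <- gen_genome(cfg)
  reads <- simulate_wgs(g, cfg)
  junction <- paste0(substr(g$element_seq, 4986, 5000),
                     substr(g$element_seq, 1, 15))
  n_j <- sum(Biostrings::vcountPattern(
    junction, Biostrings::DNAStringSet(unname(reads)))) +
    sum(Biostrings::vcountPattern(
      junction,
      Biostrings::reverseComplement(Biostrings::DNAStringSet(unname(reads)))))
  expect_gte(n_j, 1)
  expect_error(simulate_wgs(g, sim_config(seed = 14, read_length = 30000)))
})

test_that("simulate_counts inverts the RPKM formula", {
  counts <- simulate_counts(c(100, 0, 17.19), c(1000, 900, 2000), 1e6)
  expect_equal(counts, c(100L, 0L, 34L))
  expect_equal(rpkm(counts[1], 1000, 1e6), 100)
})
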