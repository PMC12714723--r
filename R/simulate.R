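#' Simulation configuration for the synthetic study design
#'
#' Bundles every knob of the synthetic-data generator: host replicons, a
#' multi-copy mobile element in circular and/or integrated form, a CRISPR
#' adaptation amplicon assay, and whole-genome sequencing. Defaults encode the
#' study conditions the downstream analyses assume: a GC-rich haloarchaeal
#' host, a 10 kb element at 20-fold copy number present both integrated and as
#' a circular replicative form, leader-proximal amplicons with three baseline
#' repeats, rare genuine acquisitions next to a 5'-TTC PAM, more frequent
#' duplications of existing spacers of which a few percent carry multiple
#' mutations, and post-quality-filter substitution errors.
#'
#' @param seed integer seed driving all randomness of the generator.
#' @param genome_lengths integer vector of host replicon lengths (bp), each
#'   >= 10 kb.
#' @param gc_fraction genome GC content in \[0, 1\].
#' @param element_length mobile element length (bp).
#' @param element_copy_number element copy number relative to the host
#'   chromosome (fold, >= 1).
#' @param element_mode one of `"circular"`, `"integrated"`, `"both"`.
#' @param n_amplicon_reads number of amplicon reads to simulate.
#' @param acquisition_rate fraction of amplicon reads carrying a newly
#'   acquired, genome-sourced spacer.
#' @param duplication_rate fraction of amplicon reads carrying a duplicated
#'   copy of an existing spacer.
#' @param offtarget_rate fraction of amplicon reads carrying a novel spacer
#'   with no genomic source (exercises unmapped-spacer handling).
#' @param duplication_mutation_distribution named numeric vector mapping
#'   mutation count to probability for duplicated spacers; must sum to 1.
#' @param pam_motif trinucleotide immediately 5' of every planted protospacer,
#'   on the protospacer strand.
#' @param per_base_error_rate substitution error rate applied to read bases.
#' @param read_length WGS read length (bp).
#' @param wgs_depth baseline WGS depth over the host replicons (fold).
#' @param spacer_length_range integer length-2 vector; planted acquisition
#'   spacer lengths are drawn uniformly from this range.
#' @param acquisition_source `"genome"` to source new spacers anywhere in the
#'   host replicons, `"element"` to source them only from the planted element
#'   interval (the locus-skew scenario).
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       genome_lengths = 50000L,
                       gc_fraction = 0.6,
                       element_length = 10000L,
                       element_copy_number = 20,
                       element_mode = c("both", "circular", "integrated"),
                       n_amplicon_reads = 2000L,
                       acquisition_rate = 0.005,
                       duplication_rate = 0.10,
                       offtarget_rate = 0,
                       duplication_mutation_distribution =
                         c("0" = 0.90, "1" = 0.04, "2" = 0.03, "3" = 0.03),
                       pam_motif = "TTC",
                       per_base_error_rate = 0.001,
                       read_length = 100L,
                       wgs_depth = 30,
                       spacer_length_range = c(34L, 40L),
                       acquisition_source = c("genome", "element")) {
  element_mode <- match.arg(element_mode)
  acquisition_source <- match.arg(acquisition_source)
  stopifnot(
    length(seed) == 1, is.finite(seed),
    all(genome_lengths > 0),
    gc_fraction >= 0, gc_fraction <= 1,
    element_length > 0,
    element_copy_number >= 1,
    n_amplicon_reads >= 0,
    acquisition_rate >= 0, acquisition_rate <= 1,
    duplication_rate >= 0, duplication_rate <= 1,
    offtarget_rate >= 0, offtarget_rate <= 1,
    acquisition_rate + duplication_rate + offtarget_rate <= 1,
    per_base_error_rate >= 0, per_base_error_rate <= 1,
    read_length > 0, wgs_depth >= 0,
    length(spacer_length_range) == 2,
    spacer_length_range[1] <= spacer_length_range[2]
  )
  p <- duplication_mutation_distribution
  if (is.null(names(p)) || any(is.na(suppressWarnings(as.integer(names(p))))))
    stop("duplication_mutation_distribution must be named by mutation count")
  if (abs(sum(p) - 1) > 1e-8)
    stop("duplication_mutation_distribution probabilities must sum to 1")
  structure(list(
    seed = as.integer(seed),
    genome_lengths = as.integer(genome_lengths),
    gc_fraction = gc_fraction,
    element_length = as.integer(element_length),
    element_copy_number = element_copy_number,
    element_mode = element_mode,
    n_amplicon_reads = as.integer(n_amplicon_reads),
    acquisition_rate = acquisition_rate,
    duplication_rate = duplication_rate,
    offtarget_rate = offtarget_rate,
    duplication_mutation_distribution = p,
    pam_motif = toupper(pam_motif),
    per_base_error_rate = per_base_error_rate,
    read_length = as.integer(read_length),
    wgs_depth = wgs_depth,
    spacer_length_range = as.integer(spacer_length_range),
    acquisition_source = acquisition_source
  ), class = "sim_config")
}

#' Generate host replicons with a planted multi-copy element
#'
#' Host replicons are i.i.d. base sequences at the configured GC content. The
#' mobile element is a separate random sequence; depending on
#' `cfg$element_mode` it is embedded at a recorded locus inside the first
#' replicon (`"integrated"`, `"both"`) and/or emitted as a standalone circular
#' replicon (`"circular"`) or standalone sequence (`"both"`, field
#' `element_seq`, so that circular-form reads map onto the embedded copy
#' rather than being dropped as multi-mapping). All coordinates in the ground
#' truth are 0-based half-open.
#'
#' @param cfg a [sim_config()] object.
#' @return list with `replicons` (named character vector; the mapping
#'   reference), `element_seq` (the circular-form sequence, or `NULL`), and
#'   `truth` — a list whose `element` entry records
#'   `(replicon, start, end, copy_number, mode)`.
#' @export
gen_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(cfg$genome_lengths < 10000))
    stop("replicon lengths must be >= 10 kb")
  set.seed(cfg$seed)
  reps <- vapply(cfg$genome_lengths, random_dna, character(1),
                 gc = cfg$gc_fraction)
  names(reps) <- sprintf("chr%d", seq_along(reps))
  elem <- random_dna(cfg$element_length, cfg$gc_fraction)
  mode <- cfg$element_mode
  if (mode %in% c("integrated", "both")) {
    L <- nchar(reps[1])
    # keep the element away from replicon ends so both flanks exist
    margin <- max(2000L, cfg$read_length * 4L)
    s0 <- sample.int(L - cfg$element_length - 2L * margin, 1) + margin  # 0-based
    reps[1] <- paste0(substr(reps[1], 1, s0),
                      elem,
                      substr(reps[1], s0 + 1, L))
    truth_elem <- list(replicon = names(reps)[1], start = s0,
                       end = s0 + cfg$element_length,
                       copy_number = cfg$element_copy_number, mode = mode)
  } else {
    reps <- c(reps, element_circular = elem)
    truth_elem <- list(replicon = "element_circular", start = 0L,
                       end = cfg$element_length,
                       copy_number = cfg$element_copy_number, mode = mode)
  }
  list(replicons = reps,
       element_seq = if (mode %in% c("circular", "both")) elem else NULL,
       truth = list(element = truth_elem))
}

#' Generate a CRISPR array (leader, repeat, ordered spacers)
#'
#' Spacers are ordered leader-proximal first (index 1 = most recently
#' acquired). The leader is AT-rich, as is typical of adaptation leaders. The
#' amplicon assayed downstream spans the leader through the third spacer, so
#' the baseline amplicon carries three repeats.
#'
#' @param seed integer seed.
#' @param n_spacers number of spacers (>= 3; the amplicon primers span the
#'   leader to the third spacer).
#' @param repeat_length repeat length in bp.
#' @param spacer_length_range length-2 integer vector of spacer lengths,
#'   sampled uniformly. Lengths outside \[10, 45\] trigger a warning because
#'   such spacers are excluded by the downstream length filter.
#' @param leader_length leader length in bp.
#' @param array_id identifier for the array.
#' @param gc GC fraction for repeat and spacers.
#' @return an object of class `crispr_array`: list with `array_id`, `leader`,
#'   `repeat_seq`, `spacers` (character vector), `baseline_repeats` (3).
#' @export
gen_array <- function(seed, n_spacers = 10L, repeat_length = 30L,
                      spacer_length_range = c(37L, 37L), leader_length = 60L,
                      array_id = "arrayA", gc = 0.6) {
  if (n_spacers < 3)
    stop("n_spacers must be >= 3: the amplicon spans the leader to the third spacer")
  if (spacer_length_range[1] < 10 || spacer_length_range[2] > 45)
    warning("spacer lengths outside [10, 45] bp would be excluded by the length filter")
  set.seed(seed)
  leader <- random_dna(leader_length, gc = 0.3)
  repeat_seq <- random_dna(repeat_length, gc = gc)
  spacers <- character(0)
  while (length(spacers) < n_spacers) {
    len <- sample1(seq(spacer_length_range[1], spacer_length_range[2]))
    sp <- random_dna(len, gc = gc)
    if (!(sp %in% spacers)) spacers <- c(spacers, sp)
  }
  structure(list(array_id = array_id, leader = leader,
                 repeat_seq = repeat_seq, spacers = spacers,
                 baseline_repeats = 3L),
            class = "crispr_array")
}

#' Baseline (no-acquisition) amplicon sequence of an array
#'
#' `leader + R + S1 + R + S2 + R + S3`: the region between the leader and the
#' third spacer that the assay primers amplify.
#'
#' @param array a [gen_array()] object.
#' @return a single DNA string.
#' @export
amplicon_baseline <- function(array) {
  stopifnot(inherits(array, "crispr_array"))
  b <- array$baseline_repeats
  paste0(array$leader,
         paste0(vapply(seq_len(b), function(i)
           paste0(array$repeat_seq, array$spacers[i]), character(1)),
           collapse = ""))
}

# All candidate protospacer placements whose 5'-adjacent trinucleotide on the
# protospacer strand equals the PAM. Returns a data.frame with 0-based
# half-open coords. For "+" the PAM lies at [start-3, start); for "-" the
# protospacer sequence is the reverse complement of the slice and the PAM is
# the reverse complement of [end, end+3).
pam_anchored_sites <- function(replicons, pam, spacer_len, region = NULL) {
  out <- list()
  rc_pam <- revcomp(pam)
  for (rn in names(replicons)) {
    seq <- replicons[[rn]]
    L <- nchar(seq)
    subj <- Biostrings::DNAString(seq)
    # + strand: PAM occurrence at 0-based p means protospacer start p+3
    plus <- Biostrings::start(Biostrings::matchPattern(pam, subj)) - 1L
    s_plus <- plus + 3L
    keep <- s_plus + spacer_len <= L
    # - strand: need rc(pam) at [end, end+3)
    minus <- Biostrings::start(Biostrings::matchPattern(rc_pam, subj)) - 1L
    e_minus <- minus
    keep_m <- e_minus - spacer_len >= 0
    df <- rbind(
      if (any(keep)) data.frame(replicon = rn, start = s_plus[keep],
                                end = s_plus[keep] + spacer_len,
                                strand = "+", stringsAsFactors = FALSE),
      if (any(keep_m)) data.frame(replicon = rn,
                                  start = e_minus[keep_m] - spacer_len,
                                  end = e_minus[keep_m],
                                  strand = "-", stringsAsFactors = FALSE)
    )
    out[[rn]] <- df
  }
  sites <- do.call(rbind, out)
  if (!is.null(region) && !is.null(sites)) {
    sites <- sites[sites$replicon == region$replicon &
                     sites$start >= region$start &
                     sites$end <= region$end, , drop = FALSE]
  }
  sites
}

#' Simulate merged amplicon reads from a spacer-acquisition assay
#'
#' Each read is the baseline amplicon or carries one extra spacer+repeat unit
#' at the leader end: either a genome-sourced new spacer whose 5'-adjacent
#' trinucleotide equals the PAM motif (acquisition), a mutated copy of an
#' existing spacer (duplication), or a sourceless novel spacer (off-target).
#' Half the reads are emitted reverse-complemented; substitution errors are
#' applied at `cfg$per_base_error_rate`. Quality strings are a constant Q30
#' placeholder (quality filtering is modelled as already applied upstream).
#'
#' @param array a [gen_array()] object.
#' @param genome a [gen_genome()] result.
#' @param cfg a [sim_config()] object.
#' @return list with `reads` (named character vector) and `truth`: data frames
#'   `acquisitions` (read_id, spacer_sequence, source_replicon, source_start,
#'   source_end, source_strand, pam), `duplications` (read_id, source_array,
#'   source_index, n_mutations, spacer_sequence) and `offtargets` (read_id,
#'   spacer_sequence). Coordinates 0-based half-open.
#' @export
simulate_acquisition_reads <- function(array, genome, cfg) {
  stopifnot(inherits(array, "crispr_array"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_amplicon_reads
  baseline <- amplicon_baseline(array)
  probs <- c(none = 1 - cfg$acquisition_rate - cfg$duplication_rate -
               cfg$offtarget_rate,
             acquisition = cfg$acquisition_rate,
             duplication = cfg$duplication_rate,
             offtarget = cfg$offtarget_rate)
  events <- sample(names(probs), n, replace = TRUE, prob = probs)
  region <- if (cfg$acquisition_source == "element")
    genome$truth$element else NULL

  sites_by_len <- list()
  lens <- seq(cfg$spacer_length_range[1], cfg$spacer_length_range[2])
  if (any(events == "acquisition")) {
    for (len in lens) {
      s <- pam_anchored_sites(as.list(genome$replicons), cfg$pam_motif, len,
                              region = region)
      if (is.null(s) || nrow(s) == 0)
        stop("no PAM-anchored protospacer window of length ", len,
             " in the reference")
      sites_by_len[[as.character(len)]] <- s
    }
  }

  mut_counts <- as.integer(names(cfg$duplication_mutation_distribution))
  mut_probs <- unname(cfg$duplication_mutation_distribution)
  ids <- sprintf("read_%06d", seq_len(n))
  reads <- rep(baseline, n)
  empty <- function(cols) stats::setNames(
    data.frame(matrix(nrow = 0, ncol = length(cols))), cols)

  # planted acquisitions (bulk by spacer length)
  ia <- which(events == "acquisition")
  acq <- empty(c("read_id", "spacer_sequence", "source_replicon",
                 "source_start", "source_end", "source_strand", "pam"))
  if (length(ia)) {
    len_draw <- sample1(lens, size = length(ia))
    rows <- do.call(rbind, lapply(seq_along(ia), function(j) {
      st <- sites_by_len[[as.character(len_draw[j])]]
      st[sample.int(nrow(st), 1), , drop = FALSE]
    }))
    slice <- substring(genome$replicons[rows$replicon],
                       rows$start + 1L, rows$end)
    minus <- rows$strand == "-"
    spacer <- slice
    if (any(minus)) spacer[minus] <- revcomp(slice[minus])
    acq <- data.frame(read_id = ids[ia], spacer_sequence = spacer,
                      source_replicon = rows$replicon,
                      source_start = rows$start, source_end = rows$end,
                      source_strand = rows$strand, pam = cfg$pam_motif,
                      stringsAsFactors = FALSE)
  }

  # planted duplications of existing spacers
  id_ <- which(events == "duplication")
  dup <- empty(c("read_id", "source_array", "source_index", "n_mutations",
                 "spacer_sequence"))
  if (length(id_)) {
    idx <- sample1(seq_along(array$spacers), size = length(id_))
    nm <- sample1(mut_counts, size = length(id_), prob = mut_probs)
    spacer <- vapply(seq_along(id_), function(j)
      mutate_substitutions(array$spacers[idx[j]], nm[j]), character(1))
    dup <- data.frame(read_id = ids[id_], source_array = array$array_id,
                      source_index = idx, n_mutations = nm,
                      spacer_sequence = spacer, stringsAsFactors = FALSE)
  }

  # off-target novel spacers with no genomic source
  io <- which(events == "offtarget")
  off <- empty(c("read_id", "spacer_sequence"))
  if (length(io)) {
    spacer <- vapply(sample1(lens, size = length(io)), random_dna,
                     character(1), gc = cfg$gc_fraction)
    off <- data.frame(read_id = ids[io], spacer_sequence = spacer,
                      stringsAsFactors = FALSE)
  }

  # new unit inserted at the leader end: leader + R + insert + R + S1 ...
  exp_i <- c(ia, id_, io)
  if (length(exp_i)) {
    inserts <- c(acq$spacer_sequence, dup$spacer_sequence,
                 off$spacer_sequence)
    reads[exp_i] <- paste0(array$leader, array$repeat_seq, inserts,
                           substr(baseline, nchar(array$leader) + 1,
                                  nchar(baseline)))
  }
  names(reads) <- ids
  reads <- apply_substitution_errors(reads, cfg$per_base_error_rate)
  flip <- runif(n) < 0.5
  if (any(flip)) reads[flip] <- revcomp(reads[flip])

  list(reads = reads,
       truth = list(acquisitions = acq, duplications = dup,
                    offtargets = off))
}

# Sample linear reads from a sequence: starts uniform on [0, L - rl].
sample_linear_reads <- function(seq, n, rl) {
  L <- nchar(seq)
  starts <- sample.int(L - rl + 1L, n, replace = TRUE) - 1L
  substring(seq, starts + 1L, starts + rl)
}

# Sample reads from a circular sequence: starts uniform over all positions,
# wrapping across the end -> start junction.
sample_circular_reads <- function(seq, n, rl) {
  L <- nchar(seq)
  doubled <- paste0(seq, substr(seq, 1, rl))
  starts <- sample.int(L, n, replace = TRUE) - 1L
  substring(doubled, starts + 1L, starts + rl)
}

#' Simulate whole-genome sequencing reads
#'
#' Host replicons are sampled uniformly at `cfg$wgs_depth`; the planted
#' element is oversampled to `element_copy_number` times that depth. Circular
#' mode draws the extra element reads from the circularized element, so reads
#' spanning the end-to-start junction are emitted; integrated mode draws them
#' across the embedded interval including the host-element edges. Half the
#' reads are reverse-complemented and substitution errors applied.
#'
#' @param genome a [gen_genome()] result.
#' @param cfg a [sim_config()] object.
#' @return named character vector of reads.
#' @export
simulate_wgs <- function(genome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  rl <- cfg$read_length
  el <- genome$truth$element
  mode <- el$mode
  host <- genome$replicons[setdiff(names(genome$replicons), "element_circular")]
  if (any(nchar(genome$replicons) < rl))
    stop("read_length exceeds a replicon length")
  reads <- character(0)
  for (rn in names(host)) {
    n <- round(cfg$wgs_depth * nchar(host[[rn]]) / rl)
    reads <- c(reads, sample_linear_reads(host[[rn]], n, rl))
  }
  extra_depth <- cfg$wgs_depth * (el$copy_number - 1)
  n_extra <- round(extra_depth * (el$end - el$start) / rl)
  if (mode == "circular") {
    # standalone circular replicon: total element depth = copy_number * depth
    n_circ <- round(cfg$wgs_depth * el$copy_number *
                      cfg$element_length / rl)
    reads <- c(reads, sample_circular_reads(genome$element_seq, n_circ, rl))
  } else if (mode == "integrated") {
    if (n_extra > 0) {
      chrom <- genome$replicons[[el$replicon]]
      lo <- max(0L, el$start - rl + 1L)
      hi <- min(nchar(chrom) - rl, el$end - 1L)
      starts <- lo + sample.int(hi - lo + 1L, n_extra, replace = TRUE) - 1L
      reads <- c(reads, substring(chrom, starts + 1L, starts + rl))
    }
  } else { # both: the replicative excess is the circular form
    if (n_extra > 0)
      reads <- c(reads, sample_circular_reads(genome$element_seq, n_extra, rl))
  }
  names(reads) <- sprintf("wgs_%07d", seq_along(reads))
  reads <- apply_substitution_errors(reads, cfg$per_base_error_rate)
  flip <- runif(length(reads)) < 0.5
  if (any(flip)) reads[flip] <- revcomp(reads[flip])
  reads
}

#' Per-gene counts engineered to hit target RPKM values
#'
#' Inverts the RPKM formula: `count = RPKM * (length/1000) * (library/1e6)`,
#' rounded to the nearest integer.
#'
#' @param target_rpkm numeric vector of desired RPKM values.
#' @param gene_length_bp gene lengths (bp).
#' @param total_mapped library size (total mapped reads) of the condition.
#' @return integer vector of counts.
#' @export
simulate_counts <- function(target_rpkm, gene_length_bp, total_mapped) {
  stopifnot(all(gene_length_bp > 0), total_mapped > 0)
  as.integer(round(target_rpkm * (gene_length_bp / 1000) *
                     (total_mapped / 1e6)))
}
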