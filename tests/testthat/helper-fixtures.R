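# Shared fixtures, built in code at test time.

# A small deterministic assay scenario: genome + array + amplicon reads.
assay_fixture <- function(seed = 101, n_reads = 300, acquisition_rate = 0.05,
                          duplication_rate = 0.10, error_rate = 0, ...) {
  cfg <- sim_config(seed = seed, n_amplicon_reads = n_reads,
                    acquisition_rate = acquisition_rate,
                    duplication_rate = duplication_rate,
                    per_base_error_rate = error_rate, ...)
  genome <- gen_genome(cfg)
  array <- gen_array(seed = seed)
  sim <- simulate_acquisition_reads(array, genome, cfg)
  list(cfg = cfg, genome = genome, array = array,
       reads = sim$reads, truth = sim$truth)
}

# Mutate exactly n positions of a sequence, reproducibly.
mutate_n <- function(seq, n, seed = 1) {
  set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), n)
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

# Brute-force reference scan: best ungapped local alignment at every offset
# on both strands (vectorized Kadane over all diagonals). Independent oracle
# for the seed-and-extend mapper. Returns all per-offset best-local results.
brute_force_scan <- function(spacer, refseq, match = 1, mismatch = -3) {
  scan_strand <- function(q) {
    L <- nchar(q)
    N <- nchar(refseq)
    qb <- charToRaw(q)
    sb <- charToRaw(refseq)
    offs <- 0:(N - L)                       # 0-based full-placement offsets
    eq <- matrix(sb[outer(seq_len(L), offs, `+`)] == qb, nrow = L)
    m <- length(offs)
    cur <- numeric(m); curstart <- rep(1L, m)
    best <- numeric(m); bs <- integer(m); be <- integer(m)
    for (i in seq_len(L)) {
      reset <- cur <= 0
      curstart[reset] <- i
      cur[reset] <- 0
      cur <- cur + ifelse(eq[i, ], match, mismatch)
      upd <- cur > best
      best[upd] <- cur[upd]; bs[upd] <- curstart[upd]; be[upd] <- i
    }
    list(offs = offs, score = best, q_start = bs, q_end = be, eq = eq)
  }
  fw <- scan_strand(spacer)
  rv <- scan_strand(revcomp(spacer))
  list(fw = fw, rv = rv)
}

# Oracle best-hit resolution mirroring the published filter + scoring rules,
# computed purely from the brute-force scan.
brute_force_best <- function(spacer, refseq, match = 1, mismatch = -3) {
  sc <- brute_force_scan(spacer, refseq, match, mismatch)
  L <- nchar(spacer)
  collect <- function(s, strand) {
    pos <- which(s$score > 0)
    if (!length(pos)) return(NULL)
    span <- s$q_end[pos] - s$q_start[pos] + 1L
    nmat <- vapply(pos, function(j)
      sum(s$eq[s$q_start[j]:s$q_end[j], j]), integer(1))
    data.frame(start = s$offs[pos] + s$q_start[pos] - 1L,
               end = s$offs[pos] + s$q_end[pos],
               strand = strand, alignment_length = span,
               n_mismatches = span - nmat,
               percent_identity = 100 * nmat / span,
               raw_score = s$score[pos])
  }
  hits <- rbind(collect(sc$fw, "+"), collect(sc$rv, "-"))
  if (is.null(hits)) return(list(status = "unmapped", hit = NULL))
  pass <- hits$percent_identity > 95 & hits$n_mismatches < 4 &
    hits$alignment_length / L > 0.9 & abs(hits$alignment_length - L) < 3
  hits <- hits[pass, , drop = FALSE]
  if (!nrow(hits)) return(list(status = "unmapped", hit = NULL))
  top <- max(hits$raw_score)
  at <- hits[hits$raw_score == top, , drop = FALSE]
  # identical (start,end,strand) rows can arise from adjacent offsets whose
  # trimmed local alignments coincide; they are one location, not a tie
  at <- at[!duplicated(at[, c("start", "end", "strand")]), , drop = FALSE]
  if (nrow(at) > 1) return(list(status = "ambiguous_tie", hit = NULL))
  list(status = "best", hit = at)
}
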