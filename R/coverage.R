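# k-mer index over the forward strand of all replicons: data.frame of
# (kmer, replicon, pos0) for every position, plus a uniqueness flag.
.kmer_index <- function(replicons, k) {
  tabs <- lapply(names(replicons), function(rn) {
    seq <- replicons[[rn]]
    L <- nchar(seq)
    if (L < k) return(NULL)
    starts <- seq_len(L - k + 1L)
    data.frame(kmer = substring(seq, starts, starts + k - 1L),
               replicon = rn, pos0 = starts - 1L, stringsAsFactors = FALSE)
  })
  idx <- do.call(rbind, tabs)
  dup <- idx$kmer[duplicated(idx$kmer)]
  idx$unique <- !(idx$kmer %in% dup)
  idx
}

#' Place reads on reference replicons by unique exact seed
#'
#' Each read (or its reverse complement) is anchored by the exact match of
#' its first `k`-mer in the reference; the placement is accepted after
#' ungapped verification with at most `max_mismatches` substitutions over the
#' full read. Reads whose seed occurs at more than one reference position, or
#' that anchor on both strands, are dropped as multi-mapping. Alignments may
#' equivalently be supplied directly in SAM text via [read_sam()].
#'
#' @param reads named character vector of reads.
#' @param replicons named character vector of reference sequences.
#' @param k seed length (default 21).
#' @param max_mismatches substitution tolerance over the full read.
#' @return data.frame of alignments: `read_id`, `replicon`, `start`, `end`
#'   (0-based half-open), `strand`, `n_mismatches`.
#' @export
map_reads <- function(reads, replicons, k = 21, max_mismatches = 3) {
  if (length(replicons) == 0 || is.null(names(replicons)))
    stop("reference replicons must be a named character vector")
  idx <- .kmer_index(replicons, k)
  rl <- nchar(reads)
  if (any(rl < k)) stop("reads shorter than the seed length")
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%07d", seq_along(reads))
  fwd_seed <- substr(reads, 1L, k)
  rc_reads <- revcomp(reads)
  rev_seed <- substr(rc_reads, 1L, k)
  mf <- match(fwd_seed, idx$kmer)
  mr <- match(rev_seed, idx$kmer)
  # a seed that matched a non-unique reference k-mer, or seeds on both
  # strands, imply multiple candidate placements
  amb <- (!is.na(mf) & !idx$unique[mf]) | (!is.na(mr) & !idx$unique[mr]) |
    (!is.na(mf) & !is.na(mr))
  use_f <- !amb & !is.na(mf)
  use_r <- !amb & !is.na(mr)

  verify <- function(sel, midx, seqs, strand) {
    if (!any(sel)) return(NULL)
    rep_n <- idx$replicon[midx[sel]]
    pos0 <- idx$pos0[midx[sel]]
    lens <- rl[sel]
    fit <- pos0 + lens <= nchar(replicons[rep_n])
    sel_i <- which(sel)[fit]
    if (!length(sel_i)) return(NULL)
    rep_n <- rep_n[fit]; pos0 <- pos0[fit]; lens <- lens[fit]
    refseq <- substring(replicons[rep_n], pos0 + 1L, pos0 + lens)
    q <- seqs[sel_i]
    exact <- refseq == q
    nm <- integer(length(q))
    chk <- which(!exact)
    for (j in chk)
      nm[j] <- sum(charToRaw(refseq[j]) != charToRaw(q[j]))
    okm <- nm <= max_mismatches
    if (!any(okm)) return(NULL)
    data.frame(read_id = ids[sel_i][okm], replicon = rep_n[okm],
               start = pos0[okm], end = pos0[okm] + lens[okm],
               strand = rep(strand, sum(okm)), n_mismatches = nm[okm],
               stringsAsFactors = FALSE)
  }
  out <- rbind(verify(use_f, mf, reads, "+"),
               verify(use_r, mr, rc_reads, "-"))
  if (is.null(out))
    out <- data.frame(read_id = character(0), replicon = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_mismatches = integer(0))
  rownames(out) <- NULL
  out
}

#' Read alignments from a SAM text file
#'
#' Minimal parser for the standard alignment format: header lines are
#' skipped, unmapped records (flag 0x4) dropped, and the reference span is
#' taken from POS and the CIGAR (M/D/N/=/X operations).
#'
#' @param path SAM file path.
#' @return alignment data.frame as from [map_reads()] (without
#'   `n_mismatches`).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(read_id = character(0), replicon = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(f, `[`, character(1), 1)
  flag <- as.integer(vapply(f, `[`, character(1), 2))
  rname <- vapply(f, `[`, character(1), 3)
  pos <- as.integer(vapply(f, `[`, character(1), 4))
  cigar <- vapply(f, `[`, character(1), 6)
  mapped <- bitwAnd(flag, 4L) == 0L & rname != "*"
  span <- vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
  data.frame(read_id = qname[mapped], replicon = rname[mapped],
             start = pos[mapped] - 1L, end = pos[mapped] - 1L + span[mapped],
             strand = ifelse(bitwAnd(flag[mapped], 16L) > 0L, "-", "+"),
             stringsAsFactors = FALSE)
}

#' Write alignments as a SAM text file
#'
#' Companion to [read_sam()] for the alignment-passthrough interface; emits
#' ungapped records (CIGAR `<len>M`).
#'
#' @param alignments data.frame from [map_reads()].
#' @param reads named character vector the alignments came from.
#' @param replicons named character vector of reference sequences.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_sam <- function(alignments, reads, replicons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rn in names(replicons))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", rn, nchar(replicons[[rn]])), con)
  if (nrow(alignments)) {
    seqs <- reads[alignments$read_id]
    rev <- alignments$strand == "-"
    seqs[rev] <- revcomp(seqs[rev])
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                       alignments$read_id,
                       ifelse(rev, 16L, 0L),
                       alignments$replicon,
                       alignments$start + 1L,
                       alignments$end - alignments$start,
                       seqs), con)
  }
  invisible(path)
}

#' Windowed read-depth profile with fold enrichment
#'
#' Per-window mean per-base depth over half-open windows tiling each
#' replicon, and each window's enrichment over a robust genome-wide baseline.
#' The baseline is a two-pass median of window depths across all replicons:
#' windows above twice the first-pass median (i.e. multi-copy elements
#' themselves) are excluded and the median recomputed, so the baseline tracks
#' the single-copy background even when the element occupies a sizeable
#' fraction of a small genome — unlike the arithmetic mean, which the
#' element inflates.
#'
#' @param alignments data.frame from [map_reads()] or [read_sam()].
#' @param replicon_lengths named integer vector of replicon lengths, or the
#'   replicons themselves.
#' @param window_size window width in bp (> 0).
#' @return data.frame: `replicon`, `start`, `end` (0-based half-open window),
#'   `depth`, `enrichment`; attribute `robust_genome_mean` holds the baseline.
#' @export
depth_profile <- function(alignments, replicon_lengths, window_size = 500) {
  if (window_size <= 0) stop("window_size must be positive")
  if (is.character(replicon_lengths))
    replicon_lengths <- stats::setNames(nchar(replicon_lengths),
                                        names(replicon_lengths))
  prof <- do.call(rbind, lapply(names(replicon_lengths), function(rn) {
    L <- as.integer(replicon_lengths[[rn]])
    al <- alignments[alignments$replicon == rn, , drop = FALSE]
    cov <- IRanges::coverage(IRanges::IRanges(start = al$start + 1L,
                                              end = al$end), width = L)
    ws <- seq(0L, L - 1L, by = as.integer(window_size))
    we <- pmin(ws + as.integer(window_size), L)
    v <- IRanges::Views(cov, start = ws + 1L, end = we)
    data.frame(replicon = rn, start = ws, end = we,
               depth = IRanges::viewMeans(v), stringsAsFactors = FALSE)
  }))
  base1 <- stats::median(prof$depth)
  base <- stats::median(prof$depth[prof$depth <= 2 * base1])
  prof$enrichment <- if (isTRUE(base > 0)) prof$depth / base else NA_real_
  attr(prof, "robust_genome_mean") <- base
  rownames(prof) <- NULL
  prof
}

#' Call elevated-coverage candidate mobile elements
#'
#' Maximal runs of at least `min_windows` consecutive windows with
#' enrichment at or above `threshold`, merged into intervals.
#'
#' @param profile data.frame from [depth_profile()].
#' @param threshold enrichment calling threshold (fold).
#' @param min_windows minimum consecutive windows per call.
#' @return data.frame of calls: `replicon`, `start`, `end`,
#'   `mean_enrichment`, `median_enrichment` (robust to partly covered edge
#'   windows), `n_windows`.
#' @export
call_elements <- function(profile, threshold = 2.5, min_windows = 2) {
  out <- list()
  for (rn in unique(profile$replicon)) {
    p <- profile[profile$replicon == rn, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    hot <- !is.na(p$enrichment) & p$enrichment >= threshold
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_windows)) {
      i1 <- starts[j]; i2 <- ends[j]
      out[[length(out) + 1L]] <- data.frame(
        replicon = rn, start = p$start[i1], end = p$end[i2],
        mean_enrichment = mean(p$enrichment[i1:i2]),
        median_enrichment = stats::median(p$enrichment[i1:i2]),
        n_windows = i2 - i1 + 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(replicon = character(0), start = integer(0),
                      end = integer(0), mean_enrichment = numeric(0),
                      median_enrichment = numeric(0),
                      n_windows = integer(0)))
  do.call(rbind, out)
}

# End k-mer positions of reads on the forward strand of one replicon: for
# each read (either orientation), the unique exact placements of its first
# and last k-mer. Returns NA where a k-mer is absent or non-unique.
.end_kmer_positions <- function(reads, idx, k, replicon) {
  lookup <- function(kmers) {
    m <- match(kmers, idx$kmer)
    bad <- !is.na(m) & (!idx$unique[m] | idx$replicon[m] != replicon)
    m[bad] <- NA
    idx$pos0[m]
  }
  first <- lookup(substr(reads, 1L, k))
  last <- lookup(substring(reads, nchar(reads) - k + 1L))
  list(first = first, last = last)
}

#' Type an element call as circular and/or integrated from junction reads
#'
#' Circular evidence counts split reads whose leading end anchors near the
#' element end and whose trailing end anchors near the element start in
#' wrapped order — the computational analogue of outward-facing primers
#' across the circularization junction. Integration evidence counts reads
#' whose alignment spans a host-element edge of the call (continuity between
#' the element and its host flank, the analogue of host+element primer
#' pairs); it is reported as not assessable (`NA`) when the call abuts a
#' replicon edge and no host flank exists.
#'
#' @param reads named character vector of the raw reads.
#' @param call single-row data.frame from [call_elements()].
#' @param replicons named character vector of reference sequences.
#' @param alignments optional precomputed [map_reads()] alignments of
#'   `reads`; computed internally when `NULL`.
#' @param flank minimum host flank (bp) required on a side for integration
#'   evidence to be assessable there.
#' @param evidence_threshold minimum junction reads to accept a topology.
#' @param k end-anchor seed length for split-read detection.
#' @param edge_slack positional slack (bp) absorbing the window quantization
#'   of call edges when matching split reads.
#' @return the call row with `n_circular_junction_reads`,
#'   `n_integration_junction_reads` and `topology` in
#'   `{circular, integrated, both, undetermined}` appended.
#' @export
junction_typing <- function(reads, call, replicons, alignments = NULL,
                            flank = 200, evidence_threshold = 3, k = 21,
                            edge_slack = 600) {
  stopifnot(nrow(call) == 1)
  rn <- call$replicon
  L <- nchar(replicons[[rn]])
  rl_max <- max(nchar(reads))
  slack <- edge_slack + rl_max
  idx <- .kmer_index(replicons, k)

  count_circular <- function(rds) {
    pos <- .end_kmer_positions(rds, idx, k, rn)
    ok <- !is.na(pos$first) & !is.na(pos$last) &
      pos$first > pos$last &                              # wrapped order
      abs(pos$first + k - call$end) <= slack &            # prefix at element end
      abs(pos$last - call$start) <= slack                 # suffix at element start
    sum(ok)
  }
  n_circ <- count_circular(reads) + count_circular(revcomp(unname(reads)))

  has_left <- call$start >= flank
  has_right <- call$end + flank <= L
  if (!has_left && !has_right) {
    n_int <- NA_integer_
  } else {
    if (is.null(alignments)) alignments <- map_reads(reads, replicons)
    al <- alignments[alignments$replicon == rn, , drop = FALSE]
    spans <- function(edge) sum(al$start < edge - 5 & al$end > edge + 5)
    n_int <- 0L
    if (has_left) n_int <- n_int + spans(call$start)
    if (has_right) n_int <- n_int + spans(call$end)
  }

  circ_ok <- n_circ >= evidence_threshold
  int_ok <- !is.na(n_int) && n_int >= evidence_threshold
  call$n_circular_junction_reads <- n_circ
  call$n_integration_junction_reads <- n_int
  call$topology <- if (circ_ok && int_ok) "both"
                   else if (circ_ok) "circular"
                   else if (int_ok) "integrated"
                   else "undetermined"
  call
}
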