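#' Length-filter merged amplicon reads
#'
#' Keeps reads strictly longer than `min_length` bp: a baseline amplicon
#' (three repeats, no insertion) falls below the cutoff, so surviving reads
#' correspond to at least one candidate spacer acquisition/duplication event.
#'
#' @param reads named character vector of merged reads.
#' @param min_length length cutoff in bp; reads must be longer than this
#'   (strict inequality) to be kept.
#' @return the retained reads; the number discarded is reported via message.
#' @export
filter_reads <- function(reads, min_length = 300) {
  if (length(reads) == 0) {
    warning("no reads supplied")
    return(reads)
  }
  keep <- nchar(reads) > min_length
  message(sum(!keep), " read(s) of ", length(reads),
          " discarded at length <= ", min_length)
  reads[keep]
}

# Minimal mismatch count of `anchor` anywhere in `seq`, searched up to
# max_mm substitutions; Inf if absent.
.best_anchor_mm <- function(anchor, seq, max_mm) {
  subj <- Biostrings::DNAString(seq)
  for (k in 0:max_mm) {
    if (Biostrings::countPattern(anchor, subj, max.mismatch = k) > 0)
      return(k)
  }
  Inf
}

#' Orient a read so the leader-derived primer end is 5'
#'
#' The amplicon is leader-anchored by primer design, so the orientation is
#' decided by the best approximate match of a leader suffix on either strand.
#' A tie or no match on either strand yields `"ambiguous"`.
#'
#' @param read a single read sequence.
#' @param array a [gen_array()]-style `crispr_array` object.
#' @param max_mismatch maximum substitutions tolerated in the anchor match.
#' @param anchor_length how many 3'-terminal leader bases form the anchor.
#' @return list with `sequence` (read in forward orientation, or `NA` if
#'   ambiguous) and `strand` (`"forward"`, `"reverse"`, or `"ambiguous"`).
#' @export
orient_read <- function(read, array, max_mismatch = 5, anchor_length = 20) {
  anchor <- substr(array$leader,
                   nchar(array$leader) - anchor_length + 1,
                   nchar(array$leader))
  rc <- revcomp(read)
  mf <- .best_anchor_mm(anchor, read, max_mismatch)
  mr <- .best_anchor_mm(anchor, rc, max_mismatch)
  if (is.infinite(mf) && is.infinite(mr))
    return(list(sequence = NA_character_, strand = "ambiguous"))
  if (mf == mr)
    return(list(sequence = NA_character_, strand = "ambiguous"))
  if (mf < mr) list(sequence = read, strand = "forward")
  else list(sequence = rc, strand = "reverse")
}

# Greedy left-to-right selection of non-overlapping matches from sorted
# start positions (leftmost-start tie-breaking); all widths equal `width`.
.greedy_nonoverlap <- function(starts, width) {
  keep <- integer(0)
  last_end <- -1L
  for (s in starts) {
    if (s > last_end) {
      keep <- c(keep, s)
      last_end <- s + width - 1L
    }
  }
  keep
}

#' Find repeat occurrences in an oriented read
#'
#' All non-overlapping occurrences of the array repeat with at most
#' `max_mismatches` substitutions (no indels), selected greedily left to
#' right with leftmost-start tie-breaking.
#'
#' @param oriented_read a read in leader-forward orientation.
#' @param repeat_seq the repeat sequence.
#' @param max_mismatches substitution tolerance per occurrence.
#' @return data.frame with 0-based half-open `start`, `end` and `mismatches`,
#'   sorted by start. Empty if the repeat is longer than the read.
#' @export
find_repeat_occurrences <- function(oriented_read, repeat_seq,
                                    max_mismatches = 2) {
  w <- nchar(repeat_seq)
  if (w > nchar(oriented_read))
    return(data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0)))
  subj <- Biostrings::DNAString(oriented_read)
  m <- Biostrings::matchPattern(repeat_seq, subj,
                                max.mismatch = max_mismatches,
                                with.indels = FALSE)
  starts <- sort(Biostrings::start(m)) - 1L  # 0-based
  starts <- .greedy_nonoverlap(starts, w)
  mism <- vapply(starts, function(s)
    hamming(substr0(oriented_read, s, s + w), repeat_seq), integer(1))
  data.frame(start = starts, end = starts + w, mismatches = mism)
}

#' Extract the leader-proximal candidate spacer from an expanded read
#'
#' Reads with more repeats than the baseline amplicon are tagged as expanded
#' and the sequence strictly between the two repeats closest to the leader
#' end is extracted, then length-filtered: fragments shorter than 10 bp or
#' longer than 45 bp are excluded as aberrant.
#'
#' @param oriented_read read in leader-forward orientation.
#' @param matches repeat occurrences from [find_repeat_occurrences()] (sorted,
#'   non-overlapping; violations are an error).
#' @param array the `crispr_array` the amplicon derives from.
#' @param min_spacer,max_spacer inclusive spacer length bounds for `kept`.
#' @return list with `sequence` (`NA` unless kept), `repeat_count`, and
#'   `status` in `{kept, too_short, too_long, not_expanded}`.
#' @export
extract_leader_proximal_spacer <- function(oriented_read, matches, array,
                                           min_spacer = 10, max_spacer = 45) {
  n <- nrow(matches)
  if (n >= 2) {
    if (is.unsorted(matches$start, strictly = TRUE) ||
        any(matches$start[-1] < matches$end[-n]))
      stop("repeat matches must be sorted and non-overlapping")
  }
  if (n <= array$baseline_repeats)
    return(list(sequence = NA_character_, repeat_count = n,
                status = "not_expanded"))
  sp <- substr0(oriented_read, matches$end[1], matches$start[2])
  len <- nchar(sp)
  status <- if (len < min_spacer) "too_short"
            else if (len > max_spacer) "too_long"
            else "kept"
  list(sequence = if (status == "kept") sp else NA_character_,
       repeat_count = n, status = status)
}

#' Extract candidate spacers from a set of amplicon reads
#'
#' Vectorized pipeline over already length-filtered reads: orientation by
#' leader anchor, repeat counting, and leader-proximal spacer extraction.
#' Equivalent read-by-read to [orient_read()] +
#' [find_repeat_occurrences()] + [extract_leader_proximal_spacer()].
#'
#' @param reads named character vector of merged reads (post
#'   [filter_reads()]).
#' @param array a `crispr_array` object.
#' @param max_repeat_mm substitution tolerance for repeat occurrences.
#' @param orient_max_mm substitution tolerance for the leader anchor.
#' @param anchor_length leader-anchor length (bp).
#' @param min_spacer,max_spacer spacer length bounds.
#' @return data.frame with one row per read: `read_id`, `array_id`, `strand`,
#'   `repeat_count`, `status`, `sequence`. Status values: `kept`, `too_short`,
#'   `too_long`, `not_expanded`, `ambiguous_orientation`.
#' @export
extract_spacers <- function(reads, array, max_repeat_mm = 2,
                            orient_max_mm = 5, anchor_length = 20,
                            min_spacer = 10, max_spacer = 45) {
  stopifnot(inherits(array, "crispr_array"))
  n <- length(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_len(n))
  if (n == 0)
    return(data.frame(read_id = character(0), array_id = character(0),
                      strand = character(0), repeat_count = integer(0),
                      status = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  res <- data.frame(read_id = ids, array_id = array$array_id,
                    strand = NA_character_, repeat_count = NA_integer_,
                    status = NA_character_, sequence = NA_character_,
                    stringsAsFactors = FALSE)
  if (n == 0) return(res)

  fwd <- Biostrings::DNAStringSet(unname(reads))
  rev <- Biostrings::reverseComplement(fwd)
  anchor <- substr(array$leader,
                   nchar(array$leader) - anchor_length + 1,
                   nchar(array$leader))
  # first mismatch level at which the anchor hits, per strand
  firstf <- rep(Inf, n); firstr <- rep(Inf, n)
  for (k in 0:orient_max_mm) {
    cf <- Biostrings::vcountPattern(anchor, fwd, max.mismatch = k)
    cr <- Biostrings::vcountPattern(anchor, rev, max.mismatch = k)
    firstf[is.infinite(firstf) & cf > 0] <- k
    firstr[is.infinite(firstr) & cr > 0] <- k
    if (all(is.finite(firstf) | is.finite(firstr))) break
  }
  strand <- ifelse(is.infinite(firstf) & is.infinite(firstr), "ambiguous",
                   ifelse(firstf < firstr, "forward",
                          ifelse(firstr < firstf, "reverse", "ambiguous")))
  res$strand <- strand
  oriented <- as.character(fwd)
  oriented[strand == "reverse"] <- as.character(rev)[strand == "reverse"]
  ok <- strand != "ambiguous"
  res$status[!ok] <- "ambiguous_orientation"
  if (!any(ok)) return(res)

  osub <- Biostrings::DNAStringSet(oriented[ok])
  mm <- Biostrings::vmatchPattern(array$repeat_seq, osub,
                                  max.mismatch = max_repeat_mm,
                                  with.indels = FALSE)
  starts_list <- Biostrings::startIndex(mm)
  w <- nchar(array$repeat_seq)
  idx_ok <- which(ok)
  for (j in seq_along(idx_ok)) {
    i <- idx_ok[j]
    st <- starts_list[[j]]
    st <- if (is.null(st)) integer(0) else sort(st) - 1L
    st <- .greedy_nonoverlap(st, w)
    cnt <- length(st)
    res$repeat_count[i] <- cnt
    if (cnt <= array$baseline_repeats) {
      res$status[i] <- "not_expanded"
    } else {
      sp <- substr0(oriented[i], st[1] + w, st[2])
      len <- nchar(sp)
      if (len < min_spacer) res$status[i] <- "too_short"
      else if (len > max_spacer) res$status[i] <- "too_long"
      else { res$status[i] <- "kept"; res$sequence[i] <- sp }
    }
  }
  res
}
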