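# memoized nucleotide substitution matrices (construction is surprisingly
# costly and align_spacer is called per spacer)
.submat_cache <- new.env(parent = emptyenv())
.get_submat <- function(match, mismatch) {
  key <- paste(match, mismatch)
  if (is.null(.submat_cache[[key]]))
    .submat_cache[[key]] <- Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = TRUE)
  .submat_cache[[key]]
}

#' Precompute a word index over reference replicons
#'
#' Exact-word lookup table (word of `word_size` -> 0-based forward-strand
#' positions) plus cached byte representations, reused across
#' [align_spacer()] calls on the same reference.
#'
#' @param replicons named character vector of reference sequences.
#' @param word_size exact seed length (default 7).
#' @return an object of class `ref_index`.
#' @export
ref_word_index <- function(replicons, word_size = 7) {
  stopifnot(length(replicons) > 0, !is.null(names(replicons)))
  words <- lapply(replicons, function(s) {
    n <- nchar(s) - word_size + 1L
    if (n < 1) return(list())
    split(0:(n - 1L), substring(s, 1:n, word_size:(n + word_size - 1L)))
  })
  structure(list(word_size = as.integer(word_size),
                 replicons = replicons,
                 words = words,
                 bytes = lapply(replicons, charToRaw)),
            class = "ref_index")
}

# Best ungapped local alignment (max-scoring subarray with traceback) of
# `query` laid on diagonal d of the subject; d is the 0-based subject offset
# of query position 1. Returns NULL if nothing scores positive.
.diag_local_ungapped <- function(qbytes, sbytes, d, match, mismatch) {
  L <- length(qbytes)
  qi <- seq_len(L)
  si <- d + qi
  ok <- si >= 1L & si <= length(sbytes)
  if (!any(ok)) return(NULL)
  qq <- qi[ok]
  eq <- qbytes[qq] == sbytes[si[ok]]
  sc <- ifelse(eq, match, mismatch)
  best <- 0; cur <- 0; cs <- 1L; bs <- 0L; be <- -1L
  for (j in seq_along(sc)) {
    if (cur <= 0) { cur <- 0; cs <- j }
    cur <- cur + sc[j]
    if (cur > best) { best <- cur; bs <- cs; be <- j }
  }
  if (best <= 0) return(NULL)
  nmat <- sum(eq[bs:be])
  span <- be - bs + 1L
  list(score = best,
       start = d + qq[bs] - 1L,       # 0-based subject coords
       end = d + qq[be],              # half-open
       alignment_length = span,
       n_mismatches = span - nmat, n_gaps = 0L,
       percent_identity = 100 * nmat / span)
}

# Short-query local alignment of one oriented query against one replicon:
# exact word-size seed anchoring, ungapped local extension per diagonal
# (the main path), and gapped extension via pairwiseAlignment where seeds
# fall on shifted diagonals (indel evidence). 0-based half-open coords.
.seed_extend <- function(query, repl_seq, repl_words, repl_bytes, word_size,
                         submat, gap_open, gap_ext, match = 1, mismatch = -3,
                         margin = 8L, prescreen_slack = 12) {
  L <- nchar(query)
  if (L < word_size) return(NULL)
  n_seeds <- L - word_size + 1L
  seeds <- substring(query, seq_len(n_seeds),
                     seq_len(n_seeds) + word_size - 1L)
  pos_list <- repl_words[seeds]
  diags <- integer(0)
  for (k in seq_len(n_seeds)) {
    p <- pos_list[[k]]
    if (!is.null(p) && length(p))
      diags <- c(diags, p + 1L - k)  # 0-based subject offset of query pos 1
  }
  if (!length(diags)) return(NULL)
  diags <- sort(unique(diags))
  qbytes <- charToRaw(query)
  N <- length(repl_bytes)
  interior <- diags >= 0L & diags + L <= N
  per_diag <- vector("list", length(diags))
  if (any(interior)) {
    dint <- diags[interior]
    # vectorized Kadane with traceback across all interior diagonals
    qi <- seq_len(L)
    eq <- matrix(repl_bytes[outer(qi, dint, `+`)] == qbytes,
                 nrow = L)
    m <- length(dint)
    cur <- numeric(m); curstart <- rep(1L, m)
    best <- numeric(m); bs <- integer(m); be <- integer(m)
    for (i in qi) {
      reset <- cur <= 0
      if (any(reset)) { curstart[reset] <- i; cur[reset] <- 0 }
      cur <- cur + ifelse(eq[i, ], match, mismatch)
      upd <- cur > best
      if (any(upd)) { best[upd] <- cur[upd]; bs[upd] <- curstart[upd]
                      be[upd] <- i }
    }
    for (j in which(best > 0)) {
      span <- be[j] - bs[j] + 1L
      nmat <- sum(eq[bs[j]:be[j], j])
      per_diag[which(interior)[j]] <- list(list(
        score = best[j],
        start = dint[j] + bs[j] - 1L, end = dint[j] + be[j],
        alignment_length = span, n_mismatches = span - nmat, n_gaps = 0L,
        percent_identity = 100 * nmat / span))
    }
  }
  for (j in which(!interior))
    per_diag[j] <- list(.diag_local_ungapped(qbytes, repl_bytes, diags[j],
                                             match, mismatch))
  # group diagonals within 5 bp (small indel shifts belong to one locus)
  grp <- cumsum(c(TRUE, diff(diags) > 5))
  groups <- split(diags, grp)
  ug <- lapply(split(per_diag, grp), function(res) {
    res <- res[!vapply(res, is.null, logical(1))]
    if (!length(res)) return(NULL)
    res[[which.max(vapply(res, `[[`, numeric(1), "score"))]]
  })
  gscore <- vapply(ug, function(x) if (is.null(x)) 0 else x$score, numeric(1))
  keep <- which(gscore >= max(gscore) - prescreen_slack)
  N <- nchar(repl_seq)
  out <- list()
  for (j in keep) {
    g <- groups[[j]]
    hit <- ug[[j]]
    if (length(g) > 1) {
      # shifted seed diagonals: try a gapped local alignment over the window
      ws <- max(1L, as.integer(min(g)) + 1L - margin)
      we <- min(N, as.integer(max(g)) + L + margin)
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(query),
        Biostrings::DNAString(substr(repl_seq, ws, we)),
        type = "local", substitutionMatrix = submat,
        gapOpening = gap_open, gapExtension = gap_ext)
      sc <- Biostrings::score(aln)
      if (sc > 0 && (is.null(hit) || sc > hit$score)) {
        pr <- Biostrings::pattern(aln)
        sr <- Biostrings::subject(aln)
        qspan <- IRanges::end(pr) - IRanges::start(pr) + 1L
        nmat <- Biostrings::nmatch(aln)
        ind <- Biostrings::nindel(aln)
        hit <- list(score = sc,
                    start = ws + IRanges::start(sr) - 2L,
                    end = ws + IRanges::end(sr) - 1L,
                    alignment_length = qspan,
                    n_mismatches = Biostrings::nmismatch(aln),
                    n_gaps = as.integer(ind@insertion[1, "WidthSum"] +
                                          ind@deletion[1, "WidthSum"]),
                    percent_identity = 100 * nmat / qspan)
      }
    }
    if (is.null(hit)) next
    out[[length(out) + 1L]] <- hit
  }
  if (!length(out)) return(NULL)
  g1 <- function(f) vapply(out, `[[`, numeric(1), f)
  df <- data.frame(start = g1("start"), end = g1("end"),
                   alignment_length = g1("alignment_length"),
                   n_mismatches = g1("n_mismatches"),
                   n_gaps = g1("n_gaps"),
                   percent_identity = g1("percent_identity"),
                   raw_score = g1("score"))
  df[!duplicated(df[, c("start", "end")]), , drop = FALSE]
}

#' Align a spacer to reference replicons (short-query local alignment)
#'
#' Seed-and-extend local alignment in the style of short-query nucleotide
#' search: exact seeds of `word_size` 7 anchored on both strands, gapped
#' local extension with scoring match +1, mismatch -3, gap open -5, gap
#' extend -2 (a gap of length L costs 5 + 2L). All hits scoring within 90%
#' of the best raw score are returned, unfiltered.
#'
#' @param spacer spacer sequence (10-45 nt).
#' @param replicons named character vector of reference sequences.
#' @param word_size exact seed length.
#' @param match,mismatch,gap_open,gap_ext scoring parameters (penalties
#'   positive).
#' @param keep_frac retain hits with raw score >= `keep_frac` * best.
#' @param index optional [ref_word_index()] of `replicons` (built internally
#'   when `NULL`; precompute it when mapping many spacers).
#' @return data.frame of hits: `replicon`, `start`, `end` (0-based half-open,
#'   forward reference coords), `strand`, `alignment_length` (aligned span in
#'   the query), `n_mismatches`, `n_gaps`, `percent_identity`, `raw_score`.
#'   Zero rows if nothing aligns.
#' @export
align_spacer <- function(spacer, replicons, word_size = 7,
                         match = 1, mismatch = -3, gap_open = 5, gap_ext = 2,
                         keep_frac = 0.9, index = NULL) {
  if (length(replicons) == 0) stop("empty reference")
  stopifnot(nchar(spacer) >= 10, nchar(spacer) <= 45)
  if (is.null(index)) index <- ref_word_index(replicons, word_size)
  stopifnot(index$word_size == word_size)
  submat <- .get_submat(match, mismatch)
  rc <- revcomp(spacer)
  out <- list()
  for (rn in names(replicons)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") spacer else rc
      df <- .seed_extend(q, replicons[[rn]], index$words[[rn]],
                         index$bytes[[rn]], word_size, submat,
                         gap_open, gap_ext,
                         match = match, mismatch = mismatch)
      if (!is.null(df)) {
        df$replicon <- rn
        df$strand <- strand
        out[[length(out) + 1L]] <- df
      }
    }
  }
  cols <- c("replicon", "start", "end", "strand", "alignment_length",
            "n_mismatches", "n_gaps", "percent_identity", "raw_score")
  if (!length(out))
    return(stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))),
                           cols))
  hits <- do.call(rbind, out)
  hits <- hits[hits$raw_score >= keep_frac * max(hits$raw_score), cols,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Apply the strict protospacer hit filters
#'
#' A hit passes iff all four criteria hold, each a strict inequality:
#' percent identity > 95, mismatches < 4, alignment length / query length
#' > 0.9, and |alignment length - query length| < 3.
#'
#' @param hits data.frame from [align_spacer()].
#' @param spacer_length length of the query spacer (bp).
#' @return `hits` with a `status` column: `"pass"` or `"filtered_out"`.
#' @export
filter_hits <- function(hits, spacer_length) {
  if (nrow(hits) == 0) { hits$status <- character(0); return(hits) }
  pass <- hits$percent_identity > 95 &
    hits$n_mismatches < 4 &
    hits$alignment_length / spacer_length > 0.9 &
    abs(hits$alignment_length - spacer_length) < 3
  hits$status <- ifelse(pass, "pass", "filtered_out")
  hits
}

#' Resolve multi-mapping hits to a single best location
#'
#' Among filter-passing hits, a unique maximum raw score is the best hit;
#' two or more hits sharing the maximum score mark the spacer as an
#' ambiguous tie (excluded from location and PAM summaries); no passing hit
#' means unmapped.
#'
#' @param hits data.frame from [filter_hits()].
#' @return list with `status` (`"best"`, `"ambiguous_tie"`, `"unmapped"`) and
#'   `hit` (single-row data.frame for `"best"`, otherwise `NULL`).
#' @export
resolve_best <- function(hits) {
  pass <- hits[hits$status == "pass", , drop = FALSE]
  if (nrow(pass) == 0) return(list(status = "unmapped", hit = NULL))
  top <- max(pass$raw_score)
  at_top <- which(pass$raw_score == top)
  if (length(at_top) > 1) return(list(status = "ambiguous_tie", hit = NULL))
  list(status = "best", hit = pass[at_top, , drop = FALSE])
}

#' Extract the PAM trinucleotide adjacent to a protospacer
#'
#' Reads the `pam_length` bases immediately 5' (default) of the protospacer,
#' on the protospacer strand: for a `+` hit the reference slice just before
#' `start`; for a `-` hit the reverse complement of the slice just after
#' `end`. `NA` if the window runs off the replicon end.
#'
#' @param hit single-row hit data.frame (`replicon`, `start`, `end`,
#'   `strand`; 0-based half-open).
#' @param replicons named character vector of reference sequences.
#' @param pam_length motif length (default 3).
#' @param side `"5prime"` (default) or `"3prime"` of the protospacer.
#' @return the PAM string, or `NA_character_`.
#' @export
extract_pam <- function(hit, replicons, pam_length = 3,
                        side = c("5prime", "3prime")) {
  side <- match.arg(side)
  seq <- replicons[[hit$replicon]]
  if (is.null(seq)) stop("unknown replicon: ", hit$replicon)
  L <- nchar(seq)
  if (hit$start < 0 || hit$end > L) stop("hit coordinates outside replicon")
  upstream <- (hit$strand == "+") == (side == "5prime")
  if (upstream) {
    if (hit$start - pam_length < 0) return(NA_character_)
    pam <- substr0(seq, hit$start - pam_length, hit$start)
  } else {
    if (hit$end + pam_length > L) return(NA_character_)
    pam <- substr0(seq, hit$end, hit$end + pam_length)
  }
  if (hit$strand == "-") pam <- revcomp(pam)
  pam
}

#' Map new spacers to reference replicons
#'
#' Orchestrates [align_spacer()], [filter_hits()], [resolve_best()] and
#' [extract_pam()] over a set of spacers (spacers classified as duplicates
#' should not be supplied; only new acquisitions are mapped).
#'
#' @param spacers named character vector of spacer sequences, or a
#'   data.frame with `read_id` and `sequence` columns.
#' @param replicons named character vector of reference sequences.
#' @param pam_length,pam_side passed to [extract_pam()].
#' @param word_size exact seed length for the shared reference index.
#' @param ... passed to [align_spacer()].
#' @return data.frame, one row per spacer: `spacer_id`, `status` (`best`,
#'   `ambiguous_tie`, `unmapped`), and for best hits `replicon`, `start`,
#'   `end`, `strand`, `alignment_length`, `n_mismatches`, `n_gaps`,
#'   `percent_identity`, `raw_score`, `pam`.
#' @export
map_spacers <- function(spacers, replicons, pam_length = 3,
                        pam_side = "5prime", word_size = 7, ...) {
  if (is.data.frame(spacers)) {
    ids <- spacers$read_id
    seqs <- spacers$sequence
  } else {
    seqs <- as.character(spacers)
    ids <- names(spacers)
    if (is.null(ids)) ids <- sprintf("spacer_%05d", seq_along(seqs))
  }
  index <- ref_word_index(replicons, word_size)
  rows <- lapply(seq_along(seqs), function(i) {
    hits <- align_spacer(seqs[i], replicons, word_size = word_size,
                         index = index, ...)
    hits <- filter_hits(hits, nchar(seqs[i]))
    res <- resolve_best(hits)
    base <- data.frame(spacer_id = ids[i], status = res$status,
                       replicon = NA_character_, start = NA_integer_,
                       end = NA_integer_, strand = NA_character_,
                       alignment_length = NA_integer_,
                       n_mismatches = NA_integer_, n_gaps = NA_integer_,
                       percent_identity = NA_real_, raw_score = NA_real_,
                       pam = NA_character_, stringsAsFactors = FALSE)
    if (res$status == "best") {
      h <- res$hit
      base[c("replicon", "strand")] <- c(h$replicon, h$strand)
      base[c("start", "end", "alignment_length", "n_mismatches", "n_gaps")] <-
        c(h$start, h$end, h$alignment_length, h$n_mismatches, h$n_gaps)
      base$percent_identity <- h$percent_identity
      base$raw_score <- h$raw_score
      base$pam <- extract_pam(h, replicons, pam_length, pam_side)
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise PAM trinucleotides over best hits
#'
#' Counts PAM motifs among best hits with a defined PAM, with the expected
#' background fraction of each motif under the reference base composition
#' (trinucleotide frequencies over both strands).
#'
#' @param best_hits data.frame from [map_spacers()].
#' @param replicons named character vector of reference sequences.
#' @return list with `counts` (named integer), `top_motif`, `top_fraction`,
#'   `background` (named numeric, expected fractions). Empty counts (with a
#'   warning) if there are no best hits with a PAM.
#' @export
pam_summary <- function(best_hits, replicons = NULL) {
  pams <- best_hits$pam[best_hits$status == "best" & !is.na(best_hits$pam)]
  background <- NULL
  if (!is.null(replicons)) {
    dss <- Biostrings::DNAStringSet(unname(replicons))
    f <- colSums(Biostrings::oligonucleotideFrequency(dss, width = 3)) +
      colSums(Biostrings::oligonucleotideFrequency(
        Biostrings::reverseComplement(dss), width = 3))
    background <- f / sum(f)
  }
  if (length(pams) == 0) {
    warning("no best hits with a defined PAM")
    return(list(counts = integer(0), top_motif = NA_character_,
                top_fraction = NaN, background = background))
  }
  counts <- sort(table(pams), decreasing = TRUE)
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts, top_motif = names(counts)[1],
       top_fraction = counts[[1]] / sum(counts), background = background)
}

#' Binned protospacer location distribution
#'
#' Bins best-hit protospacer positions (by start coordinate) per replicon
#' and reports the top locus — the bin holding the largest fraction of all
#' mapped spacers (the locus-skew summary).
#'
#' @param best_hits data.frame from [map_spacers()].
#' @param replicon_lengths named integer vector of replicon lengths, or the
#'   replicons themselves (lengths taken via `nchar`).
#' @param bin_size bin width in bp.
#' @return list with `bins` (data.frame: `replicon`, `bin_start`, `bin_end`,
#'   `count`) and `top_locus` (list: `replicon`, `start`, `end`, `fraction`).
#' @export
locus_distribution <- function(best_hits, replicon_lengths, bin_size = 1000) {
  if (is.character(replicon_lengths))
    replicon_lengths <- stats::setNames(nchar(replicon_lengths),
                                        names(replicon_lengths))
  hits <- best_hits[best_hits$status == "best", , drop = FALSE]
  bins <- do.call(rbind, lapply(names(replicon_lengths), function(rn) {
    L <- replicon_lengths[[rn]]
    starts <- seq(0L, max(0L, L - 1L), by = bin_size)
    data.frame(replicon = rn, bin_start = starts,
               bin_end = pmin(starts + bin_size, L),
               stringsAsFactors = FALSE)
  }))
  bins$count <- 0L
  if (nrow(hits)) {
    for (i in seq_len(nrow(hits))) {
      j <- which(bins$replicon == hits$replicon[i] &
                   bins$bin_start <= hits$start[i] &
                   hits$start[i] < bins$bin_end)
      bins$count[j] <- bins$count[j] + 1L
    }
  } else {
    warning("no best hits to bin")
  }
  top <- NULL
  if (sum(bins$count) > 0) {
    j <- which.max(bins$count)
    top <- list(replicon = bins$replicon[j], start = bins$bin_start[j],
                end = bins$bin_end[j],
                fraction = bins$count[j] / sum(bins$count))
  }
  list(bins = bins, top_locus = top)
}
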