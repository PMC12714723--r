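# Distance between a query spacer and one reference spacer under the chosen
# metric. "mixed": Hamming when lengths are equal, unit-cost edit distance
# (substitutions + indels) otherwise. "edit": always edit distance.
# "hamming": Hamming, Inf for unequal lengths.
.spacer_dist <- function(query, ref, metric) {
  if (metric == "hamming") {
    if (nchar(query) != nchar(ref)) return(Inf)
    return(hamming(query, ref))
  }
  if (metric == "mixed" && nchar(query) == nchar(ref))
    return(hamming(query, ref))
  as.integer(adist(query, ref))
}

#' Classify an extracted spacer as duplicate or new acquisition
#'
#' Screens the spacer against every spacer of every supplied array, on both
#' strands. The minimum distance decides the label: at most `max_mismatches`
#' (default 10) means the spacer is a duplication/rearrangement of an
#' existing spacer; otherwise it is a new acquisition. Ties are broken by
#' (array order, spacer index order), deterministic.
#'
#' @param spacer a spacer sequence.
#' @param arrays list of `crispr_array` objects (non-empty).
#' @param max_mismatches duplicate threshold (inclusive).
#' @param metric `"mixed"` (Hamming for equal lengths, edit distance
#'   otherwise; default), `"edit"`, or `"hamming"`.
#' @return list with `label` (`"duplicate"`/`"new"`), `best_array`,
#'   `best_index`, `distance` (the minimum distance; `best_*` are `NA` when
#'   no finite distance exists).
#' @export
classify_spacer <- function(spacer, arrays, max_mismatches = 10,
                            metric = c("mixed", "edit", "hamming")) {
  metric <- match.arg(metric)
  if (length(arrays) == 0) stop("empty array set")
  if (inherits(arrays, "crispr_array")) arrays <- list(arrays)
  rc <- revcomp(spacer)
  best <- Inf; best_array <- NA_character_; best_index <- NA_integer_
  for (a in arrays) {
    for (j in seq_along(a$spacers)) {
      d <- min(.spacer_dist(spacer, a$spacers[j], metric),
               .spacer_dist(rc, a$spacers[j], metric))
      if (d < best) {
        best <- d; best_array <- a$array_id; best_index <- j
      }
    }
  }
  list(label = if (is.finite(best) && best <= max_mismatches) "duplicate"
               else "new",
       best_array = if (is.finite(best)) best_array else NA_character_,
       best_index = if (is.finite(best)) best_index else NA_integer_,
       distance = if (is.finite(best)) as.integer(best) else NA_integer_)
}

#' Classify a table of extracted spacers
#'
#' Vectorized batch version of [classify_spacer()] over the `kept` rows of an
#' [extract_spacers()] table. Hamming distances for equal-length pairs are
#' computed by byte comparison; unequal-length pairs fall back to unit-cost
#' edit distance (or per `metric`).
#'
#' @param spacers data.frame from [extract_spacers()] (rows with status
#'   `kept` are classified; other rows are dropped) or a character vector of
#'   spacer sequences.
#' @param arrays list of `crispr_array` objects.
#' @inheritParams classify_spacer
#' @return data.frame: `read_id` (if available), `array_id` (the amplicon's
#'   array, if available), `sequence`, `label`, `best_array`, `best_index`,
#'   `distance`.
#' @export
classify_spacers <- function(spacers, arrays, max_mismatches = 10,
                             metric = c("mixed", "edit", "hamming")) {
  metric <- match.arg(metric)
  if (length(arrays) == 0) stop("empty array set")
  if (inherits(arrays, "crispr_array")) arrays <- list(arrays)
  if (is.data.frame(spacers)) {
    kept <- spacers[spacers$status == "kept", , drop = FALSE]
    seqs <- kept$sequence
    meta <- kept[, intersect(c("read_id", "array_id"), names(kept)),
                 drop = FALSE]
  } else {
    seqs <- as.character(spacers)
    meta <- data.frame(row.names = seq_along(seqs))
  }
  n <- length(seqs)
  ref <- do.call(rbind, lapply(arrays, function(a)
    data.frame(array = a$array_id, index = seq_along(a$spacers),
               seq = a$spacers, stringsAsFactors = FALSE)))
  out <- data.frame(meta, sequence = seqs,
                    label = character(n), best_array = NA_character_,
                    best_index = NA_integer_, distance = NA_integer_,
                    stringsAsFactors = FALSE)
  if (n == 0) { out$label <- character(0); return(out) }

  qrc <- revcomp(seqs)
  # distance matrix n x nref, min over strand
  D <- matrix(Inf, n, nrow(ref))
  use_edit <- metric != "hamming"
  if (use_edit) {
    D <- pmin(adist(seqs, ref$seq), adist(qrc, ref$seq))
  }
  if (metric %in% c("mixed", "hamming")) {
    # override equal-length pairs with Hamming distance
    qlen <- nchar(seqs); rlen <- nchar(ref$seq)
    for (L in unique(rlen)) {
      qi <- which(qlen == L); ri <- which(rlen == L)
      if (!length(qi) || !length(ri)) next
      qmat <- matrix(unlist(strsplit(seqs[qi], "")), nrow = L)
      qmat_rc <- matrix(unlist(strsplit(qrc[qi], "")), nrow = L)
      for (r in ri) {
        rv <- strsplit(ref$seq[r], "")[[1]]
        hm <- pmin(colSums(qmat != rv), colSums(qmat_rc != rv))
        D[qi, r] <- hm
      }
    }
  }
  finite <- apply(D, 1, function(r) any(is.finite(r)))
  bestd <- apply(D, 1, min)
  # first (array order, index order) attaining the minimum; ref rows are
  # already in that order
  besti <- apply(D, 1, which.min)
  out$distance <- ifelse(finite, as.integer(bestd), NA_integer_)
  out$label <- ifelse(finite & bestd <= max_mismatches, "duplicate", "new")
  out$best_array <- ifelse(finite, ref$array[besti], NA_character_)
  out$best_index <- ifelse(finite, ref$index[besti], NA_integer_)
  out
}

#' Mutation spectrum of duplicated spacers
#'
#' Histogram of mismatch distances among spacers labelled `duplicate`, and
#' the fraction with multiple mutations (distance >= 2).
#'
#' @param classified data.frame from [classify_spacers()].
#' @return list with `histogram` (named integer vector, distance -> count)
#'   and `fraction_multi_mutated`.
#' @export
mutation_spectrum <- function(classified) {
  d <- classified$distance[classified$label == "duplicate"]
  hist <- table(factor(d, levels = sort(unique(d))))
  hist <- stats::setNames(as.integer(hist), names(hist))
  list(histogram = hist,
       fraction_multi_mutated = if (length(d)) mean(d >= 2) else NaN)
}

#' Per-array acquisition statistics
#'
#' Counts of new acquisitions and duplications per array (the array whose
#' amplicon the spacer was extracted from) and their ratio — the adaptation
#' activity statistic. The ratio is `NA` (undefined) when there are no
#' duplicates.
#'
#' @param classified data.frame from [classify_spacers()] containing an
#'   `array_id` column.
#' @return data.frame with `array_id`, `n_new`, `n_duplicate`,
#'   `new_to_duplicate_ratio`, `fraction_multi_mutated`.
#' @export
acquisition_stats <- function(classified) {
  stopifnot("array_id" %in% names(classified))
  split_by <- split(classified, classified$array_id)
  do.call(rbind, lapply(names(split_by), function(aid) {
    cl <- split_by[[aid]]
    n_new <- sum(cl$label == "new")
    n_dup <- sum(cl$label == "duplicate")
    spec <- mutation_spectrum(cl)
    data.frame(array_id = aid, n_new = n_new, n_duplicate = n_dup,
               new_to_duplicate_ratio =
                 if (n_dup > 0) n_new / n_dup else NA_real_,
               fraction_multi_mutated = spec$fraction_multi_mutated,
               stringsAsFactors = FALSE)
  }))
}
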