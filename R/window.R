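#' Call one read with the indicator-window method
#'
#' Cas-Analyzer-style calling: the read is searched for two 12-nt indicator
#' sequences bracketing the sgRNA target site at `R` bases either side of
#' the cut (see [window_indicators()]).  If both are found, the enclosed
#' segment is compared with the wild-type segment: a length deviation is an
#' indel of that signed size, an identical segment is `"wt"`, and an
#' equal-length but mismatching segment is a substitution-only call.  Reads
#' missing either indicator - typically because a deletion removed it - and
#' indels larger than the comparison range (`|size_delta| > R`) are
#' `"unmatched"`: this is how deletions exceeding `R` escape the caller
#' until a rerun with a larger `R`.
#'
#' The indel sequence is extracted by trimming the longest common prefix
#' and suffix against the wild-type segment and is reported in lower case.
#' Deletions whose trimmed region covers both cut sites of a two-sgRNA
#' amplicon (when `assay$paired_site` is set) are flagged
#' `spans_both_sites`.
#'
#' @param read Read sequence (uppercase ACGT string).
#' @param assay An [assay_definition()] with `ref_seq` covering the window.
#' @param R Comparison range in bp (default `assay$comparison_range_R`).
#' @return `"wt"`, `"unmatched"`, or a list of class `window_call` with
#'   `size_delta` (0 for a substitution-only call), `indel_sequence`,
#'   `substitution` flag and `spans_both_sites` flag.
#' @export
window_call_read <- function(read, assay, R = assay$comparison_range_R) {
  ind <- window_indicators(assay, R)
  l <- .first_match(read, ind$left)
  if (is.na(l)) return("unmatched")
  l2 <- .first_match(read, ind$left, from = l + 1L)
  if (!is.na(l2))
    warning("left indicator matches more than once; using first match")
  seg_start <- l + assay$indicator_length
  r <- .first_match(read, ind$right, from = seg_start)
  if (is.na(r)) return("unmatched")
  observed <- substr(read, seg_start, r - 1L)
  .window_classify(observed, ind, assay, R)
}

# Classify an observed inter-indicator segment against the WT segment.
.window_classify <- function(observed, ind, assay, R) {
  wt_seg <- ind$wt_segment
  delta <- nchar(observed) - nchar(wt_seg)
  if (delta == 0L && observed == wt_seg) return("wt")
  if (abs(delta) > R) return("unmatched")

  tr <- .trim_common(observed, wt_seg)
  if (delta == 0L) {
    return(structure(list(size_delta = 0L,
                          indel_sequence = NA_character_,
                          substitution = TRUE, spans_both_sites = FALSE),
                     class = "window_call"))
  }
  indel_seq <- if (delta < 0L) {
    substr(wt_seg, tr$prefix + 1L, nchar(wt_seg) - tr$suffix)
  } else {
    substr(observed, tr$prefix + 1L, nchar(observed) - tr$suffix)
  }
  spans <- FALSE
  if (delta < 0L && !is.null(assay$paired_site)) {
    del_start <- ind$wt_segment_start + tr$prefix
    del_end <- ind$wt_segment_start + (nchar(wt_seg) - tr$suffix) - 1L
    sites <- sort(c(assay$target_site, assay$paired_site))
    spans <- del_start <= sites[1L] && del_end >= sites[2L]
  }
  structure(list(size_delta = as.integer(delta),
                 indel_sequence = tolower(indel_seq),
                 substitution = FALSE, spans_both_sites = spans),
            class = "window_call")
}

# Longest common prefix / suffix lengths of two strings, with
# prefix + suffix capped at the shorter length (prefix wins ties).
.trim_common <- function(a, b) {
  na <- nchar(a); nb <- nchar(b); nmin <- min(na, nb)
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  p <- 0L
  while (p < nmin && av[p + 1L] == bv[p + 1L]) p <- p + 1L
  s <- 0L
  while (s < nmin - p && av[na - s] == bv[nb - s]) s <- s + 1L
  list(prefix = p, suffix = s)
}

#' Indel spectrum of a read set under the indicator-window method
#'
#' Vectorised window calling.  The denominator is the number of reads in
#' which both indicators were found and the segment deviation is within the
#' comparison range.  Substitution-only non-WT segments are tallied in a
#' separate `substitutions` bucket: they count towards the overall non-WT
#' frequency but are never reported as indel classes (the breakdown is
#' indels only).
#'
#' @param reads Character vector of read sequences or tibble with `seq`.
#' @param assay An [assay_definition()].
#' @param R Comparison range (default `assay$comparison_range_R`).
#' @param min_report_freq Reporting floor (default 0.00015, i.e. classes
#'   below 0.015 percent of callable reads are dropped from the breakdown).
#' @return An [indel_spectrum()].
#' @export
window_spectrum <- function(reads, assay, R = assay$comparison_range_R,
                            min_report_freq = 0.00015) {
  seqs <- if (is.character(reads)) reads else reads$seq
  total <- length(seqs)
  if (!total) stop("no reads supplied")
  if (assay$reverse_reads) seqs <- revcomp(seqs)
  ind <- window_indicators(assay, R)

  l <- .vmatch_first(seqs, ind$left)
  seg_start <- l + assay$indicator_length
  r <- .vmatch_after(seqs, ind$right, seg_start - 1L)
  found <- !is.na(l) & !is.na(r)

  observed <- substr(seqs[found], seg_start[found], r[found] - 1L)
  delta <- nchar(observed) - nchar(ind$wt_segment)
  in_range <- abs(delta) <= R
  callable_idx <- which(found)[in_range]
  observed <- observed[in_range]
  delta <- delta[in_range]
  if (!length(callable_idx))
    stop("no callable reads for assay '", assay$name,
         "' (indicators never co-occur within range R = ", R, ")")

  is_wt <- delta == 0L & observed == ind$wt_segment
  is_sub <- delta == 0L & !is_wt
  is_indel <- delta != 0L

  deltas <- integer(0); iseqs <- character(0); spans <- logical(0)
  if (any(is_indel)) {
    calls <- lapply(observed[is_indel], .window_classify,
                    ind = ind, assay = assay, R = R)
    deltas <- vapply(calls, `[[`, integer(1), "size_delta")
    iseqs <- vapply(calls, `[[`, character(1), "indel_sequence")
    spans <- vapply(calls, `[[`, logical(1), "spans_both_sites")
  }
  indel_spectrum(deltas,
                 callable_reads = length(callable_idx),
                 total_reads = total,
                 min_report_freq = min_report_freq,
                 indel_seqs = iseqs, spans = spans,
                 substitution_count = sum(is_sub),
                 assay_name = assay$name)
}

#' Merge a large-deletion rerun into a primary window spectrum
#'
#' Deletions larger than the comparison range are invisible to the primary
#' pass; a rerun with a larger `R` on the reads the primary pass left
#' unmatched recovers them.  This merge appends the rerun's calls, adds its
#' newly callable reads to the denominator, and recomputes every frequency
#' (and the reporting filter) over the union.  Merging can only increase
#' the overall non-WT frequency when the rerun contributes calls.
#'
#' @param primary Primary-pass [indel_spectrum()].
#' @param large_del Rerun spectrum computed on reads not callable in the
#'   primary pass (its `callable_reads` are treated as newly callable).
#' @return Merged [indel_spectrum()].
#' @export
merge_rerun <- function(primary, large_del) {
  stopifnot(inherits(primary, "indel_spectrum"))
  if (is.null(large_del)) return(primary)
  stopifnot(inherits(large_del, "indel_spectrum"))
  if (nrow(large_del$classes) == 0L && large_del$substitutions == 0L)
    return(primary)  # nothing recovered: spectrum unchanged

  a <- primary$classes[, c("size_delta", "count", "indel_sequence",
                           "spans_both_sites")]
  b <- large_del$classes[, c("size_delta", "count", "indel_sequence",
                             "spans_both_sites")]
  overlap <- intersect(a$size_delta, b$size_delta)
  if (length(overlap))
    warning("indel classes present in both spectra (",
            paste(overlap, collapse = ", "), "); counts summed")
  merged <- rbind(a, b)
  if (nrow(merged)) {
    merged <- do.call(rbind, lapply(split(merged, merged$size_delta),
      function(g) tibble::tibble(
        size_delta = g$size_delta[1L],
        count = sum(g$count),
        indel_sequence = {
          s <- unique(stats::na.omit(g$indel_sequence))
          if (!length(s)) NA_character_ else paste(s, collapse = " or ")
        },
        spans_both_sites = any(g$spans_both_sites))))
  }
  .build_spectrum(tibble::as_tibble(merged),
                  callable_reads = primary$callable_reads +
                    large_del$callable_reads,
                  total_reads = primary$total_reads,
                  min_report_freq = primary$min_report_freq,
                  substitution_count = primary$substitutions +
                    large_del$substitutions,
                  assay_name = primary$assay_name)
}

#' Window spectrum with an automatic large-deletion rerun
#'
#' Runs the primary window pass at `R`, then reruns at `rerun_R` on the
#' reads the primary pass could not call, and merges the two with
#' [merge_rerun()].
#'
#' @inheritParams window_spectrum
#' @param rerun_R Comparison range for the large-deletion rerun (e.g. 70).
#' @return Merged [indel_spectrum()].
#' @export
window_spectrum_with_rerun <- function(reads, assay,
                                       R = assay$comparison_range_R,
                                       rerun_R = 70L,
                                       min_report_freq = 0.00015) {
  seqs <- if (is.character(reads)) reads else reads$seq
  if (assay$reverse_reads) {
    seqs <- revcomp(seqs)
    assay$reverse_reads <- FALSE
  }
  primary <- window_spectrum(seqs, assay, R = R,
                             min_report_freq = min_report_freq)
  # reads the primary pass could not call
  ind <- window_indicators(assay, R)
  l <- .vmatch_first(seqs, ind$left)
  seg_start <- l + assay$indicator_length
  r <- .vmatch_after(seqs, ind$right, seg_start - 1L)
  found <- !is.na(l) & !is.na(r)
  in_range <- rep(FALSE, length(seqs))
  in_range[found] <- abs(nchar(substr(seqs[found], seg_start[found],
                                      r[found] - 1L)) -
                           nchar(ind$wt_segment)) <= R
  leftover <- seqs[!in_range]
  if (!length(leftover)) return(primary)
  rerun <- tryCatch(window_spectrum(leftover, assay, R = rerun_R,
                                    min_report_freq = 0),
                    error = function(e) NULL)
  merge_rerun(primary, rerun)
}
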