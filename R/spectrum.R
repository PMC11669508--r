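#' Indel spectrum container
#'
#' The common result type of the read-based callers and the CE peak
#' quantifier: a breakdown of indel classes (signed size delta, count,
#' frequency, extracted indel sequence) over the callable denominator,
#' plus the overall non-wild-type frequency.
#'
#' The reporting filter removes classes below `min_report_freq` from the
#' breakdown, but those sub-threshold reads are still counted in
#' `overall_non_wt_frequency` (they are non-WT reads, just not reportable
#' classes), so the overall figure can exceed the sum of the breakdown.
#'
#' @param deltas Integer vector of per-read signed size deltas (non-zero;
#'   one element per non-WT called read), or a pre-aggregated named count
#'   vector via `counts`.
#' @param callable_reads Number of reads on which the caller could operate
#'   (both anchors / both indicators found).
#' @param total_reads Total input reads.
#' @param min_report_freq Reporting floor as a fraction of callable reads.
#' @param indel_seqs Optional character vector parallel to `deltas` with the
#'   extracted indel sequence per read (lower-case).
#' @param spans Optional logical vector parallel to `deltas`: call spans
#'   both sgRNA sites of the amplicon.
#' @param substitution_count Reads that are non-WT by sequence but have size
#'   delta 0 (detected only by the window caller); counted in the overall
#'   figure under its own bucket, never as an indel class.
#' @param assay_name Label carried in the object.
#' @return An object of class `indel_spectrum` with elements `calls`
#'   (tibble `size_delta, count, frequency, indel_sequence,
#'   spans_both_sites`, sorted by descending frequency),
#'   `overall_non_wt_frequency`, `callable_reads`, `total_reads`,
#'   `substitutions` (count), `min_report_freq`, and `classes` (the
#'   unfiltered per-delta class table, used when merging spectra).
#' @export
indel_spectrum <- function(deltas, callable_reads, total_reads,
                           min_report_freq = 0.01,
                           indel_seqs = NULL, spans = NULL,
                           substitution_count = 0L,
                           assay_name = NA_character_) {
  if (callable_reads < 1L)
    stop("no callable reads for assay '", assay_name, "'")
  deltas <- as.integer(deltas)
  if (any(deltas == 0L)) stop("size_delta 0 cannot appear in indel calls")
  if (is.null(indel_seqs)) indel_seqs <- rep(NA_character_, length(deltas))
  if (is.null(spans)) spans <- rep(FALSE, length(deltas))

  hist <- table(deltas)
  all_deltas <- as.integer(names(hist))
  counts <- as.integer(hist)

  seq_by_class <- vapply(all_deltas, function(d) {
    s <- unique(tolower(stats::na.omit(indel_seqs[deltas == d])))
    if (!length(s)) NA_character_ else paste(s, collapse = " or ")
  }, character(1))
  spans_by_class <- vapply(all_deltas, function(d)
    any(spans[deltas == d]), logical(1))

  classes <- tibble::tibble(size_delta = all_deltas, count = counts,
                            indel_sequence = seq_by_class,
                            spans_both_sites = spans_by_class)
  .build_spectrum(classes, callable_reads, total_reads, min_report_freq,
                  substitution_count, assay_name)
}

# Assemble an indel_spectrum from an aggregated per-class count table.
# `classes`: tibble size_delta, count, indel_sequence, spans_both_sites.
.build_spectrum <- function(classes, callable_reads, total_reads,
                            min_report_freq, substitution_count,
                            assay_name) {
  classes$frequency <- classes$count / callable_reads
  classes <- classes[order(-classes$frequency, classes$size_delta), ]
  calls <- classes[classes$frequency >= min_report_freq,
                   c("size_delta", "count", "frequency", "indel_sequence",
                     "spans_both_sites")]
  overall <- (sum(classes$count) + substitution_count) / callable_reads
  structure(list(calls = calls,
                 overall_non_wt_frequency = overall,
                 callable_reads = as.integer(callable_reads),
                 total_reads = as.integer(total_reads),
                 substitutions = as.integer(substitution_count),
                 min_report_freq = min_report_freq,
                 classes = classes,
                 assay_name = assay_name),
            class = "indel_spectrum")
}

#' @export
print.indel_spectrum <- function(x, ...) {
  cat("Indel spectrum", if (!is.na(x$assay_name))
    paste0(" [", x$assay_name, "]"), ":\n", sep = "")
  cat(sprintf("  %d callable / %d total reads; overall non-WT %.1f%%\n",
              x$callable_reads, x$total_reads,
              100 * x$overall_non_wt_frequency))
  if (x$substitutions > 0L)
    cat(sprintf("  %d substitution-only non-WT reads (not in breakdown)\n",
                x$substitutions))
  if (nrow(x$calls)) print(x$calls) else
    cat("  no indel classes at or above the ",
        100 * x$min_report_freq, "% reporting floor\n", sep = "")
  invisible(x)
}

#' Write an indel spectrum as TSV plus a JSON summary
#'
#' The TSV holds the breakdown (`size_delta, count, frequency,
#' indel_sequence`); the JSON carries the overall figure and denominators.
#'
#' @param x An `indel_spectrum`.
#' @param tsv_path,json_path Output paths; either may be `NULL` to skip.
#' @return `x`, invisibly.
#' @export
write_spectrum <- function(x, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(x, "indel_spectrum"))
  if (!is.null(tsv_path)) {
    utils::write.table(
      x$calls[, c("size_delta", "count", "frequency", "indel_sequence")],
      tsv_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      assay = x$assay_name,
      overall_non_wt_frequency = x$overall_non_wt_frequency,
      callable_reads = x$callable_reads,
      total_reads = x$total_reads,
      substitutions = x$substitutions,
      min_report_freq = x$min_report_freq),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(x)
}
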