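#' Call one read with the conserved-sequence (CS) method
#'
#' Searches the read for an exact match of the assay primer and then for an
#' exact match of the conserved sequence downstream of the primer.  If both
#' are found, the indel size is the deviation of the observed
#' start-to-start distance from the wild-type distance; reads matching the
#' wild-type distance are "wt", reads missing either anchor (for example
#' because a deletion removed the conserved sequence) are "uncallable".
#' Matching is exact by design; should an anchor occur more than once, the
#' first occurrence (downstream of the primer, for the conserved sequence)
#' is used and a warning is emitted.
#'
#' @param read A read sequence (uppercase ACGT string).
#' @param assay An [assay_definition()].
#' @return Integer size delta for an indel-bearing read, `"wt"`, or
#'   `"uncallable"`.
#' @examples
#' ref <- strrep("ACGTATGCCT", 20)
#' asy <- assay_definition("x", ref, substr(ref, 1, 18),
#'                         substr(ref, 121, 138), target_site = 80)
#' cs_call_read(ref, asy)
#' @export
cs_call_read <- function(read, assay) {
  stopifnot(nzchar(read))
  p <- .first_match(read, assay$primer)
  if (is.na(p)) return("uncallable")
  cs <- .first_match(read, assay$conserved_seq, from = p + 1L)
  if (is.na(cs)) return("uncallable")
  cs2 <- .first_match(read, assay$conserved_seq, from = cs + 1L)
  if (!is.na(cs2))
    warning("conserved sequence matches more than once; using first match")
  delta <- (cs - p) - assay$wt_distance
  if (delta == 0L) "wt" else as.integer(delta)
}

#' Indel spectrum of a read set under the CS method
#'
#' Vectorised CS calling over a read set.  The denominator of every
#' frequency is the number of callable reads (both anchors found).  Size
#' classes below `min_report_freq` are dropped from the breakdown but their
#' reads remain in the overall non-WT frequency; the breakdown is sorted by
#' descending frequency.
#'
#' @param reads Character vector of read sequences, or a tibble with a
#'   `seq` column (as returned by [read_fastq()] / [simulate_reads()]).
#' @param assay An [assay_definition()].  When `assay$reverse_reads` is
#'   `TRUE` the reads are reverse-complemented before calling.
#' @param min_report_freq Reporting floor (default 0.01, i.e. deviations
#'   below 1 percent of callable reads are not reported as classes).
#' @return An [indel_spectrum()].
#' @export
cs_spectrum <- function(reads, assay, min_report_freq = 0.01) {
  seqs <- if (is.character(reads)) reads else reads$seq
  total <- length(seqs)
  if (!total) stop("no reads supplied")
  if (assay$reverse_reads) seqs <- revcomp(seqs)

  p <- .vmatch_first(seqs, assay$primer)
  cs <- .vmatch_after(seqs, assay$conserved_seq, p)
  callable <- !is.na(p) & !is.na(cs)
  if (!any(callable))
    stop("no callable reads for assay '", assay$name,
         "' (primer/conserved sequence never co-occur)")
  deltas <- (cs[callable] - p[callable]) - assay$wt_distance
  indel_spectrum(deltas[deltas != 0L],
                 callable_reads = sum(callable),
                 total_reads = total,
                 min_report_freq = min_report_freq,
                 assay_name = assay$name)
}

# Vectorised first exact occurrence (1-based; NA if absent).
.vmatch_first <- function(seqs, pattern) {
  m <- regexpr(pattern, seqs, fixed = TRUE)
  out <- as.integer(m)
  out[out < 0L] <- NA_integer_
  out
}

# Vectorised first occurrence strictly after position `from` (per element).
.vmatch_after <- function(seqs, pattern, from) {
  out <- rep(NA_integer_, length(seqs))
  ok <- !is.na(from)
  if (!any(ok)) return(out)
  tails <- substr(seqs[ok], from[ok] + 1L, nchar(seqs[ok]))
  m <- regexpr(pattern, tails, fixed = TRUE)
  pos <- as.integer(m)
  pos[pos < 0L] <- NA_integer_
  out[ok] <- pos + from[ok]
  out
}
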