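#' Define a genotyping assay for one sgRNA target
#'
#' An assay definition bundles everything the read-based callers need to know
#' about one sgRNA target site: the anchor sequences used by the
#' conserved-sequence (CS) caller, the wild-type amplicon geometry, and the
#' parameters of the indicator-window caller (comparison range `R`, indicator
#' placement relative to the cut site).
#'
#' The CS caller anchors each read on an exact match of `primer` and then on
#' an exact match of `conserved_seq`; `wt_distance` is the start-to-start
#' distance (bp) between the two matches in an unedited read.  The window
#' caller brackets the cut site with two 12-nt indicator sequences taken from
#' `ref_seq` at `comparison_range_R` bases either side of `target_site`, and
#' compares the enclosed segment to the wild-type segment.
#'
#' @param name Assay name (e.g. the sgRNA identifier).
#' @param ref_seq Wild-type amplicon sequence (uppercase ACGT), forward
#'   orientation.  Anchors and indicators are located on this sequence.
#' @param primer 5' primer sequence expected at the start of forward reads.
#' @param conserved_seq Conserved sequence expected downstream of the primer.
#' @param target_site 1-based position of the Cas9 cut site in `ref_seq`
#'   (the blunt cut falls between `target_site` and `target_site + 1`).
#' @param comparison_range_R Window-caller comparison range in bp (default
#'   35).  Indicators are placed `R` bases from the cut site and indels with
#'   `|size_delta| > R` are not callable.
#' @param indicator_length Length of each indicator sequence (default 12 nt).
#' @param wt_distance Expected primer-to-conserved-sequence distance in WT
#'   reads; computed from `ref_seq` when not supplied.
#' @param expected_wt_amplicon_lengths Integer vector of wild-type amplicon
#'   lengths (bp); defaults to `nchar(ref_seq)`.  Multi-length WT amplicon
#'   pools (e.g. 226/227/231 bp) list all lengths here.
#' @param paired_site Optional 1-based cut position of a second sgRNA site
#'   sharing the amplicon (used to flag deletions spanning both sites).
#' @param reverse_reads Set `TRUE` for assays read from the reverse strand;
#'   the read stream is reverse-complemented before calling.
#'
#' @return An object of class `assay_definition`.
#' @examples
#' ref <- paste(rep("ACGT", 60), collapse = "")
#' asy <- assay_definition("demo", ref_seq = ref,
#'                         primer = substr(ref, 1, 20),
#'                         conserved_seq = substr(ref, 121, 140),
#'                         target_site = 60)
#' asy$wt_distance
#' @export
assay_definition <- function(name, ref_seq, primer, conserved_seq,
                             target_site,
                             comparison_range_R = 35L,
                             indicator_length = 12L,
                             wt_distance = NULL,
                             expected_wt_amplicon_lengths = NULL,
                             paired_site = NULL,
                             reverse_reads = FALSE) {
  ref_seq       <- toupper(ref_seq)
  primer        <- toupper(primer)
  conserved_seq <- toupper(conserved_seq)
  .check_dna(ref_seq, "ref_seq")
  .check_dna(primer, "primer")
  .check_dna(conserved_seq, "conserved_seq")
  stopifnot(nzchar(primer), nzchar(conserved_seq),
            target_site >= 1, target_site < nchar(ref_seq),
            comparison_range_R >= 1)

  p_pos  <- .first_match(ref_seq, primer)
  cs_pos <- .first_match(ref_seq, conserved_seq)
  if (is.na(p_pos))
    stop("primer has no exact match in ref_seq for assay '", name, "'")
  if (is.na(cs_pos))
    stop("conserved_seq has no exact match in ref_seq for assay '", name, "'")
  if (is.null(wt_distance)) wt_distance <- cs_pos - p_pos
  if (wt_distance <= nchar(primer))
    stop("wt_distance must exceed the primer length (assay '", name, "')")

  if (is.null(expected_wt_amplicon_lengths))
    expected_wt_amplicon_lengths <- nchar(ref_seq)

  structure(list(
    name = name,
    ref_seq = ref_seq,
    primer = primer,
    conserved_seq = conserved_seq,
    wt_distance = as.integer(wt_distance),
    target_site = as.integer(target_site),
    comparison_range_R = as.integer(comparison_range_R),
    indicator_length = as.integer(indicator_length),
    expected_wt_amplicon_lengths = as.integer(expected_wt_amplicon_lengths),
    paired_site = if (is.null(paired_site)) NULL else as.integer(paired_site),
    reverse_reads = isTRUE(reverse_reads)
  ), class = "assay_definition")
}

#' Read an assay definition from a YAML or JSON file
#'
#' The file holds the fields of [assay_definition()] as top-level keys.
#' Format is chosen by extension (`.yaml`/`.yml` vs `.json`).
#'
#' @param path Path to the assay file.
#' @return An `assay_definition`.
#' @export
read_assay <- function(path) {
  ext <- tolower(tools::file_ext(path))
  spec <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
          else stop("unrecognised assay file extension: .", ext)
  keep <- intersect(names(spec), names(formals(assay_definition)))
  do.call(assay_definition, spec[keep])
}

#' Indicator sequences for a window-caller pass
#'
#' Extracts the two flanking indicator sequences from the assay's wild-type
#' amplicon for a given comparison range `R`: the left indicator ends `R`
#' bases before the cut site, the right indicator starts `R` bases after it.
#' Rerunning with a larger `R` (e.g. 70 bp instead of 35 bp) moves the
#' indicators outwards so that larger deletions fall inside the window.
#'
#' @param assay An `assay_definition`.
#' @param R Comparison range in bp; defaults to the assay's
#'   `comparison_range_R`.
#' @return A list with `left`, `right` (indicator strings) and `wt_segment`,
#'   the wild-type sequence enclosed between them.
#' @export
window_indicators <- function(assay, R = assay$comparison_range_R) {
  len <- assay$indicator_length
  cut <- assay$target_site
  l_start <- cut - R - len + 1L
  r_start <- cut + R + 1L
  if (l_start < 1L || r_start + len - 1L > nchar(assay$ref_seq))
    stop("comparison range R = ", R, " places an indicator outside the ",
         "amplicon for assay '", assay$name, "'")
  list(
    left  = substr(assay$ref_seq, l_start, l_start + len - 1L),
    right = substr(assay$ref_seq, r_start, r_start + len - 1L),
    wt_segment = substr(assay$ref_seq, l_start + len, r_start - 1L),
    wt_segment_start = l_start + len
  )
}

#' @export
print.assay_definition <- function(x, ...) {
  cat("Assay '", x$name, "': ", nchar(x$ref_seq), " bp amplicon, cut site at ",
      x$target_site, "\n", sep = "")
  cat("  primer ", nchar(x$primer), " nt, conserved seq ",
      nchar(x$conserved_seq), " nt, WT anchor distance ", x$wt_distance,
      " bp\n", sep = "")
  cat("  window R = ", x$comparison_range_R, " bp, indicators ",
      x$indicator_length, " nt\n", sep = "")
  invisible(x)
}

.check_dna <- function(x, what) {
  if (length(x) != 1L || is.na(x) || grepl("[^ACGT]", x))
    stop(what, " must be a single uppercase ACGT string")
  invisible(TRUE)
}

# First exact occurrence (1-based) of `pattern` in `x` at or after `from`;
# NA when absent.
.first_match <- function(x, pattern, from = 1L) {
  if (from > 1L) {
    p <- regexpr(pattern, substr(x, from, nchar(x)), fixed = TRUE)
    if (p < 0) return(NA_integer_)
    as.integer(p) + from - 1L
  } else {
    p <- regexpr(pattern, x, fixed = TRUE)
    if (p < 0) NA_integer_ else as.integer(p)
  }
}

#' Reverse-complement a DNA string vector
#'
#' @param x Character vector of ACGT(N) sequences.
#' @return Reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}
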