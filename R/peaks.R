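#' Fragment-analysis peak table
#'
#' A capillary-electrophoresis peak table for one sample: fragment sizes in
#' bp (as sized against the internal standard, so generally non-integer)
#' and peak heights in fluorescence units.
#'
#' @param sample Sample label.
#' @param size_bp Numeric vector of peak sizes (bp).
#' @param height Numeric vector of peak heights (> 0).
#' @return A `peak_table` tibble with columns `sample`, `size_bp`, `height`,
#'   sorted by size.
#' @export
peak_table <- function(sample, size_bp, height) {
  stopifnot(length(size_bp) == length(height))
  if (any(height <= 0)) stop("peak heights must be positive")
  if (anyDuplicated(size_bp)) stop("peak sizes must be distinct")
  ord <- order(size_bp)
  structure(tibble::tibble(sample = sample, size_bp = size_bp[ord],
                           height = height[ord]),
            class = c("peak_table", "tbl_df", "tbl", "data.frame"))
}

#' Read peak tables from CSV
#'
#' Expects columns `sample,size_bp,height`; returns one `peak_table` per
#' sample.
#'
#' @param path CSV path.
#' @return Named list of [peak_table()]s.
#' @export
read_peak_tables <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "size_bp", "height") %in% names(df)))
  lapply(split(df, df$sample),
         function(g) peak_table(g$sample[1L], g$size_bp, g$height))
}

#' Define the wild-type peak set from a WT sample
#'
#' Wild-type amplicon pools can present several peaks (intron-derived
#' length variants, e.g. a main 227 bp peak with satellites at 226 and
#' 231 bp).  Every WT peak at or above `min_rel_height` of the tallest peak
#' becomes a WT size; in mutant samples, peaks matching any of those sizes
#' are treated as wild type.  The tallest peak is the main WT size against
#' which indel deltas are measured.
#'
#' @param wt_table [peak_table()] of the wild-type sample.
#' @param min_rel_height Minimum height relative to the tallest peak for a
#'   WT peak to enter the reference set (default 0.1).
#' @param match_tolerance Size-matching tolerance in bp used downstream
#'   (default 0.5; CE sizing scatter is sub-bp).
#' @return A `wt_reference` list with `wt_peak_sizes`, `main_wt_size`,
#'   `match_tolerance`.
#' @export
define_wt_peaks <- function(wt_table, min_rel_height = 0.1,
                            match_tolerance = 0.5) {
  if (!nrow(wt_table)) stop("empty WT peak table")
  stopifnot(min_rel_height > 0, min_rel_height <= 1, match_tolerance > 0)
  keep <- wt_table$height >= min_rel_height * max(wt_table$height)
  sizes <- wt_table$size_bp[keep]
  main <- wt_table$size_bp[which.max(wt_table$height)]
  structure(list(wt_peak_sizes = sizes, main_wt_size = main,
                 match_tolerance = match_tolerance),
            class = "wt_reference")
}

#' Classify sample peaks against the wild-type reference
#'
#' A peak within `match_tolerance` of any WT size is labelled `"wt"` -
#' including, by design, true 1 bp deletion peaks that coincide with a
#' secondary WT length variant (the documented CE undercall).  Any other
#' peak is an indel of size `round(size - main_wt_size)`; sizes are rounded
#' to the nearest integer bp (a 7.56 bp deviation reports as 8).
#'
#' @param sample_table [peak_table()] of the sample.
#' @param ref [define_wt_peaks()] reference.
#' @param min_height_frac Peaks below this fraction of total height are
#'   dropped as baseline noise before classification (default 0.01).
#' @return The peak table with added columns `label` (`"wt"` or the signed
#'   delta as character) and `size_delta` (integer, `NA` for WT).
#' @export
classify_peaks <- function(sample_table, ref, min_height_frac = 0.01) {
  stopifnot(inherits(ref, "wt_reference"))
  tab <- sample_table[sample_table$height >=
                        min_height_frac * sum(sample_table$height), ]
  is_wt <- vapply(tab$size_bp, function(s)
    any(abs(s - ref$wt_peak_sizes) <= ref$match_tolerance), logical(1))
  delta <- ifelse(is_wt, NA_integer_,
                  as.integer(round(tab$size_bp - ref$main_wt_size)))
  tab$label <- ifelse(is_wt, "wt", sprintf("%+d", delta))
  tab$size_delta <- delta
  tab
}

#' Co-editing percentage from peak heights
#'
#' The estimated co-editing percentage is
#' `100 * (total height - WT height) / total height`, where the WT height
#' sums every peak labelled wild type (all WT-size peaks, not just the main
#' one, when the WT sample showed several).
#'
#' @inheritParams classify_peaks
#' @return Percentage in `[0, 100]`.
#' @export
co_editing_percent <- function(sample_table, ref, min_height_frac = 0.01) {
  tab <- classify_peaks(sample_table, ref, min_height_frac)
  total <- sum(tab$height)
  if (total <= 0) stop("zero total peak height")
  100 * (total - sum(tab$height[tab$label == "wt"])) / total
}

#' Per-indel frequencies from a peak table
#'
#' Each non-WT label's frequency is its summed peak height over the total
#' height; the overall non-WT frequency equals [co_editing_percent()] / 100
#' by construction (height is conserved across labels).
#'
#' @inheritParams classify_peaks
#' @return An [indel_spectrum()] with frequencies as fractions of total
#'   peak height; `callable_reads`/`total_reads` hold the (rounded) total
#'   height as the signal denominator.
#' @export
indel_frequencies <- function(sample_table, ref, min_height_frac = 0.01) {
  tab <- classify_peaks(sample_table, ref, min_height_frac)
  total <- sum(tab$height)
  if (total <= 0) stop("zero total peak height")
  mut <- tab[tab$label != "wt", ]
  classes <- if (nrow(mut)) {
    agg <- stats::aggregate(height ~ size_delta, data = mut, FUN = sum)
    tibble::tibble(size_delta = as.integer(agg$size_delta),
                   count = agg$height,
                   indel_sequence = NA_character_,
                   spans_both_sites = FALSE)
  } else {
    tibble::tibble(size_delta = integer(), count = numeric(),
                   indel_sequence = character(), spans_both_sites = logical())
  }
  .build_spectrum(classes, callable_reads = total, total_reads = total,
                  min_report_freq = 0, substitution_count = 0L,
                  assay_name = sample_table$sample[1L])
}
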