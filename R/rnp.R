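#' Gel lane measurements for an RNP cleavage assay
#'
#' Band densitometry (mean grey values, GV) for one sample lane of an
#' in-vitro Cas9 ribonucleoprotein digestion: one or two cleaved products,
#' an un-cleaved product (absent when cleavage is complete... or when a
#' large indel shifted the amplicon), and any bands not matching the
#' expected sizes.
#'
#' @param sample Lane label.
#' @param cleaved_gvs Numeric vector (length 1 or 2) of mean grey values of
#'   the expected cleaved products; may be empty if no cleaved band.
#' @param uncleaved_gv Mean grey value of the un-cleaved product, or `NA`
#'   when the band is absent.
#' @param expected_cleaved_sizes,expected_uncleaved_size Expected band
#'   sizes in bp.
#' @param extra_bands Optional data frame `size_bp, gv` of observed bands
#'   matching neither expectation (triggers score 5).
#' @return A `gel_lane` list.
#' @export
gel_lane <- function(sample, cleaved_gvs, uncleaved_gv = NA_real_,
                     expected_cleaved_sizes = NULL,
                     expected_uncleaved_size = NULL,
                     extra_bands = NULL) {
  cleaved_gvs <- as.numeric(cleaved_gvs)
  if (length(cleaved_gvs) > 2L)
    stop("at most two cleaved products are supported")
  if (any(cleaved_gvs < 0, na.rm = TRUE) ||
      (!is.na(uncleaved_gv) && uncleaved_gv < 0))
    stop("grey values must be non-negative")
  if (!length(cleaved_gvs) && is.na(uncleaved_gv) && is.null(extra_bands))
    stop("lane has no bands")
  if (!is.null(extra_bands)) {
    extra_bands <- as.data.frame(extra_bands)
    stopifnot(all(c("size_bp", "gv") %in% names(extra_bands)))
  }
  structure(list(sample = sample, cleaved_gvs = cleaved_gvs,
                 uncleaved_gv = uncleaved_gv,
                 expected_cleaved_sizes = expected_cleaved_sizes,
                 expected_uncleaved_size = expected_uncleaved_size,
                 extra_bands = extra_bands),
            class = "gel_lane")
}

#' Read gel lanes from CSV
#'
#' Long format, columns `sample,band,expected_size_bp,mean_gv` where `band`
#' is `cleaved`, `uncleaved` or `extra`.
#'
#' @param path CSV path.
#' @return Named list of [gel_lane()]s.
#' @export
read_gel_lanes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "band", "expected_size_bp", "mean_gv")
                %in% names(df)))
  lapply(split(df, df$sample), function(g) {
    cl <- g[g$band == "cleaved", ]
    un <- g[g$band == "uncleaved", ]
    ex <- g[g$band == "extra", ]
    gel_lane(sample = g$sample[1L],
             cleaved_gvs = cl$mean_gv,
             uncleaved_gv = if (nrow(un)) un$mean_gv[1L] else NA_real_,
             expected_cleaved_sizes = cl$expected_size_bp,
             expected_uncleaved_size = if (nrow(un))
               un$expected_size_bp[1L] else NULL,
             extra_bands = if (nrow(ex))
               data.frame(size_bp = ex$expected_size_bp, gv = ex$mean_gv)
             else NULL)
  })
}

#' Grey-value difference of a gel lane
#'
#' `delta_gv = mean GV of the cleaved product(s) - GV of the un-cleaved
#' product`.  With two cleaved products their mean grey value is used.  An
#' absent un-cleaved band contributes 0 (lanes with only a cleaved product
#' are still scorable).  Note the convention: a strongly *negative* delta
#' indicates a fully cleavable, unmutated template.
#'
#' @param lane A [gel_lane()].
#' @return Numeric delta GV, or `NA` when no cleaved band exists (handled
#'   by the score-5 rule in [rnp_score()]).
#' @export
delta_gv <- function(lane) {
  stopifnot(inherits(lane, "gel_lane"))
  if (!length(lane$cleaved_gvs)) return(NA_real_)
  un <- if (is.na(lane$uncleaved_gv)) 0 else lane$uncleaved_gv
  mean(lane$cleaved_gvs) - un
}

# Single-product score thresholds on floor(delta_gv); dual-product
# thresholds are the same cut points scaled by 2/3 (two cleaved products
# halve the per-band signal relative to the pooled un-cleaved band).
.rnp_cuts_single <- c(-90, -31, -30, 30, 31, 90)
.rnp_cuts_dual   <- c(-60, -21, -20, 20, 21, 60)

.rnp_bands <- c("0" = "0%", "1" = "<40%", "2" = "~50%", "3" = ">60%",
                "4" = "100%", "5" = "100% large indel")

#' Categorical mutation score of an RNP assay lane
#'
#' Maps the lane's grey-value difference onto the 0-4 co-mutation score:
#' for a single cleaved product, delta GV below -90 scores 0 (no
#' mutations), -90 to -31 scores 1 (< 40 percent co-mutated), -30 to 30
#' scores 2 (~50 percent), 31 to 90 scores 3 (> 60 percent) and above 90
#' scores 4 (100 percent).  With two cleaved products the adjusted cut
#' points -60/-21/-20/20/21/60 apply.  Real-valued deltas are floored to
#' integers first, so values falling in the gaps between printed ranges
#' take the lower score.
#'
#' Score 5 (100 percent mutated with a large indel) is assigned when the
#' lane shows a band matching neither the expected cleaved nor un-cleaved
#' size (within `size_tolerance` of expectation), or no band at any
#' expected size at all.
#'
#' @param lane A [gel_lane()].
#' @param size_tolerance Relative band-size matching tolerance for the
#'   score-5 rule (default 0.05, i.e. +/- 5 percent of expected size).
#' @return An `rnp_score` list with `score` (integer 0-5), `delta_gv`
#'   (`NA` for score 5 without a cleaved band) and `frequency_band`.
#' @export
rnp_score <- function(lane, size_tolerance = 0.05) {
  stopifnot(inherits(lane, "gel_lane"))
  if (!is.null(lane$extra_bands) && nrow(lane$extra_bands)) {
    expected <- c(lane$expected_cleaved_sizes, lane$expected_uncleaved_size)
    if (!length(expected))
      stop("lane '", lane$sample, "' has extra bands but no expected sizes")
    unmatched <- vapply(lane$extra_bands$size_bp, function(s)
      all(abs(s - expected) > size_tolerance * expected), logical(1))
    if (any(unmatched))
      return(.rnp_result(5L, delta_gv(lane)))
  }
  if (!length(lane$cleaved_gvs)) {
    if (is.na(lane$uncleaved_gv))
      return(.rnp_result(5L, NA_real_))
    # only the un-cleaved product present: nothing cleavable remains
    return(.rnp_result(4L, NA_real_))
  }
  dgv <- delta_gv(lane)
  cuts <- if (length(lane$cleaved_gvs) == 2L) .rnp_cuts_dual
          else .rnp_cuts_single
  x <- floor(dgv)
  score <- if (x < cuts[1L]) 0L
    else if (x <= cuts[2L]) 1L
    else if (x <= cuts[4L]) 2L      # gap values fall to the lower score
    else if (x <= cuts[6L]) 3L
    else 4L
  .rnp_result(score, dgv)
}

.rnp_result <- function(score, dgv) {
  structure(list(score = score, delta_gv = dgv,
                 frequency_band = unname(.rnp_bands[as.character(score)])),
            class = "rnp_score")
}

#' @export
print.rnp_score <- function(x, ...) {
  cat(sprintf("RNP score %d (%s)%s\n", x$score, x$frequency_band,
              if (is.na(x$delta_gv)) "" else
                sprintf(", delta GV = %.1f", x$delta_gv)))
  invisible(x)
}
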