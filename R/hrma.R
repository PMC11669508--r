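#' Assemble a melt-curve set
#'
#' Bundles long-format melt traces (`sample, replicate, temp_c,
#' fluorescence`) with the identity of the wild-type reference samples.
#' All traces must share one temperature grid; the WT samples (typically
#' two, run in triplicate) define the baseline for difference curves.
#'
#' @param curves Long-format data frame / tibble of traces.
#' @param wt_sample_ids Character vector of sample labels to treat as the
#'   wild-type genotype.
#' @return A `melt_curve_set` list with `curves` and `wt_sample_ids`.
#' @export
melt_curve_set <- function(curves, wt_sample_ids) {
  curves <- tibble::as_tibble(curves)
  stopifnot(all(c("sample", "replicate", "temp_c", "fluorescence")
                %in% names(curves)))
  if (!length(wt_sample_ids))
    stop("at least one WT sample is required for difference analysis")
  if (!all(wt_sample_ids %in% curves$sample))
    stop("WT sample(s) not present in the curves: ",
         paste(setdiff(wt_sample_ids, curves$sample), collapse = ", "))
  grids <- split(curves$temp_c, interaction(curves$sample, curves$replicate,
                                            drop = TRUE))
  ref <- sort(grids[[1L]])
  if (anyDuplicated(ref))
    stop("duplicated temperatures within a trace")
  if (!all(vapply(grids, function(g)
    length(g) == length(ref) && all(sort(g) == ref), logical(1))))
    stop("all traces must share one temperature grid")
  structure(list(curves = curves, wt_sample_ids = wt_sample_ids,
                 temp_grid = ref),
            class = "melt_curve_set")
}

#' Read a melt-curve CSV into a melt-curve set
#'
#' @param path Long-format CSV `sample,replicate,temp_c,fluorescence`.
#' @param wt_sample_ids WT sample labels.
#' @return A [melt_curve_set()].
#' @export
read_melt_curves <- function(path, wt_sample_ids) {
  melt_curve_set(utils::read.csv(path, stringsAsFactors = FALSE),
                 wt_sample_ids)
}

#' Melt-peak temperatures of one trace
#'
#' Smooths the negative derivative -dF/dT with a centred moving average
#' and reports the temperatures of its peaks to 0.1 degrees C.  Multi-Tm
#' samples (mixtures of alleles with distinct melting temperatures) return
#' one temperature per derivative peak.
#'
#' @param temp_c Temperature grid (degrees C, increasing).
#' @param fluorescence Fluorescence trace on that grid.
#' @param smoothing_window Moving-average window in grid points (odd;
#'   default 5).
#' @param min_prominence Minimum peak height as a fraction of the maximum
#'   derivative (default 0.1, which sits safely above the derivative noise
#'   floor of replicate-level traces while keeping 10 percent mixture
#'   components detectable).
#' @return Numeric vector of peak temperatures (possibly empty, with a
#'   warning when no peak clears the prominence floor).
#' @export
melt_peaks <- function(temp_c, fluorescence, smoothing_window = 5L,
                       min_prominence = 0.1) {
  stopifnot(length(temp_c) == length(fluorescence), length(temp_c) >= 3L)
  smooth <- function(x) {
    if (smoothing_window <= 1L) return(x)
    k <- rep(1 / smoothing_window, smoothing_window)
    as.numeric(stats::filter(x, k, sides = 2))
  }
  f <- smooth(fluorescence)
  d <- -diff(f) / diff(temp_c)
  mid <- (temp_c[-1L] + temp_c[-length(temp_c)]) / 2
  d <- smooth(d)  # second pass keeps derivative noise below the floor
  keep <- !is.na(d)
  d <- d[keep]; mid <- mid[keep]
  if (!length(d) || max(d) <= 0) {
    warning("no melt transition found (flat or rising trace)")
    return(numeric(0))
  }
  idx <- .plateau_peaks(d, min_height = min_prominence * max(d))
  if (!length(idx)) {
    warning("no derivative peak above the prominence floor")
    return(numeric(0))
  }
  sort(round(mid[idx], 1L))
}

# Local maxima tolerant of flat tops: symmetric smoothing of a symmetric
# transition produces exact two-point plateaus at the apex, which strict
# peak finders skip.  Runs of equal value are compressed and a run is a
# peak when both neighbouring runs are lower; the plateau midpoint is
# reported.
.plateau_peaks <- function(d, min_height) {
  r <- rle(d)
  v <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(v)
  if (k < 3L) return(integer(0))
  i <- 2:(k - 1L)
  pk <- i[v[i] > v[i - 1L] & v[i] > v[i + 1L] & v[i] >= min_height]
  as.integer(floor((starts[pk] + ends[pk]) / 2))
}

#' Two-point normalization of a melt trace
#'
#' Linearly rescales fluorescence so that the mean within the
#' pre-melt window maps to 100 and the mean within the post-melt window
#' maps to 0, removing per-well gain and offset differences.  The map is
#' affine-invariant and idempotent.
#'
#' @param temp_c,fluorescence Trace.
#' @param pre_window,post_window Temperature intervals `c(lo, hi)` before
#'   and after the melt transition.
#' @return Normalized fluorescence vector.
#' @export
normalize_melt <- function(temp_c, fluorescence, pre_window, post_window) {
  stopifnot(pre_window[1L] < pre_window[2L],
            post_window[1L] < post_window[2L],
            pre_window[2L] <= post_window[1L])
  pre <- temp_c >= pre_window[1L] & temp_c <= pre_window[2L]
  post <- temp_c >= post_window[1L] & temp_c <= post_window[2L]
  if (!any(pre) || !any(post))
    stop("normalization window falls outside the temperature grid")
  hi <- mean(fluorescence[pre]); lo <- mean(fluorescence[post])
  if (abs(hi - lo) < .Machine$double.eps^0.5)
    stop("degenerate normalization windows (equal mean fluorescence)")
  100 * (fluorescence - lo) / (hi - lo)
}

#' HRMA difference curves against the wild-type baseline
#'
#' Normalizes every replicate trace ([normalize_melt()]), averages the
#' wild-type replicates into a baseline, and reports per sample the mean
#' normalized curve, its difference to the baseline, the maximum absolute
#' fluorescence difference, and the melt-peak temperatures of the raw mean
#' trace.
#'
#' @param set A [melt_curve_set()].
#' @param pre_window,post_window Normalization windows; default to the
#'   first and last 1 degree C of the acquisition range.
#' @param ... Passed on to [melt_peaks()].
#' @return An `hrma_result` list: `summary` tibble (`sample`,
#'   `max_fluor_diff`, `melt_peak_temps` as comma-joined string),
#'   `difference` tibble (`sample, temp_c, diff`), `normalized` tibble,
#'   and `temp_grid`.
#' @export
difference_curves <- function(set,
                              pre_window = NULL, post_window = NULL, ...) {
  stopifnot(inherits(set, "melt_curve_set"))
  grid <- set$temp_grid
  if (is.null(pre_window)) pre_window <- c(grid[1L], grid[1L] + 1)
  if (is.null(post_window))
    post_window <- c(grid[length(grid)] - 1, grid[length(grid)])

  cur <- set$curves
  key <- interaction(cur$sample, cur$replicate, drop = TRUE)
  cur$norm <- NA_real_
  for (i in split(seq_len(nrow(cur)), key)) {
    cur$norm[i] <- normalize_melt(cur$temp_c[i], cur$fluorescence[i],
                                  pre_window, post_window)
  }
  # per-sample mean of replicates, in grid order (grid values are exact
  # copies of the trace temperatures, so match() is safe)
  sample_mean <- function(column) {
    vapply(samples, function(s) {
      sub <- cur[cur$sample == s, ]
      reps <- split(sub, sub$replicate)
      rowMeans(vapply(reps, function(g)
        g[[column]][match(grid, g$temp_c)], numeric(length(grid))))
    }, numeric(length(grid)))
  }
  samples <- unique(cur$sample)
  mean_norm <- sample_mean("norm")
  baseline <- rowMeans(mean_norm[, set$wt_sample_ids, drop = FALSE])

  diffs <- mean_norm - baseline
  raw_mean <- sample_mean("fluorescence")
  peaks <- lapply(samples, function(s)
    melt_peaks(grid, raw_mean[, s], ...))

  summary <- tibble::tibble(
    sample = samples,
    max_fluor_diff = apply(abs(diffs), 2L, max),
    melt_peak_temps = vapply(peaks, function(p)
      paste(sprintf("%.1f", p), collapse = ", "), character(1)))
  difference <- tibble::tibble(
    sample = rep(samples, each = length(grid)),
    temp_c = rep(grid, length(samples)),
    diff = as.vector(diffs))
  normalized <- tibble::tibble(
    sample = rep(samples, each = length(grid)),
    temp_c = rep(grid, length(samples)),
    fluorescence = as.vector(mean_norm))
  structure(list(summary = summary, difference = difference,
                 normalized = normalized, temp_grid = grid,
                 melt_peak_temps = stats::setNames(peaks, samples)),
            class = "hrma_result")
}

#' @export
print.hrma_result <- function(x, ...) {
  cat("HRMA result over", length(x$temp_grid), "temperature points\n")
  print(x$summary, ...)
  invisible(x)
}
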