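#' Collect one line's results across genotyping methods
#'
#' A line result holds whatever subset of method outputs exists for one
#' plant line: CS and window NGS spectra, a CE spectrum, an RNP score, and
#' HRMA summaries.  At least one method must be present.
#'
#' @param line_id Line label (e.g. "N8a").
#' @param cs,window,ce Optional [indel_spectrum()]s from the CS caller, the
#'   indicator-window caller and CE peak quantification.
#' @param rnp Optional [rnp_score()].
#' @param hrma_max_diff Optional maximum fluorescence difference to WT.
#' @param melt_peak_temps Optional numeric vector of melt-peak temperatures.
#' @return A `line_result` list.
#' @export
line_result <- function(line_id, cs = NULL, window = NULL, ce = NULL,
                        rnp = NULL, hrma_max_diff = NULL,
                        melt_peak_temps = NULL) {
  if (is.null(cs) && is.null(window) && is.null(ce) && is.null(rnp) &&
      is.null(hrma_max_diff) && is.null(melt_peak_temps))
    stop("line '", line_id, "' has no method results")
  structure(list(line_id = line_id, cs = cs, window = window, ce = ce,
                 rnp = rnp, hrma_max_diff = hrma_max_diff,
                 melt_peak_temps = melt_peak_temps),
            class = "line_result")
}

#' Cross-method concordance table
#'
#' One row per line, mirroring the side-by-side layout used to compare the
#' methods: overall non-WT frequency per method (percent), RNP score and
#' HRMA summaries, plus per-indel agreement and method-specific miss flags:
#'
#' * `indel_agreement`: for each indel class called by any read-based
#'   method, which methods report a class within `size_tolerance_bp`;
#' * `ce_undercall`: CE overall lower than the best NGS estimate by more
#'   than `undercall_margin` percentage points (the 1 bp deletion absorbed
#'   by a secondary WT peak produces exactly this signature);
#' * `spanning_deletion`: the CS spectrum holds a deletion flagged (or
#'   reconcilable) as spanning both sgRNA sites that the single-site window
#'   caller cannot report as one event.
#'
#' @param results List of [line_result()]s.
#' @param size_tolerance_bp Size agreement tolerance between methods
#'   (default 1 bp, the drift observed between CE/CS/window sizing).
#' @param undercall_margin Percentage-point margin for the CE undercall
#'   flag (default 5).
#' @return A list with `lines` (summary tibble) and `agreement` (long
#'   tibble `line_id, size_delta, cs, window, ce, spanning`).
#' @export
concordance_table <- function(results, size_tolerance_bp = 1,
                              undercall_margin = 5) {
  stopifnot(length(results) >= 1L)
  ov <- function(sp) if (is.null(sp)) NA_real_
                     else 100 * sp$overall_non_wt_frequency
  deltas_of <- function(sp) if (is.null(sp)) integer(0)
                            else sp$calls$size_delta

  rows <- list(); agree <- list()
  for (lr in results) {
    cs_ov <- ov(lr$cs); wd_ov <- ov(lr$window); ce_ov <- ov(lr$ce)
    union_deltas <- sort(unique(c(deltas_of(lr$cs), deltas_of(lr$window),
                                  deltas_of(lr$ce))))
    near <- function(sp, d) any(abs(deltas_of(sp) - d) <= size_tolerance_bp)
    spanning_cs <- if (!is.null(lr$cs) && "spans_both_sites" %in%
                       names(lr$cs$calls))
      lr$cs$calls$size_delta[lr$cs$calls$spans_both_sites] else integer(0)
    spanning_wd <- if (!is.null(lr$window))
      lr$window$calls$size_delta[lr$window$calls$spans_both_sites]
      else integer(0)

    if (length(union_deltas)) {
      ag <- tibble::tibble(
        line_id = lr$line_id,
        size_delta = union_deltas,
        cs = vapply(union_deltas, near, logical(1), sp = lr$cs),
        window = vapply(union_deltas, near, logical(1), sp = lr$window),
        ce = vapply(union_deltas, near, logical(1), sp = lr$ce))
      # a CS deletion missing from the window calls but matching a window
      # call flagged as spanning both sites is reconciled as one spanning
      # deletion, not a disagreement
      ag$spanning <- ag$size_delta %in% spanning_cs |
        vapply(ag$size_delta, function(d)
          !near(lr$window, d) && length(spanning_wd) > 0 &&
            any(abs(spanning_wd - d) <= size_tolerance_bp), logical(1)) |
        ag$size_delta %in% spanning_wd
      agree[[length(agree) + 1L]] <- ag
    }

    best_ngs <- suppressWarnings(max(c(cs_ov, wd_ov), na.rm = TRUE))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      line_id = lr$line_id,
      cs_overall = cs_ov, window_overall = wd_ov, ce_overall = ce_ov,
      rnp_score = if (is.null(lr$rnp)) NA_integer_ else lr$rnp$score,
      hrma_max_diff = if (is.null(lr$hrma_max_diff)) NA_real_
                      else lr$hrma_max_diff,
      melt_peak_temps = if (is.null(lr$melt_peak_temps)) NA_character_
        else paste(sprintf("%.1f", lr$melt_peak_temps), collapse = ", "),
      all_methods_agree = if (length(union_deltas)) {
        a <- agree[[length(agree)]]
        methods_present <- c(cs = !is.null(lr$cs),
                             window = !is.null(lr$window),
                             ce = !is.null(lr$ce))
        all(apply(as.matrix(a[, names(methods_present)[methods_present]]),
                  1L, all) | a$spanning)
      } else TRUE,
      ce_undercall = !is.na(ce_ov) && is.finite(best_ngs) &&
        best_ngs - ce_ov > undercall_margin,
      spanning_deletion = length(spanning_cs) > 0L ||
        length(spanning_wd) > 0L)
  }
  list(lines = do.call(rbind, rows),
       agreement = if (length(agree)) do.call(rbind, agree) else
         tibble::tibble(line_id = character(), size_delta = integer(),
                        cs = logical(), window = logical(), ce = logical(),
                        spanning = logical()))
}

#' Detect chimerism across vegetative progenies of one event
#'
#' Each progeny is classified mutant (overall non-WT frequency at or above
#' `mutant_threshold`) or wild type; a transformation event is chimeric
#' when its progenies disagree - the signature of genetically distinct
#' cell lineages within one event.
#'
#' @param progeny List of [line_result()]s from the same event.  The
#'   overall frequency is taken from the CS spectrum when present, else the
#'   window spectrum, else CE.
#' @param mutant_threshold Overall non-WT frequency (fraction) above which
#'   a progeny is called mutant (default 0.05).
#' @return A list with `verdict` (`"chimeric"`, `"uniform"` or
#'   `"insufficient replicates"`) and `progeny` (tibble `line_id, overall,
#'   class`).  The verdict does not depend on progeny order.
#' @export
detect_chimerism <- function(progeny, mutant_threshold = 0.05) {
  overall_of <- function(lr) {
    sp <- lr$cs %||% lr$window %||% lr$ce
    if (is.null(sp)) stop("line '", lr$line_id,
                          "' carries no frequency-bearing method")
    sp$overall_non_wt_frequency
  }
  tab <- tibble::tibble(
    line_id = vapply(progeny, `[[`, character(1), "line_id"),
    overall = vapply(progeny, overall_of, numeric(1)))
  tab$class <- ifelse(tab$overall >= mutant_threshold, "mutant", "wt")
  verdict <- if (nrow(tab) < 2L) "insufficient replicates"
    else if (length(unique(tab$class)) > 1L) "chimeric" else "uniform"
  list(verdict = verdict, progeny = tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assay cost table
#'
#' Per-component consumable costs: pack price, the number of reactions one
#' pack supports (choosing the smallest pack size that processes a 96-well
#' batch), the method the component belongs to, and whether the component
#' is consumed once per technical replicate (`per_replicate = TRUE`, e.g.
#' HRMA master mix for triplicate runs) or once per sample.
#'
#' @param components Data frame with columns `component`, `pack_price`,
#'   `reactions_per_pack`, `method` and optional logical `per_replicate`.
#' @return A validated `cost_table` tibble.
#' @export
cost_table <- function(components) {
  df <- tibble::as_tibble(components)
  need <- c("component", "pack_price", "reactions_per_pack", "method")
  if (!all(need %in% names(df)))
    stop("cost table must have columns: ", paste(need, collapse = ", "))
  if (!"per_replicate" %in% names(df)) df$per_replicate <- FALSE
  if (any(df$pack_price < 0)) stop("pack prices must be non-negative")
  if (any(df$reactions_per_pack < 1)) stop("reactions_per_pack must be >= 1")
  structure(df, class = c("cost_table", class(df)))
}

#' Per-sample cost of one genotyping method
#'
#' Sums `pack_price / reactions_per_pack` over the method's components;
#' components flagged `per_replicate` are multiplied by the replicate
#' count (3 for triplicate HRMA).
#'
#' @param table A [cost_table()].
#' @param method Method name to cost.
#' @param replicates Technical replicates per sample (default 1).
#' @return Cost per sample (currency units of the table).
#' @export
cost_per_sample <- function(table, method, replicates = 1L) {
  stopifnot(inherits(table, "cost_table"), replicates >= 1)
  rows <- table[table$method == method, ]
  if (!nrow(rows))
    stop("no components listed for method '", method, "'")
  per <- rows$pack_price / rows$reactions_per_pack
  sum(per * ifelse(rows$per_replicate, replicates, 1))
}

#' Write a concordance report
#'
#' Emits the per-line summary as both TSV (the tabular cross-method
#' layout) and JSON (one object per line).
#'
#' @param conc Result of [concordance_table()].
#' @param tsv_path,json_path Output paths; `NULL` skips.
#' @return `conc`, invisibly.
#' @export
write_concordance <- function(conc, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(conc$lines, tsv_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(conc, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  invisible(conc)
}
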