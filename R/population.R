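#' Construct a polyploid allele population with planted edits
#'
#' Models the pool of hom(e)ologous gene copies amplified from a polyploid
#' sample: one or more wild-type amplicon variants (possibly of different
#' lengths, as intron-derived WT length variants produce) plus a set of
#' edited alleles, each an indel of known size, sequence and frequency at
#' the cut site.  Planted frequencies are the ground truth that the callers
#' are later asked to recover.
#'
#' @param ref Wild-type reference amplicon (uppercase ACGT).
#' @param cut_site 1-based cut position in `ref` (cut falls after this base).
#' @param edits Data frame with columns `size_delta` (signed bp),
#'   `indel_seq` (inserted bases for insertions; may be `NA` for deletions,
#'   in which case the deleted reference bases are recorded), `offset`
#'   (signed bp, position of the indel relative to the cut site; default 0)
#'   and `frequency` (fraction of the allele pool).  May be `NULL` or empty
#'   for an all-WT population.
#' @param wt_variants Optional data frame with columns `seq`, `abundance`
#'   giving additional wild-type amplicon variants and their relative
#'   abundances within the WT fraction.  Defaults to `ref` alone.
#'
#' @return An `allele_population`: a table of distinct allele sequences with
#'   columns `allele` (label), `seq`, `frequency`, `size_delta`, `is_wt`.
#'   Frequencies sum to 1.
#' @examples
#' pop <- allele_population(strrep("ACGT", 50), cut_site = 100,
#'                          edits = data.frame(size_delta = +1,
#'                                             indel_seq = "A",
#'                                             frequency = 0.3))
#' pop$alleles
#' @export
allele_population <- function(ref, cut_site, edits = NULL, wt_variants = NULL) {
  ref <- toupper(ref)
  .check_dna(ref, "ref")
  stopifnot(cut_site >= 1, cut_site <= nchar(ref))
  if (is.null(edits) || nrow(as.data.frame(edits)) == 0L) {
    edits <- data.frame(size_delta = integer(), indel_seq = character(),
                        offset = integer(), frequency = numeric())
  }
  edits <- as.data.frame(edits)
  if (!"offset" %in% names(edits)) edits$offset <- 0L
  if (!"indel_seq" %in% names(edits)) edits$indel_seq <- NA_character_
  stopifnot(all(c("size_delta", "frequency") %in% names(edits)))
  if (any(edits$size_delta == 0L))
    stop("edits must have non-zero size_delta")
  if (any(edits$frequency < 0 | edits$frequency > 1))
    stop("edit frequencies must lie in [0, 1]")
  mut_total <- sum(edits$frequency)
  if (mut_total > 1 + 1e-9)
    stop("edit frequencies sum to ", mut_total, " > 1")
  wt_total <- max(0, 1 - mut_total)

  if (is.null(wt_variants)) {
    wt_variants <- data.frame(seq = ref, abundance = 1)
  }
  wt_variants <- as.data.frame(wt_variants)
  wt_variants$seq <- toupper(wt_variants$seq)
  wt_variants$abundance <- wt_variants$abundance / sum(wt_variants$abundance)

  rows <- list()
  if (wt_total > 0) {
    for (i in seq_len(nrow(wt_variants))) {
      rows[[length(rows) + 1L]] <- data.frame(
        allele = if (nrow(wt_variants) == 1L) "WT" else paste0("WT", i),
        seq = wt_variants$seq[i],
        frequency = wt_total * wt_variants$abundance[i],
        size_delta = 0L, is_wt = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(edits))) {
    ed <- apply_edit(ref, cut_site, edits$size_delta[i],
                     indel_seq = edits$indel_seq[i],
                     offset = edits$offset[i])
    rows[[length(rows) + 1L]] <- data.frame(
      allele = sprintf("%+d@%d", edits$size_delta[i], edits$offset[i]),
      seq = ed$seq, frequency = edits$frequency[i],
      size_delta = as.integer(edits$size_delta[i]), is_wt = FALSE,
      stringsAsFactors = FALSE)
  }
  alleles <- do.call(rbind, rows)
  if (abs(sum(alleles$frequency) - 1) > 1e-9)
    stop("allele frequencies do not sum to 1")
  structure(list(ref = ref, cut_site = as.integer(cut_site),
                 alleles = tibble::as_tibble(alleles)),
            class = "allele_population")
}

#' Apply a single indel to a reference sequence
#'
#' Deletions of size `-k` remove `k` bases; by convention the deleted block
#' ends at the cut site when `offset = 0`, so the lesion abuts the cut.
#' Insertions place `indel_seq` immediately after `cut_site + offset`.
#'
#' @param ref Reference sequence.
#' @param cut_site 1-based cut position.
#' @param size_delta Signed indel size in bp (non-zero).
#' @param indel_seq Inserted bases (required for insertions, length must
#'   equal `size_delta`); ignored for deletions.
#' @param offset Signed shift of the indel relative to the cut site.
#' @return List with `seq` (edited sequence) and `indel_seq` (inserted or
#'   deleted bases, uppercase).
#' @export
apply_edit <- function(ref, cut_site, size_delta, indel_seq = NA, offset = 0L) {
  n <- nchar(ref)
  size_delta <- as.integer(size_delta)
  if (size_delta == 0L) stop("size_delta must be non-zero")
  if (size_delta > 0L) {
    if (is.na(indel_seq) || nchar(indel_seq) != size_delta)
      stop("insertion of +", size_delta, " bp needs an indel_seq of that length")
    at <- cut_site + offset
    if (at < 0L || at > n) stop("insertion position outside the reference")
    seq <- paste0(substr(ref, 1L, at), toupper(indel_seq),
                  substr(ref, at + 1L, n))
    list(seq = seq, indel_seq = toupper(indel_seq))
  } else {
    k <- -size_delta
    del_end <- cut_site + offset
    del_start <- del_end - k + 1L
    if (del_start < 1L || del_end > n)
      stop("deletion of ", k, " bp does not fit inside the reference")
    deleted <- substr(ref, del_start, del_end)
    seq <- paste0(substr(ref, 1L, del_start - 1L),
                  substr(ref, del_end + 1L, n))
    list(seq = seq, indel_seq = deleted)
  }
}

#' @export
print.allele_population <- function(x, ...) {
  cat("Allele population on a ", nchar(x$ref), " bp amplicon (cut at ",
      x$cut_site, "): ", nrow(x$alleles), " alleles\n", sep = "")
  print(x$alleles, ...)
  invisible(x)
}

#' Simulation configuration for the synthetic-data generators
#'
#' One config object seeds and parameterises every generator, so a fixed
#' seed yields byte-identical FASTQ/CSV output.
#'
#' @param n_reads Number of amplicon reads to simulate.
#' @param substitution_rate Per-base substitution error rate.
#' @param read_indel_rate Per-read probability of a small (1-2 bp) spurious
#'   indel, emulating the sub-1 percent background length deviations that
#'   sequencing error produces.
#' @param seed Integer RNG seed.
#' @param peak_size_jitter_sd Gaussian SD (bp) on simulated CE peak sizes.
#' @param peak_height_noise_cv Multiplicative coefficient of variation on
#'   simulated CE peak heights.
#' @param gel_noise_sd Additive SD on simulated gel-band grey values.
#' @param melt_replicates Melt-curve technical replicates per sample.
#' @param melt_noise_sd Additive fluorescence noise SD per melt-curve point.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_reads = 20000L,
                       substitution_rate = 0.001,
                       read_indel_rate = 0.002,
                       seed = 1L,
                       peak_size_jitter_sd = 0.15,
                       peak_height_noise_cv = 0.05,
                       gel_noise_sd = 5,
                       melt_replicates = 3L,
                       melt_noise_sd = 0.5) {
  rates <- c(substitution_rate, read_indel_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  stopifnot(n_reads >= 1, melt_replicates >= 1)
  structure(list(n_reads = as.integer(n_reads),
                 substitution_rate = substitution_rate,
                 read_indel_rate = read_indel_rate,
                 seed = as.integer(seed),
                 peak_size_jitter_sd = peak_size_jitter_sd,
                 peak_height_noise_cv = peak_height_noise_cv,
                 gel_noise_sd = gel_noise_sd,
                 melt_replicates = as.integer(melt_replicates),
                 melt_noise_sd = melt_noise_sd),
            class = "sim_config")
}
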