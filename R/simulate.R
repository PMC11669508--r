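#' Simulate forward amplicon reads from an allele population
#'
#' Each read is drawn from an allele with probability equal to its frequency,
#' then passed through a simple error model: independent per-base
#' substitutions at `cfg$substitution_rate` and, with per-read probability
#' `cfg$read_indel_rate`, one spurious 1-2 bp indel at a random position.
#' The allele of origin and its true size delta are recorded in the read
#' identifier (`|allele=...|delta=...`) so downstream callers can be scored
#' against exact truth.
#'
#' Reads are generated in the forward orientation; assays read from the
#' reverse strand are handled by reverse-complementing the read stream at
#' calling time.
#'
#' @param pop An [allele_population()].
#' @param cfg A [sim_config()]; `cfg$seed` fully determines the output.
#' @return A tibble with columns `id`, `seq`, `allele`, `true_delta`.
#' @export
simulate_reads <- function(pop, cfg = sim_config()) {
  stopifnot(inherits(pop, "allele_population"))
  al <- pop$alleles
  if (nrow(al) == 0L) stop("empty allele population")
  set.seed(cfg$seed)
  n <- cfg$n_reads

  idx <- sample.int(nrow(al), n, replace = TRUE, prob = al$frequency)
  seqs <- al$seq[idx]

  if (cfg$substitution_rate > 0) {
    lens <- nchar(seqs)
    n_sub <- stats::rbinom(n, lens, cfg$substitution_rate)
    hit <- which(n_sub > 0L)
    for (i in hit) {
      pos <- sample.int(lens[i], n_sub[i])
      s <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
      for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
      seqs[i] <- paste(s, collapse = "")
    }
  }

  if (cfg$read_indel_rate > 0) {
    hit <- which(stats::runif(n) < cfg$read_indel_rate)
    for (i in hit) {
      len <- nchar(seqs[i])
      k <- sample(1:2, 1L)
      if (stats::runif(1) < 0.5 && len > k + 2L) {        # spurious deletion
        at <- sample.int(len - k, 1L)
        seqs[i] <- paste0(substr(seqs[i], 1L, at - 1L),
                          substr(seqs[i], at + k, len))
      } else {                                            # spurious insertion
        at <- sample.int(len, 1L)
        ins <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                     collapse = "")
        seqs[i] <- paste0(substr(seqs[i], 1L, at), ins,
                          substr(seqs[i], at + 1L, len))
      }
    }
  }

  tibble::tibble(
    id = sprintf("read%06d|allele=%s|delta=%d",
                 seq_len(n), al$allele[idx], al$size_delta[idx]),
    seq = seqs,
    allele = al$allele[idx],
    true_delta = al$size_delta[idx])
}

#' Write simulated reads as a 4-line-record FASTQ file
#'
#' Quality characters are fixed to `I` (Phred+33, Q40); the simulator does
#' not model per-base quality.  Output is byte-identical for identical
#' input, so seeded simulations round-trip exactly.
#'
#' @param reads Tibble from [simulate_reads()] (columns `id`, `seq`).
#' @param path Output path; a `.gz` suffix writes gzip-compressed text.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$seq))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a FASTQ file into an id/sequence tibble
#'
#' Plain or gzip-compressed 4-line-record FASTQ.  Qualities are discarded:
#' the callers in this package use only the base sequence.
#'
#' @param path FASTQ path (optionally `.gz`).
#' @return Tibble with columns `id`, `seq`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)  # readLines handles gzip transparently
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: line count not a multiple of 4 in ", path)
  ids <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
  tibble::tibble(id = ids, seq = toupper(lines[seq(2L, length(lines), by = 4L)]))
}

#' Simulate a capillary-electrophoresis peak table
#'
#' Produces one peak per distinct amplicon length in the population, with
#' height proportional to the summed allele frequency at that length
#' (multiplicative log-normal-free noise with CV `peak_height_noise_cv`)
#' and size equal to the true length plus Gaussian jitter
#' (`peak_size_jitter_sd`), emulating fragment-analysis sizing scatter.
#'
#' @param pop An [allele_population()].
#' @param cfg A [sim_config()].
#' @param sample_name Sample label for the table.
#' @param height_scale Height of a frequency-1 peak (arbitrary fluorescence
#'   units).
#' @return A [peak_table()].
#' @export
simulate_peak_table <- function(pop, cfg = sim_config(),
                                sample_name = "sample",
                                height_scale = 10000) {
  stopifnot(inherits(pop, "allele_population"))
  set.seed(cfg$seed)
  al <- pop$alleles
  len <- nchar(al$seq)
  freq <- tapply(al$frequency, len, sum)
  sizes <- as.numeric(names(freq))
  heights <- as.numeric(freq) * height_scale
  if (cfg$peak_height_noise_cv > 0)
    heights <- heights *
      pmax(1e-6, 1 + stats::rnorm(length(heights), 0, cfg$peak_height_noise_cv))
  if (cfg$peak_size_jitter_sd > 0)
    sizes <- sizes + stats::rnorm(length(sizes), 0, cfg$peak_size_jitter_sd)
  peak_table(sample = sample_name, size_bp = sizes, height = heights)
}

#' Simulate gel-band grey values for an RNP cleavage assay lane
#'
#' Grey values are generated on the convention the densitometry scorer
#' expects: `delta_gv = GV(cleaved) - GV(uncleaved)` decreases as the
#' cleaved fraction increases, so a fully cleavable (wild-type) template
#' gives a strongly negative delta.  The noiseless construction is linear,
#' `delta_gv = K * (1 - 2 * cleaved_fraction)` with `K = 120` for a
#' single-cleaved-product assay and `K = 80` for a dual-product assay, which
#' lands cleaved fractions 1.0/0.8/0.5/0.2/0.0 in the score 0/1/2/3/4 bands
#' of the respective threshold tables.  Additive Gaussian noise
#' (`cfg$gel_noise_sd`) perturbs each band.
#'
#' @param cleaved_fraction Fraction of template cleaved by the RNP (1 for
#'   fully wild-type, 0 for fully mutated).
#' @param dual_cleaved `TRUE` when the assay yields two cleaved products.
#' @param cfg A [sim_config()].
#' @param sample_name Lane label.
#' @param expected_uncleaved_size,expected_cleaved_sizes Band sizes in bp
#'   used to populate the lane's expectations.
#' @return A [gel_lane()].
#' @export
simulate_gel_lane <- function(cleaved_fraction, dual_cleaved = FALSE,
                              cfg = sim_config(), sample_name = "lane",
                              expected_uncleaved_size = 1048,
                              expected_cleaved_sizes = if (dual_cleaved)
                                c(414, 541) else 852) {
  stopifnot(cleaved_fraction >= 0, cleaved_fraction <= 1)
  set.seed(cfg$seed)
  K <- if (dual_cleaved) 80 else 120
  centre <- 128
  gv_cleaved  <- centre - K / 2 * (2 * cleaved_fraction - 1)
  gv_uncleaved <- centre + K / 2 * (2 * cleaved_fraction - 1)
  n_cl <- if (dual_cleaved) 2L else 1L
  cl <- rep(gv_cleaved, n_cl)
  if (cfg$gel_noise_sd > 0) {
    cl <- cl + stats::rnorm(n_cl, 0, cfg$gel_noise_sd)
    gv_uncleaved <- gv_uncleaved + stats::rnorm(1L, 0, cfg$gel_noise_sd)
  }
  gel_lane(sample = sample_name,
           cleaved_gvs = pmax(0, cl),
           uncleaved_gv = max(0, gv_uncleaved),
           expected_cleaved_sizes = expected_cleaved_sizes,
           expected_uncleaved_size = expected_uncleaved_size)
}

#' Simulate melt curves for a mixture of alleles
#'
#' Fluorescence is a frequency-weighted mixture of two-state sigmoid melt
#' transitions, one per allele: `F(T) = sum_a f_a / (1 + exp((T - Tm_a) / w))`
#' scaled to 100, plus replicate Gaussian noise.  `melt_replicates` traces
#' are produced per sample on a shared temperature grid.
#'
#' @param pop An [allele_population()].
#' @param tm_by_allele Named numeric vector mapping allele labels (as in
#'   `pop$alleles$allele`) to melting temperatures in degrees C.
#' @param cfg A [sim_config()].
#' @param sample_name Sample label.
#' @param temp_grid Monotone increasing temperature grid (degrees C).
#' @param transition_width Sigmoid width parameter `w` in degrees C.
#' @return A long-format tibble `sample, replicate, temp_c, fluorescence`
#'   (a melt-curve set for one sample).
#' @export
simulate_melt_curves <- function(pop, tm_by_allele, cfg = sim_config(),
                                 sample_name = "sample",
                                 temp_grid = seq(70, 95, by = 0.1),
                                 transition_width = 0.4) {
  stopifnot(inherits(pop, "allele_population"))
  if (length(temp_grid) < 2L) stop("temperature grid needs at least 2 points")
  if (any(diff(temp_grid) <= 0)) stop("temperature grid must be increasing")
  al <- pop$alleles
  missing <- setdiff(al$allele, names(tm_by_allele))
  if (length(missing))
    stop("no Tm given for allele(s): ", paste(missing, collapse = ", "))
  set.seed(cfg$seed)
  base <- rep(0, length(temp_grid))
  for (i in seq_len(nrow(al))) {
    tm <- tm_by_allele[[al$allele[i]]]
    base <- base + al$frequency[i] /
      (1 + exp((temp_grid - tm) / transition_width))
  }
  base <- 100 * base
  out <- lapply(seq_len(cfg$melt_replicates), function(r) {
    f <- base
    if (cfg$melt_noise_sd > 0)
      f <- f + stats::rnorm(length(f), 0, cfg$melt_noise_sd)
    tibble::tibble(sample = sample_name, replicate = r,
                   temp_c = temp_grid, fluorescence = f)
  })
  do.call(rbind, out)
}
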