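ref <- make_ref()

test_that("noiseless simulation reproduces the wild-type sequence exactly", {
  pop <- allele_population(ref, 115)
  cfg <- sim_config(n_reads = 100, substitution_rate = 0,
                    read_indel_rate = 0, seed = 5)
  rd <- simulate_reads(pop, cfg)
  expect_equal(nrow(rd), 100L)
  expect_true(all(rd$seq == ref))
  expect_true(all(rd$true_delta == 0L))
})

test_that("allele sampling recovers planted frequencies within 3 binomial SDs", {
  pop <- allele_population(ref, 115,
    edits = data.frame(size_delta = 1, indel_seq = "A", frequency = 0.3))
  n <- 20000L
  rd <- simulate_reads(pop, sim_config(n_reads = n, substitution_rate = 0,
                                       read_indel_rate = 0, seed = 1))
  frac <- mean(nchar(rd$seq) == nchar(ref) + 1L)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("identical seeds give byte-identical FASTQ; different seeds differ", {
  pop <- allele_population(ref, 115,
    edits = data.frame(size_delta = -3, indel_seq = NA, frequency = 0.2))
  f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
  f3 <- tempfile(fileext = ".fq")
  write_fastq(simulate_reads(pop, sim_config(n_reads = 500, seed = 9)), f1)
  write_fastq(simulate_reads(pop, sim_config(n_reads = 500, seed = 9)), f2)
  write_fastq(simulate_reads(pop, sim_config(n_reads = 500, seed = 10)), f3)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false(identical(readLines(f1), readLines(f3)))
  # round trip through the FASTQ reader preserves ids and sequences
  back <- read_fastq(f1)
  fwd <- simulate_reads(pop, sim_config(n_reads = 500, seed = 9))
  expect_equal(back$id, fwd$id)
  expect_equal(back$seq, fwd$seq)
})

test_that("allele-of-origin tags in read ids match the true delta", {
  pop <- allele_population(ref, 115,
    edits = data.frame(size_delta = c(2, -5), indel_seq = c("GG", NA),
                       frequency = c(0.25, 0.25)))
  rd <- simulate_reads(pop, sim_config(n_reads = 300, seed = 2))
  tagged <- as.integer(sub(".*delta=(-?\\d+)$", "\\1", rd$id))
  expect_equal(tagged, rd$true_delta)
})

test_that("peak simulation is height- and size-faithful without noise", {
  cfg0 <- sim_config(peak_size_jitter_sd = 0, peak_height_noise_cv = 0,
                     seed = 3)
  pop1 <- allele_population(ref, 115)
  pt <- simulate_peak_table(pop1, cfg0, height_scale = 1)
  expect_equal(nrow(pt), 1L)
  expect_equal(pt$size_bp, nchar(ref))
  expect_equal(pt$height, 1)

  # two WT length variants at 50/50: two equal peaks 1 bp apart
  wt2 <- data.frame(seq = c(ref, substr(ref, 1, nchar(ref) - 1L)),
                    abundance = c(0.5, 0.5))
  pop2 <- allele_population(ref, 115, wt_variants = wt2)
  pt2 <- simulate_peak_table(pop2, cfg0, height_scale = 1)
  expect_equal(nrow(pt2), 2L)
  expect_equal(diff(pt2$size_bp), 1)
  expect_equal(pt2$height, c(0.5, 0.5))
})

test_that("peak size jitter is unbiased (Monte-Carlo mean within 0.05 bp)", {
  pop <- allele_population(ref, 115)
  sizes <- vapply(1:1000, function(s)
    simulate_peak_table(pop, sim_config(peak_size_jitter_sd = 0.3,
                                        peak_height_noise_cv = 0,
                                        seed = s))$size_bp,
    numeric(1))
  expect_lt(abs(mean(sizes) - nchar(ref)), 0.05)
})

test_that("gel-lane grey values encode the cleaved fraction", {
  cfg0 <- sim_config(gel_noise_sd = 0)
  expect_lt(delta_gv(simulate_gel_lane(1, cfg = cfg0)), -90)
  expect_gt(delta_gv(simulate_gel_lane(0, cfg = cfg0)), 90)
  mid <- delta_gv(simulate_gel_lane(0.5, cfg = cfg0))
  expect_gte(mid, -30); expect_lte(mid, 30)
  # monotone decreasing in cleaved fraction
  dgvs <- vapply(seq(0, 1, by = 0.1), function(f)
    delta_gv(simulate_gel_lane(f, cfg = cfg0)), numeric(1))
  expect_true(all(diff(dgvs) < 0))
})

test_that("melt-curve mixtures place derivative peaks at the allele Tms", {
  cfg0 <- sim_config(melt_noise_sd = 0)
  pop1 <- allele_population(ref, 115)
  mc <- simulate_melt_curves(pop1, c(WT = 82), cfg0)
  tr <- mc[mc$replicate == 1, ]
  pk <- melt_peaks(tr$temp_c, tr$fluorescence)
  expect_equal(length(pk), 1L)
  expect_lt(abs(pk - 82), 0.1 + 1e-9)  # within one grid step

  pop2 <- allele_population(ref, 115,
    edits = data.frame(size_delta = -8, indel_seq = NA, frequency = 0.5))
  mc2 <- simulate_melt_curves(pop2, c(WT = 85, `-8@0` = 80), cfg0)
  tr2 <- mc2[mc2$replicate == 1, ]
  pk2 <- melt_peaks(tr2$temp_c, tr2$fluorescence)
  expect_equal(length(pk2), 2L)
  expect_lt(abs(pk2[1] - 80), 0.2)
  expect_lt(abs(pk2[2] - 85), 0.2)

  # identical populations, identical seeds: identical curves
  mc3 <- simulate_melt_curves(pop1, c(WT = 82), cfg0)
  expect_identical(mc, mc3)
  expect_equal(nrow(mc) / length(unique(mc$temp_c)), cfg0$melt_replicates)
})

test_that("generator rejects invalid populations and configs", {
  expect_error(sim_config(substitution_rate = 1.5), "rates")
  expect_error(allele_population(ref, 115,
    edits = data.frame(size_delta = 0, indel_seq = NA, frequency = 0.1)),
    "non-zero")
  expect_error(allele_population(ref, 115,
    edits = data.frame(size_delta = c(-1, 1), indel_seq = c(NA, "A"),
                       frequency = c(0.7, 0.6))), "sum")
  expect_error(apply_edit(ref, 5, -10), "fit inside")
  expect_error(simulate_melt_curves(allele_population(ref, 115), c(WT = 82),
                                    temp_grid = 80), "2 points")
})
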