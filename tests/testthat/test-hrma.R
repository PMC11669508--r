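amp <- make_ref(150)
wt_pop <- allele_population(amp, 75)

sigmoid_trace <- function(tm, grid = seq(70, 95, by = 0.1), w = 0.4)
  100 / (1 + exp((grid - tm) / w))

test_that("two-point normalization is idempotent and affine-invariant", {
  grid <- seq(70, 95, by = 0.1)
  f <- sigmoid_trace(82)
  pre <- c(70, 71); post <- c(94, 95)
  n1 <- normalize_melt(grid, f, pre, post)
  expect_equal(normalize_melt(grid, n1, pre, post), n1)
  expect_equal(normalize_melt(grid, 3 * f + 7, pre, post), n1)
  expect_error(normalize_melt(grid, rep(5, length(grid)), pre, post),
               "degenerate")
  expect_error(normalize_melt(grid, f, c(60, 61), post), "outside")
})

test_that("replicates differing only in gain normalize identically", {
  grid <- seq(70, 95, by = 0.1)
  f <- sigmoid_trace(81.5)
  expect_equal(normalize_melt(grid, f, c(70, 71), c(94, 95)),
               normalize_melt(grid, 2.5 * f, c(70, 71), c(94, 95)))
})

test_that("melt peaks land on the allele Tm and flat traces yield none", {
  grid <- seq(70, 95, by = 0.1)
  pk <- melt_peaks(grid, sigmoid_trace(82.3))
  expect_equal(length(pk), 1L)
  expect_lt(abs(pk - 82.3), 0.11)
  expect_warning(none <- melt_peaks(grid, rep(10, length(grid))), "flat")
  expect_length(none, 0L)
})

test_that("WT-vs-WT difference stays within 3 SDs of replicate noise", {
  noise <- 0.5
  cfg <- function(s) sim_config(seed = s, melt_noise_sd = noise)
  curves <- rbind(
    simulate_melt_curves(wt_pop, c(WT = 82.3), cfg(1), "WT1"),
    simulate_melt_curves(wt_pop, c(WT = 82.3), cfg(2), "WT2"),
    simulate_melt_curves(wt_pop, c(WT = 82.3), cfg(3), "S"))
  res <- difference_curves(melt_curve_set(curves, c("WT1", "WT2")))
  expect_lt(res$summary$max_fluor_diff[res$summary$sample == "S"], 3 * noise)
})

test_that("max fluorescence difference grows with mutant fraction (noiseless)", {
  cfg0 <- sim_config(melt_noise_sd = 0)
  tm <- c(WT = 83, `-8@0` = 82)   # 1 degree Tm shift
  maxdiff_at <- function(frac) {
    pop <- if (frac == 0) wt_pop else allele_population(amp, 75,
      edits = data.frame(size_delta = -8, indel_seq = NA, frequency = frac))
    curves <- rbind(
      simulate_melt_curves(wt_pop, tm["WT"], cfg0, "WT1"),
      simulate_melt_curves(wt_pop, tm["WT"], cfg0, "WT2"),
      simulate_melt_curves(pop, tm, cfg0, "S"))
    res <- difference_curves(melt_curve_set(curves, c("WT1", "WT2")))
    res$summary$max_fluor_diff[res$summary$sample == "S"]
  }
  diffs <- vapply(c(0, 0.2, 0.5, 0.8, 1), maxdiff_at, numeric(1))
  expect_true(all(diff(diffs) > 0))
  expect_lt(diffs[1], 1e-9)
})

test_that("difference curves are invariant to replicate order and per-trace gain", {
  cfg <- sim_config(seed = 4, melt_noise_sd = 0.3)
  pop <- allele_population(amp, 75,
    edits = data.frame(size_delta = -4, indel_seq = NA, frequency = 0.5))
  curves <- rbind(
    simulate_melt_curves(wt_pop, c(WT = 83), sim_config(seed = 5), "WT1"),
    simulate_melt_curves(pop, c(WT = 83, `-4@0` = 81.5), cfg, "S"))
  set1 <- melt_curve_set(curves, "WT1")
  shuffled <- curves[rev(seq_len(nrow(curves))), ]
  set2 <- melt_curve_set(shuffled, "WT1")
  r1 <- difference_curves(set1)
  r2 <- difference_curves(set2)
  expect_equal(r1$summary$max_fluor_diff[r1$summary$sample == "S"],
               r2$summary$max_fluor_diff[r2$summary$sample == "S"])
  # per-trace gain/offset cancels through the full pipeline
  gained <- curves
  gained$fluorescence <- ifelse(gained$sample == "S",
                                2 * gained$fluorescence + 11,
                                gained$fluorescence)
  r3 <- difference_curves(melt_curve_set(gained, "WT1"))
  expect_equal(r3$summary$max_fluor_diff, r1$summary$max_fluor_diff)
})

test_that("two-Tm mixtures report both melt peaks through difference_curves", {
  cfg0 <- sim_config(melt_noise_sd = 0)
  pop <- allele_population(amp, 75,
    edits = data.frame(size_delta = -8, indel_seq = NA, frequency = 0.5))
  curves <- rbind(
    simulate_melt_curves(wt_pop, c(WT = 85), cfg0, "WT1"),
    simulate_melt_curves(pop, c(WT = 85, `-8@0` = 80.9), cfg0, "S"))
  res <- difference_curves(melt_curve_set(curves, "WT1"))
  pks <- res$melt_peak_temps$S
  expect_equal(length(pks), 2L)
  expect_lt(abs(pks[1] - 80.9), 0.2)
  expect_lt(abs(pks[2] - 85), 0.2)
})

test_that("melt-curve CSVs round-trip into a curve set", {
  curves <- simulate_melt_curves(wt_pop, c(WT = 82), sim_config(seed = 6),
                                 "WT1")
  path <- tempfile(fileext = ".csv")
  utils::write.csv(curves, path, row.names = FALSE)
  set <- read_melt_curves(path, "WT1")
  expect_s3_class(set, "melt_curve_set")
  expect_equal(nrow(set$curves), nrow(curves))
  expect_error(read_melt_curves(path, "WTX"), "not present")
})
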