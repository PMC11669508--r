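ref <- make_ref()
asy <- make_assay(ref)

test_that("single-read window calls: wt, sequence-faithful deletion, insertion", {
  expect_identical(window_call_read(ref, asy), "wt")

  # plant a known 12-mer at the cut, with flanks chosen to differ from the
  # block ends so prefix/suffix trimming cannot drift
  ref12 <- paste0(substr(ref, 1, 102), "A", "CCACTCCCTAGG", "T",
                  substr(ref, 117, nchar(ref)))
  asy12 <- make_assay(ref12)
  del <- apply_edit(ref12, 115, -12)$seq   # removes exactly that block
  call <- window_call_read(del, asy12)
  expect_s3_class(call, "window_call")
  expect_equal(call$size_delta, -12L)
  expect_equal(call$indel_sequence, "ccactccctagg")

  ins <- apply_edit(ref, 115, +2, indel_seq = "GG")$seq
  call2 <- window_call_read(ins, asy)
  expect_equal(call2$size_delta, 2L)
  expect_equal(call2$indel_sequence, "gg")
})

test_that("a 54 bp deletion is unmatched at R=35 but called at R=70", {
  del54 <- apply_edit(ref, 115, -54, offset = 27)$seq
  expect_identical(window_call_read(del54, asy, R = 35), "unmatched")
  call <- window_call_read(del54, asy, R = 70)
  expect_s3_class(call, "window_call")
  expect_equal(call$size_delta, -54L)
})

test_that("equal-length substitutions land in the substitution bucket, not the calls", {
  sub_read <- ref
  flip <- c(A = "C", C = "G", G = "T", T = "A")
  substr(sub_read, 115, 115) <- unname(flip[substr(ref, 115, 115)])
  call <- window_call_read(sub_read, asy)
  expect_s3_class(call, "window_call")
  expect_true(call$substitution)
  expect_equal(call$size_delta, 0L)

  sp <- window_spectrum(c(rep(ref, 90), rep(sub_read, 10)), asy)
  expect_equal(sp$substitutions, 10L)
  expect_equal(nrow(sp$calls), 0L)
  expect_equal(sp$overall_non_wt_frequency, 0.10)
})

test_that("window spectrum recovers a planted spectrum within 3 binomial SDs", {
  pop <- allele_population(ref, 115,
    edits = data.frame(size_delta = c(1, -3), indel_seq = c("A", NA),
                       frequency = c(0.30, 0.15)))
  n <- 10000L
  rd <- simulate_reads(pop, sim_config(n_reads = n, seed = 21))
  sp <- window_spectrum(rd, asy)
  for (tp in list(c(1, 0.30), c(-3, 0.15))) {
    f <- sp$calls$frequency[sp$calls$size_delta == tp[1]]
    expect_length(f, 1L)
    expect_lt(abs(f - tp[2]), 3 * sqrt(tp[2] * (1 - tp[2]) / n))
  }
})

test_that("CS and window overall frequencies agree on clean in-window indels", {
  pop <- allele_population(ref, 115,
    edits = data.frame(size_delta = c(1, -3, -10),
                       indel_seq = c("A", NA, NA),
                       frequency = c(0.25, 0.15, 0.1)))
  rd <- simulate_reads(pop, sim_config(n_reads = 3000, substitution_rate = 0,
                                       read_indel_rate = 0, seed = 22))
  cs <- cs_spectrum(rd, asy)
  wd <- window_spectrum(rd, asy)
  expect_equal(wd$overall_non_wt_frequency, cs$overall_non_wt_frequency,
               tolerance = 1e-12)
})

test_that("merge_rerun uses the union denominator and renormalizes", {
  primary <- indel_spectrum(rep(-1L, 100), callable_reads = 1000,
                            total_reads = 1000, min_report_freq = 0.00015)
  rerun <- indel_spectrum(rep(-43L, 50), callable_reads = 500,
                          total_reads = 500, min_report_freq = 0)
  merged <- merge_rerun(primary, rerun)
  expect_equal(merged$callable_reads, 1500L)
  expect_equal(merged$calls$frequency[merged$calls$size_delta == -1],
               100 / 1500)
  expect_equal(merged$calls$frequency[merged$calls$size_delta == -43],
               50 / 1500)
  expect_equal(merged$overall_non_wt_frequency, 150 / 1500)

  # identity when the rerun found nothing
  empty <- indel_spectrum(integer(0), callable_reads = 500,
                          total_reads = 500)
  expect_identical(merge_rerun(primary, empty), primary)

  # overlapping classes are summed with a warning
  dup <- indel_spectrum(rep(-1L, 10), callable_reads = 100,
                        total_reads = 100, min_report_freq = 0)
  expect_warning(m2 <- merge_rerun(primary, dup), "summed")
  expect_equal(m2$calls$count, 110)
})

test_that("the automatic rerun recovers large deletions and raises the overall frequency", {
  pop <- allele_population(ref, 115,
    edits = data.frame(size_delta = c(-1, -54), indel_seq = c(NA, NA),
                       offset = c(0, 27), frequency = c(0.2, 0.3)))
  rd <- simulate_reads(pop, sim_config(n_reads = 2000, substitution_rate = 0,
                                       read_indel_rate = 0, seed = 23))
  primary <- window_spectrum(rd, asy, R = 35)
  expect_false(-54 %in% primary$calls$size_delta)
  merged <- window_spectrum_with_rerun(rd, asy, R = 35, rerun_R = 70)
  expect_true(-54 %in% merged$calls$size_delta)
  expect_gt(merged$overall_non_wt_frequency,
            primary$overall_non_wt_frequency)
  # merged frequencies sit near the planted truth
  f54 <- merged$calls$frequency[merged$calls$size_delta == -54]
  expect_lt(abs(f54 - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
})

test_that("deletions spanning both sgRNA sites of an amplicon are flagged", {
  asy2 <- make_assay(ref, target_site = 115, R = 35, paired_site = 100)
  # deletion from 95 to 137: covers both cut sites (100 and 115)
  del <- apply_edit(ref, 115, -43, offset = 22)$seq
  call <- window_call_read(del, asy2, R = 70)
  expect_s3_class(call, "window_call")
  expect_equal(call$size_delta, -43L)
  expect_true(call$spans_both_sites)
  # the CS analysis sees the same event as a single -43 class
  expect_identical(cs_call_read(del, asy2), -43L)
})

test_that("window spectrum equals the brute-force scan oracle on 200 reads", {
  pop <- allele_population(ref, 115,
    edits = data.frame(size_delta = c(2, -6), indel_seq = c("CA", NA),
                       frequency = c(0.25, 0.2)))
  rd <- simulate_reads(pop, sim_config(n_reads = 200, seed = 24,
                                       substitution_rate = 0.005,
                                       read_indel_rate = 0.02))
  sp <- window_spectrum(rd, asy, min_report_freq = 0)
  orc <- oracle_window(rd$seq, asy)
  expect_same_histogram(sp, orc)
  expect_equal(sp$substitutions, orc$substitutions)
})
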