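# Shared fixtures: a fixed random amplicon and a default assay on it, plus
# naive string-scan oracles kept deliberately independent of the package's
# vectorised matchers (positional substring comparison only).

make_ref <- function(n = 230L, seed = 42L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_assay <- function(ref = make_ref(), target_site = 115L,
                       R = 35L, paired_site = NULL) {
  assay_definition("test-assay", ref_seq = ref,
                   primer = substr(ref, 1L, 20L),
                   conserved_seq = substr(ref, 141L, 160L),
                   target_site = target_site,
                   comparison_range_R = R,
                   paired_site = paired_site)
}

# All start positions where `pattern` occurs in `x`, by brute substring
# comparison.
scan_occurrences <- function(x, pattern) {
  w <- nchar(pattern)
  hits <- integer(0)
  for (i in seq_len(nchar(x) - w + 1L))
    if (substr(x, i, i + w - 1L) == pattern) hits <- c(hits, i)
  hits
}

# Brute-force CS histogram: first primer hit, first conserved-sequence hit
# after it, delta of the start-to-start distance from wt_distance.
oracle_cs <- function(reads, assay) {
  deltas <- integer(0); callable <- 0L
  for (r in reads) {
    p <- scan_occurrences(r, assay$primer)
    if (!length(p)) next
    cs <- scan_occurrences(r, assay$conserved_seq)
    cs <- cs[cs > p[1L]]
    if (!length(cs)) next
    callable <- callable + 1L
    d <- (cs[1L] - p[1L]) - assay$wt_distance
    if (d != 0L) deltas <- c(deltas, d)
  }
  list(histogram = table(deltas), callable = callable)
}

# Brute-force window histogram for comparison range R.
oracle_window <- function(reads, assay, R = assay$comparison_range_R) {
  ind <- window_indicators(assay, R)
  deltas <- integer(0); callable <- 0L; subs <- 0L
  for (r in reads) {
    l <- scan_occurrences(r, ind$left)
    if (!length(l)) next
    seg_start <- l[1L] + nchar(ind$left)
    rr <- scan_occurrences(r, ind$right)
    rr <- rr[rr >= seg_start]
    if (!length(rr)) next
    seg <- substr(r, seg_start, rr[1L] - 1L)
    d <- nchar(seg) - nchar(ind$wt_segment)
    if (abs(d) > R) next
    callable <- callable + 1L
    if (d != 0L) deltas <- c(deltas, d)
    else if (seg != ind$wt_segment) subs <- subs + 1L
  }
  list(histogram = table(deltas), callable = callable, substitutions = subs)
}

expect_same_histogram <- function(spectrum, oracle) {
  got <- spectrum$classes[order(spectrum$classes$size_delta), ]
  want <- oracle$histogram
  expect_equal(spectrum$callable_reads, oracle$callable)
  expect_equal(got$size_delta, sort(as.integer(names(want))))
  expect_equal(got$count,
               as.integer(want[as.character(got$size_delta)]),
               ignore_attr = TRUE)
}
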