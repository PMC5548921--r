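# Independent oracles used across the suite.

# Brute-force response detection: enumerate every sample pair (i, j) after
# stimulus onset and accept if all samples in between are strictly above the
# threshold, no inter-sample gap exceeds max_gap, and the span is at least
# min_dur. Quadratic on purpose -- written from the rule, not from the
# implementation.
oracle_detect <- function(time_s, ratio_au, onset_s, threshold,
                          min_dur = 10, max_gap = 8) {
  keep <- time_s >= onset_s
  t <- time_s[keep]
  r <- ratio_au[keep]
  n <- length(t)
  for (i in seq_len(n)) {
    if (r[i] <= threshold) next
    for (j in i:n) {
      if (r[j] <= threshold) break
      if (j > i && (t[j] - t[j - 1]) > max_gap) break
      if (t[j] - t[i] >= min_dur) return(TRUE)
    }
  }
  FALSE
}

# Random irregular trace around a known baseline, mixing sub- and
# supra-threshold stretches so both detector outcomes occur.
random_trace <- function(seed) {
  set.seed(seed)
  n <- sample(20:60, 1)
  gaps <- runif(n - 1, 0.5, 10)
  time_s <- cumsum(c(0, gaps))
  onset <- time_s[ceiling(n / 3)]
  ratio <- rnorm(n, mean = 1.3, sd = 0.35)
  list(trace = tibble::tibble(time_s = time_s, ratio_au = ratio),
       onset_s = onset,
       baseline = tibble::tibble(mean_au = 1, sd_au = 0.05))
}

# Generic contingency-table oracle for the enrichment chi-square.
oracle_chi2 <- function(a, b, c, d) {
  suppressWarnings(
    stats::chisq.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                      correct = FALSE)$statistic
  )
}
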