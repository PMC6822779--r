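# Brute-force posterior by direct summation over a discrete support and both
# identities; deliberately shares no code with the package's log-space
# engine.
brute_posterior <- function(values, sigma_I, e_I, e_d = NULL, sigma_d = NULL) {
  vapply(seq_along(e_I), function(j) {
    num <- 0
    den <- 0
    for (d in values) {
      for (I in c(-1, 1)) {
        term <- (1 / length(values)) *
          stats::dnorm(e_I[j], mean = d * I, sd = sigma_I)
        if (!is.null(e_d)) {
          term <- term * stats::dnorm(e_d[j], mean = d, sd = sigma_d)
        }
        if (I == 1) num <- num + term
        den <- den + term
      }
    }
    num / den
  }, numeric(1))
}

# Calibration check: split scored trials into equal-count confidence bins
# and compare per-bin accuracy with per-bin mean confidence. Returns the
# maximum number of binomial SEs by which any bin deviates.
calibration_max_z <- function(trials, n_bins = 20L) {
  n <- nrow(trials)
  bin <- ceiling(rank(trials$confidence, ties.method = "first") / (n / n_bins))
  z <- vapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    p <- mean(trials$confidence[sel])
    a <- mean(trials$accuracy[sel])
    se <- sqrt(p * (1 - p) / sum(sel))
    abs(a - p) / max(se, 1e-12)
  }, numeric(1))
  max(z)
}
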