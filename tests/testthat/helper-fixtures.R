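# shared fixtures and independent oracles

hourly_grid <- function(n, start = "2017-03-01 00:00") {
  seq(as.POSIXct(start, tz = "UTC"), by = "hour", length.out = n)
}

make_series <- function(values, term = "q", start = "2017-03-01 00:00",
                        reconstructed = FALSE) {
  hourly_series(term, hourly_grid(length(values), start), values,
                is_reconstructed = reconstructed)
}

folded_from_matrix <- function(m, term = "q") {
  structure(list(matrix = m, day_labels = seq_len(nrow(m)),
                 hour_labels = 0:23, term = term),
            class = "folded_days")
}

# independent brute-force band-pass: zero all DFT bins whose period (1/f)
# falls outside [band[1], band[2]] hours, then invert
dft_bandpass <- function(x, band, dt = 1) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) / (n * dt)        # cycles per hour, folded
  keep <- f > 0 & 1 / f >= band[1] & 1 / f <= band[2]
  X[!keep] <- 0i
  Re(stats::fft(X, inverse = TRUE) / n)
}

# one-way ANOVA F statistic, minimal and fast, for permutation oracles
fast_F <- function(values, gi, k) {
  n_g <- tabulate(gi, k)
  s_g <- rowsum(values, gi)
  m_g <- s_g / n_g
  gm <- mean(values)
  ssb <- sum(n_g * (m_g - gm)^2)
  ssw <- sum(values^2) - sum(s_g^2 / n_g)
  (ssb / (k - 1)) / (ssw / (length(values) - k))
}

perm_anova_p <- function(values, gi, k, reps = 2000, seed = 1) {
  set.seed(seed)
  obs <- fast_F(values, gi, k)
  hits <- 0L
  for (r in seq_len(reps))
    if (fast_F(sample(values), gi, k) >= obs) hits <- hits + 1L
  (hits + 1) / (reps + 1)
}
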