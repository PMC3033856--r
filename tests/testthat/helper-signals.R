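# signal builders shared across the suite

# two-tone mixture at 4 Hz: a fast 0.5 Hz tone over a slow 0.05 Hz tone
two_tone <- function(duration_s = 240, fs = 4, phase_fast = 0, phase_slow = 0) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  list(t = t,
       fast = sin(2 * pi * 0.5 * t + phase_fast),
       slow = sin(2 * pi * 0.05 * t + phase_slow))
}

# FHR-like random signal: baseline + a few random tones + noise + drift
random_trace_signal <- function(n = 1024, fs = 4, seed = 1) {
  withr::with_seed(seed, {
    t <- (seq_len(n) - 1) / fs
    x <- 130 + 0.002 * t^1.5
    for (f in runif(4, 0.02, 1))
      x <- x + runif(1, 0.5, 3) * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
    x + rnorm(n, sd = 0.5)
  })
}

# well-separated 2-D Gaussian blobs (centres 6 SDs apart)
toy_blobs <- function(n_per_class = 10, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(2 * n_per_class, mean = 0, sd = 1), ncol = 2),
               matrix(rnorm(2 * n_per_class, mean = 6, sd = 1), ncol = 2))
    list(x = x, y = rep(c(1, -1), each = n_per_class))
  })
}

# hand-built decomposition object for noise-order tests: each column of
# `imfs` is one component; residue defaults to zero
fake_decomposition <- function(imfs, residue = NULL, threshold = 0.2) {
  imfs <- as.matrix(imfs)
  colnames(imfs) <- paste0("imf_", seq_len(ncol(imfs)))
  if (is.null(residue)) residue <- rep(0, nrow(imfs))
  structure(
    list(imfs = imfs, residue = residue,
         n_imfs_total = ncol(imfs) + 1L, sifting_threshold = threshold,
         signal = rowSums(imfs) + residue, fs = 4, id = "fake"),
    class = "emd_decomposition")
}
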