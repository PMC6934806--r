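# Shared fixture builders; everything is generated in code at test time.

quiet_network <- function(...) suppressWarnings(make_group_network(...))

# Simple lag-coupled VAR(1) chain 1 -> 2 (plus optional extra independent
# nodes): the canonical system for directed-connectivity oracles.
sim_chain_var1 <- function(n, coupling = 0.3, d = 2L, a = 0.5, seed = NULL,
                           sd = 1) {
  if (!is.null(seed)) set.seed(seed)
  y <- matrix(0, d, n)
  for (t in 2:n) {
    y[, t] <- a * y[, t - 1L] + stats::rnorm(d, sd = sd)
    if (d >= 2L) y[2L, t] <- y[2L, t] + coupling * y[1L, t - 1L]
  }
  y
}

# Simulate from explicit coefficient matrices.
sim_var <- function(A, n, seed = NULL, sd = 1, burn = 200L) {
  if (!is.null(seed)) set.seed(seed)
  d <- nrow(A[[1L]]); p <- length(A)
  y <- matrix(0, d, n + burn)
  for (t in (p + 1L):(n + burn)) {
    acc <- stats::rnorm(d, sd = sd)
    for (k in seq_len(p)) acc <- acc + A[[k]] %*% y[, t - k]
    y[, t] <- acc
  }
  y[, (burn + 1L):(n + burn), drop = FALSE]
}

add_noise_snr <- function(y, snr_db = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- matrix(stats::rnorm(length(y)), nrow(y))
  y + n * sqrt(mean(y^2) / 10^(snr_db / 10)) / sqrt(mean(n^2))
}

# Sinusoid-in-noise epoched recording.
sine_recording <- function(freq = 10, fs = 256, n_epochs = 20L, n_ch = 3L,
                           noise_sd = 0.3, seed = 1L) {
  set.seed(seed)
  tt <- seq(0, 1 - 1 / fs, by = 1 / fs)
  x <- array(0, c(n_ch, fs, n_epochs))
  for (e in seq_len(n_epochs)) for (ch in seq_len(n_ch))
    x[ch, , e] <- sin(2 * pi * freq * tt + stats::runif(1) * 2 * pi) +
      stats::rnorm(fs, sd = noise_sd)
  epoched_recording(x, fs)
}

white_recording <- function(fs = 256, n_epochs = 50L, n_ch = 2L, seed = 1L) {
  set.seed(seed)
  epoched_recording(array(stats::rnorm(n_ch * fs * n_epochs),
                          c(n_ch, fs, n_epochs)), fs)
}

# Independent band-limited resonator source (10.5 Hz, pole radius 0.95).
ar2_source <- function(n, fs = 256, f0 = 10.5, r = 0.95) {
  a <- c(2 * r * cos(2 * pi * f0 / fs), -r^2)
  as.numeric(stats::filter(rnorm(n + 200), a, method = "recursive"))[-(1:200)]
}

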