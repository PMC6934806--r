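#' @title Synthetic directed-network cohorts
#' @description Ground-truth directed networks of band-limited oscillators,
#'   VAR simulation, synthetic lead fields and two-group sensor-level
#'   cohorts. These emulate the statistical structure that the connectivity
#'   pipeline assumes: band-limited sources, lagged directed coupling that is
#'   bidirectional in a control-like group and weaker/unidirectional in a
#'   patient-like group, higher temporal coupling variability in the
#'   patient-like group, and optional instantaneous sensor mixing emulating
#'   volume conduction.
#' @name synthdata
NULL

band_center <- function(name) {
  b <- band_by_name(name)
  (b$lo + b$hi) / 2
}

#' Companion matrix of a VAR coefficient set
#'
#' @param A list of p square coefficient matrices A1..Ap.
#' @return the (p d) x (p d) companion matrix.
#' @export
companion_matrix <- function(A) {
  p <- length(A)
  d <- nrow(A[[1L]])
  M <- matrix(0, p * d, p * d)
  for (k in seq_len(p)) M[seq_len(d), (k - 1L) * d + seq_len(d)] <- A[[k]]
  if (p > 1L) M[(d + 1L):(p * d), seq_len((p - 1L) * d)] <- diag((p - 1L) * d)
  M
}

spectral_radius <- function(A) max(Mod(eigen(companion_matrix(A), only.values = TRUE)$values))

# Pole radius per band: the AR(2) resonance half-width is about
# fs (1 - r) / pi, so the radius is set to keep it at 40% of the band
# width (never below 0.95), concentrating each source's power in its band.
band_pole_radius <- function(band_name, fs) {
  b <- band_by_name(band_name)
  max(0.95, exp(-0.4 * pi * (b$hi - b$lo) / fs))
}

# Per-source pole frequencies: spread across the middle half of each band so
# same-band sources are spectrally distinct (identical-frequency resonators
# injection-lock through coupling and defeat beamformer separation).
source_pole_freqs <- function(source_bands) {
  n <- length(source_bands)
  pos <- if (n == 1L) 0.5 else 0.25 + 0.5 * (seq_len(n) - 1L) / (n - 1L)
  vapply(seq_len(n), function(i) {
    b <- band_by_name(source_bands[i])
    b$lo + pos[i] * (b$hi - b$lo)
  }, numeric(1L))
}

# Diagonal AR(2) resonator blocks plus lag-1 cross-coupling from the edge
# table. Returns list(A1, A2).
assemble_var <- function(n_sources, source_bands, edges, fs, pole_radius,
                         source_freqs = NULL) {
  if (is.null(source_freqs)) source_freqs <- source_pole_freqs(source_bands)
  th <- 2 * pi * source_freqs / fs
  if (length(pole_radius) == 1L) pole_radius <- rep(pole_radius, n_sources)
  A1 <- diag(2 * pole_radius * cos(th), n_sources)
  A2 <- diag(-pole_radius^2, n_sources)
  if (nrow(edges) > 0L)
    for (i in seq_len(nrow(edges)))
      A1[edges$to[i], edges$from[i]] <- A1[edges$to[i], edges$from[i]] + edges$coupling[i]
  list(A1, A2)
}

# Down-scale the cross-coupling by 0.9 repeatedly until the companion matrix
# is stable (spectral radius < 1). Warns when rescaling was needed.
stabilize_network <- function(net, max_iter = 20L, quiet = FALSE) {
  A <- assemble_var(net$n_sources, net$source_bands, net$edges, net$fs,
                    net$pole_radius, net$source_freqs)
  it <- 0L
  while (spectral_radius(A) >= 1 && it < max_iter) {
    net$edges$coupling <- net$edges$coupling * 0.9
    A <- assemble_var(net$n_sources, net$source_bands, net$edges, net$fs,
                      net$pole_radius, net$source_freqs)
    it <- it + 1L
  }
  if (spectral_radius(A) >= 1)
    stop("network remains unstable after ", max_iter, " coupling rescales")
  if (it > 0L && !quiet)
    warning(sprintf("cross-coupling rescaled by 0.9^%d to restore stability", it))
  net$A <- A
  net
}

#' Ground-truth directed network for one study group
#'
#' Builds the two group templates that encode the headline thalamo-cortical
#' contrast: in the control-like template every designated "cortical" node
#' (nodes `1..n_sources-1`) exchanges reciprocal lag-1 coupling with the
#' "thalamic" node (`n_sources`); in the patient-like template only the
#' cortex-to-thalamus direction is present, at reduced strength and with a
#' larger slow modulation of the coupling coefficient over time.
#'
#' Every source is an AR(2) resonator inside its assigned band: pole
#' frequencies are spread across the middle half of the band so same-band
#' sources stay spectrally distinct, and the pole radius is derived from
#' the band width (never below 0.95) so each resonance stays inside the
#' band; cross-coupling enters at lag 1. If
#' inserting the couplings destabilizes the induced VAR, the cross-coupling
#' is scaled down by 0.9 (at most 20 times) with a warning. Reciprocal
#' coupling between slow narrow-band resonators (delta, theta) sits outside
#' the stabilizable region and raises the rescaling-failure error.
#'
#' @param group_label `"control"` (bidirectional template) or `"patient"`
#'   (unidirectional, weaker, more modulated).
#' @param n_sources number of sources (>= 2); the last is the thalamus analog.
#' @param band_assignment band name per source (recycled).
#' @param coupling_strength lag-1 coupling coefficient; defaults to 0.3
#'   (control) or 0.15 (patient).
#' @param modulation_amplitude relative amplitude of the slow coupling
#'   modulation; defaults to 0 (control) or 0.2 (patient).
#' @param fs sampling rate (Hz) at which the oscillator poles are placed.
#' @param seed optional integer seed (templates are deterministic; kept for
#'   interface symmetry).
#' @return object of class `ground_truth_network`.
#' @export
make_group_network <- function(group_label = c("control", "patient"),
                               n_sources = 4L,
                               band_assignment = "alpha",
                               coupling_strength = NULL,
                               modulation_amplitude = NULL,
                               fs = 256,
                               seed = NULL) {
  group_label <- match.arg(group_label)
  if (n_sources < 2L) stop("'n_sources' must be >= 2")
  if (is.null(coupling_strength))
    coupling_strength <- if (group_label == "control") 0.3 else 0.15
  if (is.null(modulation_amplitude))
    modulation_amplitude <- if (group_label == "control") 0.0 else 0.2
  if (coupling_strength < 0) stop("'coupling_strength' must be >= 0")
  source_bands <- rep_len(band_assignment, n_sources)
  thal <- n_sources
  cortical <- seq_len(n_sources - 1L)
  from <- cortical
  to <- rep(thal, length(cortical))
  if (group_label == "control") {          # reciprocal pairs
    from <- c(from, rep(thal, length(cortical)))
    to <- c(to, cortical)
  }
  edges <- data.frame(from = from, to = to,
                      band = source_bands[from],
                      coupling = coupling_strength,
                      modulation = modulation_amplitude,
                      stringsAsFactors = FALSE)
  net <- structure(list(group = group_label, n_sources = n_sources,
                        source_bands = source_bands,
                        source_freqs = source_pole_freqs(source_bands),
                        edges = edges,
                        fs = fs,
                        pole_radius = vapply(source_bands, band_pole_radius,
                                             numeric(1L), fs = fs),
                        order = 2L),
                   class = "ground_truth_network")
  stabilize_network(net)
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat(sprintf("Ground-truth network (%s-like): %d sources, %d directed edges @ %g Hz\n",
              x$group, x$n_sources, nrow(x$edges), x$fs))
  if (nrow(x$edges) > 0L)
    cat(paste(sprintf("  %d -> %d (%s, c=%.3g, mod=%.2g)", x$edges$from,
                      x$edges$to, x$edges$band, x$edges$coupling,
                      x$edges$modulation), collapse = "\n"), "\n")
  invisible(x)
}

# Smoothed standard-normal random walk, standardized to zero mean / unit sd;
# the carrier of slow coupling modulation.
smooth_walk <- function(n, fs, seed_offset = 0L) {
  r <- cumsum(stats::rnorm(n))
  L <- max(5L, round(fs / 4))
  s <- stats::filter(r, rep(1 / L, L), sides = 2L)
  s[is.na(s)] <- r[is.na(s)]
  s <- as.numeric(s)
  sdv <- stats::sd(s)
  if (sdv < .Machine$double.eps) return(rep(0, n))
  (s - mean(s)) / sdv
}

#' Simulate source time series from a ground-truth network
#'
#' Generates the coupled AR(2) resonator system sample by sample. Edges with
#' a positive modulation amplitude have their coupling coefficient scaled by
#' `1 + modulation_amplitude * s(t)` where `s` is a smoothed standard-normal
#' random walk, yielding slowly time-varying directed coupling.
#'
#' @param network a `ground_truth_network`.
#' @param n_samples samples to return (after an internal 200-sample burn-in).
#' @param fs sampling rate; must match the network's.
#' @param seed integer seed; the output is a pure function of
#'   (network, n_samples, seed).
#' @param innovation_sd innovation noise standard deviation.
#' @return numeric matrix, sources x samples, zero-mean.
#' @export
simulate_var_timeseries <- function(network, n_samples, fs = network$fs,
                                    seed = NULL, innovation_sd = 1) {
  stopifnot(inherits(network, "ground_truth_network"))
  if (fs != network$fs) stop("'fs' must match the network sampling rate")
  p <- network$order
  if (n_samples < 10L * p) stop("'n_samples' must be at least 10x the model order")
  if (!is.null(seed)) set.seed(seed)
  d <- network$n_sources
  burn <- 200L
  ntot <- n_samples + burn
  A1 <- network$A[[1L]]; A2 <- network$A[[2L]]
  mod_edges <- which(network$edges$modulation > 0)
  mods <- lapply(mod_edges, function(i) smooth_walk(ntot, fs))
  eps <- matrix(stats::rnorm(d * ntot, sd = innovation_sd), d, ntot)
  y <- matrix(0, d, ntot)
  guard <- 1e6
  for (t in 3:ntot) {
    A1t <- A1
    if (length(mod_edges) > 0L) {
      for (k in seq_along(mod_edges)) {
        e <- network$edges[mod_edges[k], ]
        A1t[e$to, e$from] <- e$coupling * (1 + e$modulation * mods[[k]][t])
      }
    }
    y[, t] <- A1t %*% y[, t - 1L] + A2 %*% y[, t - 2L] + eps[, t]
    if (any(abs(y[, t]) > guard)) {
      j <- which.max(abs(y[, t]))
      stop(sprintf("simulation diverged at sample %d (source %d); offending diagonal coefficient %.3g",
                   t, j, A1[j, j]))
    }
  }
  out <- y[, (burn + 1L):ntot, drop = FALSE]
  out - rowMeans(out)
}

#' Synthetic lead field on a regular voxel grid
#'
#' Random Gaussian gain columns, normalized to unit norm, over a regular
#' 3-D grid (default 5 mm spacing). Columns are checked for separability
#' (maximal pairwise correlation below `max_corr`); degenerate draws are
#' regenerated with a shifted seed a bounded number of times.
#'
#' @param n_channels sensors (rows).
#' @param grid_shape integer 3-vector of voxels per axis (>= 27 voxels total).
#' @param grid_spacing_mm grid spacing in mm (default 5).
#' @param seed integer seed.
#' @param max_corr column-correlation bound (default 0.99).
#' @return object of class `leadfield` with `gain` (channels x voxels),
#'   `voxel_coords` (voxels x 3, mm), `grid_shape`, `grid_spacing`.
#' @export
make_leadfield <- function(n_channels, grid_shape = c(6L, 6L, 6L),
                           grid_spacing_mm = 5, seed = NULL, max_corr = 0.99) {
  if (length(grid_shape) != 3L || prod(grid_shape) < 27L)
    stop("'grid_shape' must give at least 27 voxels")
  if (grid_spacing_mm <= 0) stop("'grid_spacing_mm' must be positive")
  nv <- prod(grid_shape)
  for (try in 0:4) {
    if (!is.null(seed)) set.seed(seed + try)
    G <- matrix(stats::rnorm(n_channels * nv), n_channels, nv)
    G <- sweep(G, 2L, colMeans(G))          # average-referenced, like EEG gains
    G <- sweep(G, 2L, sqrt(colSums(G^2)), `/`)
    cc <- abs(stats::cor(G))
    diag(cc) <- 0
    if (max(cc) < max_corr) {
      coords <- as.matrix(expand.grid(x = seq_len(grid_shape[1L]),
                                      y = seq_len(grid_shape[2L]),
                                      z = seq_len(grid_shape[3L]))) * grid_spacing_mm
      return(structure(list(gain = G, voxel_coords = coords,
                            grid_shape = as.integer(grid_shape),
                            grid_spacing = grid_spacing_mm),
                       class = "leadfield"))
    }
  }
  stop("could not generate a separable lead field (columns nearly collinear)")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("Lead field: %d channels x %d voxels (%dx%dx%d grid, %g mm)\n",
              nrow(x$gain), ncol(x$gain), x$grid_shape[1], x$grid_shape[2],
              x$grid_shape[3], x$grid_spacing))
  invisible(x)
}

#' Cohort specification
#'
#' Parameters of a simulated two-group cohort. Defaults mirror a small
#' resting-state study: 11 subjects per group, 280 one-second epochs, 56
#' channels. The sampling rate defaults to 256 Hz, which keeps every
#' analysis band (<= 49 Hz) far below Nyquist at desk scale.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param n_epochs epochs per subject.
#' @param epoch_len epoch length in seconds.
#' @param fs sampling rate (Hz); must exceed twice the highest band edge.
#' @param n_channels sensors.
#' @param snr_db sensor signal-to-noise ratio in dB.
#' @param leakage instantaneous cross-channel mixing coefficient in [0, 1].
#' @param jitter_sd relative between-subject jitter of coupling coefficients.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 11L, n_epochs = 280L, epoch_len = 1,
                        fs = 256, n_channels = 56L, snr_db = 10,
                        leakage = 0, jitter_sd = 0.05, seed = 1L) {
  if (n_per_group < 2L) stop("'n_per_group' must be >= 2")
  if (fs <= 2 * 98) stop("'fs' must exceed twice the highest band edge (98 Hz)")
  if (leakage < 0 || leakage > 1) stop("'leakage' must lie in [0, 1]")
  if (n_epochs < 1L || epoch_len <= 0) stop("invalid epoching parameters")
  structure(list(n_per_group = as.integer(n_per_group),
                 n_epochs = as.integer(n_epochs), epoch_len = epoch_len,
                 fs = fs, n_channels = as.integer(n_channels),
                 snr_db = snr_db, leakage = leakage,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# 1/f-amplitude (pink) noise via spectral shaping of white noise.
pink_noise <- function(n) {
  X <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1L))
  f <- pmin(f, n - f + 1)
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

# Symmetric (approximately doubly) stochastic mixing matrix.
sym_stochastic <- function(n, iters = 50L) {
  M <- matrix(stats::runif(n * n), n, n)
  M <- (M + t(M)) / 2
  for (i in seq_len(iters)) {
    M <- M / rowSums(M)
    M <- (M + t(M)) / 2
  }
  M
}

#' Simulate a two-group sensor-level cohort
#'
#' For each subject: the group template's coupling coefficients are jittered
#' multiplicatively (`jitter_sd`), source signals are simulated, sources are
#' placed at randomly chosen distinct voxels of the lead field, and sensor
#' data are formed as lead-field projection plus 50/50 white-plus-pink
#' sensor noise at `snr_db`, optionally followed by instantaneous
#' cross-channel mixing `(1 - leakage) I + leakage M` with `M` a random
#' symmetric stochastic matrix (a volume-conduction stand-in; the mixing is
#' zero-lag by construction, so the time-reversal test should reject edges
#' it induces). The result is epoched into `n_epochs` segments.
#'
#' @param spec a [cohort_spec()].
#' @param control_network,patient_network group templates from
#'   [make_group_network()].
#' @param leadfield optional [make_leadfield()] result; generated from the
#'   spec when missing.
#' @return object of class `cohort`: `recordings` (list of
#'   [epoched_recording]), `networks` (per-subject jittered truths),
#'   `labels` (`"control"`/`"patient"`), `source_voxels` (per subject),
#'   `leadfield`, `spec`.
#' @export
make_cohort <- function(spec, control_network, patient_network, leadfield = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(leadfield))
    leadfield <- make_leadfield(spec$n_channels, seed = spec$seed + 7919L)
  if (nrow(leadfield$gain) != spec$n_channels)
    stop("lead-field channel count does not match the cohort spec")
  n_samp <- round(spec$n_epochs * spec$epoch_len * spec$fs)
  epoch_samp <- round(spec$epoch_len * spec$fs)
  labels <- rep(c("control", "patient"), each = spec$n_per_group)
  templates <- list(control = control_network, patient = patient_network)
  recordings <- vector("list", length(labels))
  networks <- vector("list", length(labels))
  source_voxels <- vector("list", length(labels))
  for (s in seq_along(labels)) {
    sseed <- spec$seed * 1000L + s
    set.seed(sseed)
    net <- templates[[labels[s]]]
    if (spec$jitter_sd > 0 && nrow(net$edges) > 0L) {
      net$edges$coupling <- net$edges$coupling *
        (1 + stats::rnorm(nrow(net$edges), sd = spec$jitter_sd))
      net <- stabilize_network(net, quiet = TRUE)
    }
    src <- simulate_var_timeseries(net, n_samp, seed = sseed + 1L)
    vox <- sample(ncol(leadfield$gain), net$n_sources)
    sensors <- leadfield$gain[, vox, drop = FALSE] %*% src
    sig_pow <- mean(sensors^2)
    if (sig_pow <= 0) stop("projected signal power is zero; check snr/coupling settings")
    nch <- spec$n_channels
    noise <- matrix(stats::rnorm(nch * n_samp), nch, n_samp) / sqrt(2) +
      t(vapply(seq_len(nch), function(i) pink_noise(n_samp), numeric(n_samp))) / sqrt(2)
    noise <- noise * sqrt(sig_pow / 10^(spec$snr_db / 10)) / sqrt(mean(noise^2))
    sensors <- sensors + noise
    if (spec$leakage > 0) {
      M <- (1 - spec$leakage) * diag(nch) + spec$leakage * sym_stochastic(nch)
      sensors <- M %*% sensors
    }
    recordings[[s]] <- epoched_recording(
      array(sensors[, seq_len(epoch_samp * spec$n_epochs)],
            dim = c(nch, epoch_samp, spec$n_epochs)),
      fs = spec$fs, modality = "synthetic")
    networks[[s]] <- net
    source_voxels[[s]] <- vox
  }
  structure(list(recordings = recordings, networks = networks, labels = labels,
                 source_voxels = source_voxels, leadfield = leadfield,
                 spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%d control, %d patient), %d epochs x %g s @ %g Hz\n",
              length(x$labels), sum(x$labels == "control"),
              sum(x$labels == "patient"), x$spec$n_epochs, x$spec$epoch_len,
              x$spec$fs))
  invisible(x)
}
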