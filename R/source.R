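#' Band-averaged cross-spectral density matrix
#'
#' Mean over epochs and over the band's frequency bins of the tapered
#' Fourier cross-products. Hermitian symmetry is enforced by averaging the
#' matrix with its conjugate transpose. When there are fewer epochs than
#' channels the CSD is rank deficient and a warning flag is recorded
#' (beamformer regularization handles this downstream).
#'
#' @param recording a preprocessed [epoched_recording].
#' @param band one-row band data.frame or band name.
#' @param resolution_hz frequency resolution (default 0.25 Hz).
#' @param taper `"tukey01"` or `"hann"`.
#' @return object of class `csd` with fields `matrix` (channels x channels,
#'   complex), `band`, `n_epochs`, `rank_warning`.
#' @export
csd_matrix <- function(recording, band, resolution_hz = 0.25, taper = "tukey01") {
  if (is.character(band)) band <- band_by_name(band)
  if (band$hi > recording$fs / 2) stop("band exceeds the Nyquist frequency")
  ef <- epoch_ffts(recording, resolution_hz, taper)
  idx <- band_bins(ef$freqs, band$lo, band$hi)
  if (length(idx) == 0L) stop("band contains no frequency bins")
  csd_from_ffts(ef, idx, band)
}

csd_from_ffts <- function(ef, idx, band) {
  nch <- dim(ef$coef)[1L]; ne <- dim(ef$coef)[3L]
  S <- matrix(0i, nch, nch)
  for (f in idx) {
    Xf <- matrix(ef$coef[, f, ], nch, ne)
    S <- S + Xf %*% Conj(t(Xf)) / ne
  }
  S <- S / length(idx)
  S <- (S + Conj(t(S))) / 2
  structure(list(matrix = S, band = band, n_epochs = ne,
                 rank_warning = ne < nch),
            class = "csd")
}

#' @export
print.csd <- function(x, ...) {
  cat(sprintf("CSD: %d x %d channels, band [%g, %g] Hz, %d epochs%s\n",
              nrow(x$matrix), ncol(x$matrix), x$band$lo, x$band$hi,
              x$n_epochs,
              if (x$rank_warning) " (rank-deficient: fewer epochs than channels)" else ""))
  invisible(x)
}

#' DICS beamformer spatial filters
#'
#' Per voxel, the unit-gain minimum-variance spatial filter
#' `w = (l' C^-1 l)^-1 l' C^-1` with `C = Re(CSD) + reg_lambda * mean-diag *
#' I`. The unit-gain constraint `w l = 1` holds at every voxel.
#'
#' @param leadfield a [make_leadfield()] object.
#' @param csd a `csd` object.
#' @param reg_lambda regularization as a fraction of the mean CSD diagonal
#'   (default 0.05).
#' @return object of class `dics_filter` with `weights` (voxels x channels)
#'   and the `leadfield` it was built on.
#' @export
dics_filter <- function(leadfield, csd, reg_lambda = 0.05) {
  stopifnot(inherits(leadfield, "leadfield"), inherits(csd, "csd"))
  G <- leadfield$gain
  if (nrow(G) != nrow(csd$matrix)) stop("lead-field channels do not match the CSD dimension")
  C <- Re(csd$matrix) + reg_lambda * mean(Re(diag(csd$matrix))) * diag(nrow(G))
  kap <- kappa(C, exact = FALSE)
  Cinv <- tryCatch(solve(C), error = function(e)
    stop(sprintf("regularized CSD is singular (condition number %.3g)", kap)))
  CiG <- Cinv %*% G                        # channels x voxels
  gain <- colSums(G * CiG)                 # l' C^-1 l per voxel
  W <- t(CiG) / gain                       # voxels x channels
  structure(list(weights = W, leadfield = leadfield, reg_lambda = reg_lambda,
                 band = csd$band),
            class = "dics_filter")
}

#' Voxel source-power map
#'
#' Projects the CSD through the beamformer: voxel power
#' `p_v = Re(w_v S w_v^H)`. Peaks are the local maxima over the voxel grid
#' (26-neighbourhood), sorted by descending power; they are unflagged until
#' a surrogate analysis assigns significance.
#'
#' @param filter a `dics_filter`.
#' @param csd the `csd` the map is evaluated on.
#' @return object of class `source_map` with `voxel_power`, `peaks`
#'   (data.frame: voxel, power, flagged), `leadfield`, `band`.
#' @export
source_power_map <- function(filter, csd) {
  stopifnot(inherits(filter, "dics_filter"), inherits(csd, "csd"))
  pw <- map_power(filter$weights, csd$matrix)
  if (any(pw < -1e-9)) stop("negative voxel power: broken CSD or filter")
  pw <- pmax(pw, 0)
  lf <- filter$leadfield
  pk <- grid_local_maxima(pw, lf$grid_shape)
  peaks <- data.frame(voxel = pk, power = pw[pk], flagged = FALSE)
  peaks <- peaks[order(-peaks$power), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(voxel_power = pw, peaks = peaks, leadfield = lf,
                 band = csd$band),
            class = "source_map")
}

map_power <- function(W, S) {
  WS <- W %*% S
  Re(rowSums(WS * Conj(W)))
}

#' @export
print.source_map <- function(x, ...) {
  cat(sprintf("Source map: %d voxels, band [%g, %g] Hz, %d peaks (%d flagged)\n",
              length(x$voxel_power), x$band$lo, x$band$hi,
              nrow(x$peaks), sum(x$peaks$flagged)))
  invisible(x)
}

# 26-neighbourhood voxel indices on a regular grid (the voxel itself excluded).
grid_neighbors <- function(v, shape) {
  nz <- shape[1L] * shape[2L]
  z <- (v - 1L) %/% nz
  r <- (v - 1L) %% nz
  y <- r %/% shape[1L]
  x <- r %% shape[1L]
  out <- integer(0)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0L && dy == 0L && dz == 0L) next
    xx <- x + dx; yy <- y + dy; zz <- z + dz
    if (xx < 0L || xx >= shape[1L] || yy < 0L || yy >= shape[2L] ||
        zz < 0L || zz >= shape[3L]) next
    out <- c(out, xx + yy * shape[1L] + zz * nz + 1L)
  }
  out
}

grid_local_maxima <- function(pw, shape) {
  Filter(function(v) all(pw[v] >= pw[grid_neighbors(v, shape)]) &&
           any(pw[v] > pw[grid_neighbors(v, shape)]),
         seq_along(pw))
}

#' Surrogate-flagged peak selection
#'
#' Monte-Carlo permutation surrogates for within-subject peak significance:
#' per permutation the epoch order is shuffled independently per channel
#' (destroying cross-channel covariance while preserving each channel's
#' spectrum), the CSD and the source-power map are recomputed, and a peak is
#' flagged significant when its observed power exceeds the chosen quantile
#' (default 99th percentile) of its voxel's surrogate power distribution.
#'
#' @param recording a preprocessed [epoched_recording] (>= 20 epochs).
#' @param band band data.frame or name.
#' @param leadfield a [make_leadfield()] object.
#' @param n_perm number of permutations (default 100, >= 20 required).
#' @param seed integer seed.
#' @param reg_lambda beamformer regularization.
#' @param prob surrogate quantile (default 0.99).
#' @param resolution_hz,taper spectral settings passed to the CSD.
#' @return a `source_map` with the `flagged` column of `peaks` set, plus a
#'   `surrogate` element holding the voxels x permutations power array.
#' @export
peak_selection_surrogate <- function(recording, band, leadfield, n_perm = 100L,
                                     seed = NULL, reg_lambda = 0.05,
                                     prob = 0.99, resolution_hz = 0.25,
                                     taper = "tukey01") {
  if (is.character(band)) band <- band_by_name(band)
  if (n_perm < 20L) stop("'n_perm' must be >= 20 for a stable percentile")
  if (dim(recording$data)[3L] < 20L) stop("at least 20 epochs are required")
  if (!is.null(seed)) set.seed(seed)
  ef <- epoch_ffts(recording, resolution_hz, taper)
  idx <- band_bins(ef$freqs, band$lo, band$hi)
  obs_csd <- csd_from_ffts(ef, idx, band)
  obs_filter <- dics_filter(leadfield, obs_csd, reg_lambda)
  obs_map <- source_power_map(obs_filter, obs_csd)
  nch <- dim(ef$coef)[1L]; ne <- dim(ef$coef)[3L]
  surr <- matrix(0, ncol(leadfield$gain), n_perm)
  for (b in seq_len(n_perm)) {
    perm <- vapply(seq_len(nch), function(i) sample.int(ne), integer(ne))
    efp <- ef
    for (ch in seq_len(nch)) efp$coef[ch, , ] <- ef$coef[ch, , perm[, ch]]
    cs <- csd_from_ffts(efp, idx, band)
    fl <- dics_filter(leadfield, cs, reg_lambda)
    surr[, b] <- map_power(fl$weights, cs$matrix)
  }
  thr <- apply(surr, 1L, stats::quantile, probs = prob, names = FALSE)
  obs_map$peaks$flagged <- obs_map$voxel_power[obs_map$peaks$voxel] >
    thr[obs_map$peaks$voxel]
  obs_map$surrogate <- surr
  obs_map$surrogate_quantile <- prob
  obs_map
}

#' Pooled regional source signals
#'
#' For every flagged peak, the region is the peak voxel plus its
#' 26-neighbourhood on the grid. Each region voxel's time series is obtained
#' by applying its beamformer weights to the sensor data. The voxels are
#' combined through their band-limited second-order statistics: the region's
#' band CSD is projected through the beamformer, voxels are weighted by
#' their share of the region's band power, and the pooling direction is the
#' leading eigenvector of the weighted region CSD, so the pooled (broadband)
#' signal maximizes variance in the analyzed frequency range rather than
#' wherever broadband noise is strongest. The sign is fixed so the pooled
#' signal correlates positively with the peak voxel's series.
#'
#' @param recording the preprocessed [epoched_recording].
#' @param filter the `dics_filter` used for the map.
#' @param source_map a `source_map` with at least one flagged peak.
#' @param max_sources optional cap on the number of pooled regions (top
#'   flagged peaks by power).
#' @param csd optional sensor `csd` for the map's band; recomputed from the
#'   recording when missing.
#' @return object of class `pooled_sources` with `signals` (sources x
#'   samples x epochs), `regions` (list of voxel sets), `peaks`, `band`, `fs`.
#' @export
pooled_source_signal <- function(recording, filter, source_map,
                                 max_sources = NULL, csd = NULL) {
  stopifnot(inherits(source_map, "source_map"))
  pk <- source_map$peaks[source_map$peaks$flagged, , drop = FALSE]
  if (nrow(pk) == 0L) stop("no flagged peaks: nothing to pool")
  if (!is.null(max_sources)) pk <- pk[seq_len(min(nrow(pk), max_sources)), , drop = FALSE]
  if (is.null(csd)) csd <- csd_matrix(recording, source_map$band)
  lf <- source_map$leadfield
  x <- recording$data
  nch <- dim(x)[1L]; n <- dim(x)[2L]; ne <- dim(x)[3L]
  xs <- matrix(x, nch, n * ne)
  signals <- array(0, dim = c(nrow(pk), n, ne))
  regions <- vector("list", nrow(pk))
  for (r in seq_len(nrow(pk))) {
    region <- c(pk$voxel[r], grid_neighbors(pk$voxel[r], lf$grid_shape))
    regions[[r]] <- region
    W <- filter$weights[region, , drop = FALSE]
    V <- W %*% xs                           # voxels x (samples*epochs)
    Sr <- Re(W %*% csd$matrix %*% Conj(t(W)))  # region band CSD
    pw <- pmax(diag(Sr), 0)
    wts <- sqrt(pw / sum(pw))               # band-power-share weighting
    Srw <- Sr * (wts %o% wts)
    u1 <- eigen((Srw + t(Srw)) / 2, symmetric = TRUE)$vectors[, 1L]
    pooled <- as.numeric(crossprod(u1 * wts, V))
    if (stats::cor(pooled, V[1L, ]) < 0) pooled <- -pooled
    signals[r, , ] <- pooled
  }
  structure(list(signals = signals, regions = regions, peaks = pk,
                 band = source_map$band, fs = recording$fs),
            class = "pooled_sources")
}

#' @export
print.pooled_sources <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf("Pooled source signals: %d regions x %d samples x %d epochs (band [%g, %g] Hz)\n",
              d[1], d[2], d[3], x$band$lo, x$band$hi))
  invisible(x)
}

#' Euclidean distance between rank-matched peaks of two maps
#'
#' Flagged peaks are matched by descending-power rank; if the flagged counts
#' differ, remaining peaks are matched greedily to their nearest unmatched
#' counterpart and the surplus is reported as unmatched.
#'
#' @param map_a,map_b `source_map` objects sharing a grid.
#' @return list with `distance_mm` (per matched pair) and `unmatched`
#'   (count of unmatched peaks).
#' @export
peak_distance <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "source_map"), inherits(map_b, "source_map"))
  if (!identical(map_a$leadfield$grid_shape, map_b$leadfield$grid_shape))
    stop("maps are defined on different grids")
  co <- map_a$leadfield$voxel_coords
  pa <- map_a$peaks$voxel[map_a$peaks$flagged]
  pb <- map_b$peaks$voxel[map_b$peaks$flagged]
  k <- min(length(pa), length(pb))
  dists <- numeric(0)
  if (k > 0L) {
    dists <- sqrt(rowSums((co[pa[seq_len(k)], , drop = FALSE] -
                           co[pb[seq_len(k)], , drop = FALSE])^2))
    rest_a <- pa[-seq_len(k)]; rest_b <- pb[-seq_len(k)]
    extra <- if (length(rest_a) > 0L) rest_a else rest_b
    pool <- if (length(rest_a) > 0L) pb else pa
    for (v in extra) {
      dd <- sqrt(rowSums(sweep(co[pool, , drop = FALSE], 2L, co[v, ])^2))
      dists <- c(dists, min(dd))
    }
  }
  list(distance_mm = dists, unmatched = abs(length(pa) - length(pb)))
}
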