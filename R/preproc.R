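#' Preprocessing configuration
#'
#' Numeric parameters of the functional preprocessing chain. Defaults follow
#' a high-field mouse rs-fMRI protocol: 0.3 mm FWHM in-plane smoothing and a
#' 0.01--0.08 Hz band-pass.
#'
#' @param fwhm_mm in-plane Gaussian smoothing FWHM in mm (>= 0; 0 disables).
#' @param band length-2 Hz pair `(low, high)`, `0 < low < high`; `high` must
#'   stay below the Nyquist frequency `1/(2 tr)` of the series it is applied
#'   to (checked at filter time).
#' @param drift_order polynomial drift order regressed out (0, 1 or 2).
#' @param include_respiration,include_motion include the recorded nuisance
#'   series in the regression design.
#' @return An object of class `preproc_config`.
#' @export
preproc_config <- function(fwhm_mm = 0.3, band = c(0.01, 0.08),
                           drift_order = 2L, include_respiration = TRUE,
                           include_motion = TRUE) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  band <- as.numeric(band)
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1]) {
    stop("band must satisfy 0 < low < high")
  }
  structure(list(fwhm_mm = fwhm_mm, band = band,
                 drift_order = as.integer(drift_order),
                 include_respiration = isTRUE(include_respiration),
                 include_motion = isTRUE(include_motion)),
            class = "preproc_config")
}

# polynomial drift basis on the frame index: intercept handled separately,
# columns are centered monomials (t, t^2) so they are well scaled
drift_basis <- function(n_frames, order) {
  if (order == 0L) return(NULL)
  t <- seq_len(n_frames) - (n_frames + 1) / 2
  t <- t / max(abs(t))
  b <- sapply(seq_len(order), function(k) t^k)
  colnames(b) <- paste0("drift", seq_len(order))
  b
}

# design matrix for nuisance regression: intercept + drifts + respiration +
# motion, with all-zero columns dropped
nuisance_design <- function(nuisance, n_frames, drift_order,
                            include_respiration = TRUE,
                            include_motion = TRUE) {
  X <- cbind(intercept = rep(1, n_frames), drift_basis(n_frames, drift_order))
  if (include_respiration && !is.null(nuisance$respiration)) {
    X <- cbind(X, respiration = nuisance$respiration)
  }
  if (include_motion && !is.null(nuisance$motion)) {
    mo <- nuisance$motion
    colnames(mo) <- paste0("motion", 1:6)
    X <- cbind(X, mo)
  }
  keep <- colSums(X != 0) > 0
  X <- X[, keep, drop = FALSE]
  if (qr(X)$rank < ncol(X)) {
    stop("nuisance design matrix is rank deficient")
  }
  X
}

#' Regress nuisance series out of a BOLD dataset
#'
#' Ordinary least squares of every voxel time series on a design of
#' intercept, polynomial drifts up to `drift_order`, the recorded respiratory
#' trace and the six motion parameters; the returned data are the residuals.
#' Linear detrending is subsumed by the drift terms: including the drift
#' columns in one joint regression is algebraically equivalent to detrending
#' first and regressing afterwards.
#'
#' @param bold a [bold4d()].
#' @param nuisance a [nuisance_set()] with series of length `bold$n_frames`.
#' @param drift_order polynomial drift order (default: the nuisance set's).
#' @param include_respiration,include_motion design column switches.
#' @return A `bold4d` of residuals (orthogonal to every design column).
#' @export
regress_nuisance <- function(bold, nuisance,
                             drift_order = nuisance$drift_order,
                             include_respiration = TRUE,
                             include_motion = TRUE) {
  nt <- bold$n_frames
  if (nuisance$n_frames != nt) {
    stop(sprintf("nuisance series length %d does not match %d frames",
                 nuisance$n_frames, nt))
  }
  X <- nuisance_design(nuisance, nt, as.integer(drift_order),
                       include_respiration, include_motion)
  qrX <- qr(X)
  nvox <- prod(dim(bold$data)[1:3])
  Y <- matrix(bold$data, nvox, nt)
  res <- t(qr.resid(qrX, t(Y)))
  bold4d(array(res, dim(bold$data)), bold$geometry, bold$tr)
}

# one-dimensional zero-padded Gaussian convolution matrix (n x n)
gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 1e-8) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  off <- (-r):r
  w <- exp(-off^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (d in seq_along(off)) {
    i <- seq_len(n)
    j <- i + off[d]
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- K[cbind(i[ok], j[ok])] + w[d]
  }
  K
}

#' In-plane Gaussian smoothing
#'
#' Convolves each slice of each frame with a separable 2D Gaussian of
#' `sigma = fwhm / (2 sqrt(2 log 2))` per axis (converted from mm to voxels
#' using the in-plane voxel sizes). Nothing is smoothed across slices or
#' frames. Edges are handled by kernel renormalization: the zero-padded
#' convolution is divided by the convolved all-ones image, so constants are
#' preserved exactly and interior mass is conserved.
#'
#' @param bold a [bold4d()].
#' @param fwhm_mm Gaussian FWHM in mm (0 returns the input unchanged).
#' @return A smoothed `bold4d`.
#' @export
smooth_inplane <- function(bold, fwhm_mm = 0.3) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(bold)
  sig_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  sig_vox <- sig_mm / bold$geometry$voxel_size[1:2]
  d <- dim(bold$data)
  Kx <- gauss_conv_matrix(d[1], sig_vox[1])
  Ky <- gauss_conv_matrix(d[2], sig_vox[2])
  # separable pass along x, then y, on the flattened array
  m <- Kx %*% matrix(bold$data, d[1], prod(d[2:4]))
  a <- array(m, d)
  ap <- aperm(a, c(2, 1, 3, 4))
  m2 <- Ky %*% matrix(ap, d[2], prod(d[c(1, 3, 4)]))
  a2 <- aperm(array(m2, d[c(2, 1, 3, 4)]), c(2, 1, 3, 4))
  # renormalize by the smoothed all-ones image (outer product of the two
  # one-dimensional row sums, constant across slices and frames)
  den <- outer(drop(Kx %*% rep(1, d[1])), drop(Ky %*% rep(1, d[2])))
  a2 <- a2 / as.vector(den)     # first two dims vary fastest: recycles per slice
  bold4d(a2, bold$geometry, bold$tr)
}

# cached Butterworth design (trivial cost, kept for clarity)
.bandpass_design <- function(tr, band, order = 4) {
  nyq <- 1 / (2 * tr)
  if (band[2] >= nyq) {
    stop(sprintf("band high %.4g Hz is not below Nyquist %.4g Hz",
                 band[2], nyq))
  }
  if (band[1] <= 0) stop("band low must be > 0")
  signal::butter(order, band / nyq, type = "pass")
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass of order 4. The line
#' through the series endpoints is removed first (DC and linear trend lie
#' outside the pass-band), which zeroes both ends and keeps the filter's
#' warm-up transients small; as with any zero-phase IIR filter, the stated
#' attenuation figures hold in steady state, i.e. away from the first and
#' last few dozen samples. The output has the input's length.
#'
#' @param series numeric vector.
#' @param tr sampling interval in seconds.
#' @param band Hz pair `(low, high)` with `high` below Nyquist `1/(2 tr)`.
#' @return Filtered numeric vector of the same length.
#' @export
bandpass_filter <- function(series, tr, band = c(0.01, 0.08)) {
  bf <- .bandpass_design(tr, band)
  .bandpass_apply(series, bf)
}

.bandpass_apply <- function(series, bf) {
  n <- length(series)
  if (n <= 3L * 8L) stop("series too short for the filter warm-up")
  # remove the line through the endpoints (DC and linear trend are outside
  # the pass-band) so the series starts and ends at zero, minimizing the
  # onset transients of the forward and backward passes
  line <- series[1] + (series[n] - series[1]) * (seq_len(n) - 1) / (n - 1)
  signal::filtfilt(bf, series - line)
}

#' Band-pass filter every voxel of a BOLD dataset
#'
#' Voxels whose series is constant (e.g. background zeros) are passed through
#' as zeros without filtering.
#'
#' @inheritParams bandpass_filter
#' @param bold a [bold4d()].
#' @return A filtered `bold4d`.
#' @export
bandpass_bold <- function(bold, band = c(0.01, 0.08)) {
  bf <- .bandpass_design(bold$tr, band)
  d <- dim(bold$data)
  Y <- matrix(bold$data, prod(d[1:3]), d[4])
  rng <- matrixStats_range(Y)
  active <- which(rng > 0)
  out <- matrix(0, nrow(Y), ncol(Y))
  for (v in active) out[v, ] <- .bandpass_apply(Y[v, ], bf)
  bold4d(array(out, d), bold$geometry, bold$tr)
}

# per-row max - min without extra dependencies
matrixStats_range <- function(Y) {
  apply(Y, 1, function(r) max(r) - min(r))
}

#' Per-voxel temporal normalization
#'
#' Z-scores every voxel time series (mean 0, unit sample SD). Constant
#' (zero-variance) voxels are set to all zeros and their count is attached as
#' attribute `n_flagged` (with 1-based array indices in `flagged`).
#'
#' @param bold a [bold4d()].
#' @return A normalized `bold4d`.
#' @export
normalize_timeseries <- function(bold) {
  d <- dim(bold$data)
  Y <- matrix(bold$data, prod(d[1:3]), d[4])
  mu <- rowMeans(Y)
  Yc <- Y - mu
  sd <- sqrt(rowSums(Yc^2) / (d[4] - 1))
  flagged <- which(sd == 0)
  sd[sd == 0] <- 1
  Yz <- Yc / sd
  Yz[flagged, ] <- 0
  out <- bold4d(array(Yz, d), bold$geometry, bold$tr)
  attr(out, "flagged") <- flagged
  attr(out, "n_flagged") <- length(flagged)
  out
}

#' Full functional preprocessing chain
#'
#' Applies, in order: nuisance regression (drifts, respiration, motion),
#' in-plane Gaussian smoothing, zero-phase band-pass, per-voxel
#' normalization. The order matches the processing listing of the underlying
#' protocol; normalization is idempotent, so re-running the last step is a
#' no-op.
#'
#' @param bold a [bold4d()].
#' @param nuisance a [nuisance_set()].
#' @param config a [preproc_config()].
#' @return A preprocessed `bold4d`.
#' @export
preprocess_bold <- function(bold, nuisance, config = preproc_config()) {
  b <- regress_nuisance(bold, nuisance, config$drift_order,
                        config$include_respiration, config$include_motion)
  b <- smooth_inplane(b, config$fwhm_mm)
  b <- bandpass_bold(b, config$band)
  normalize_timeseries(b)
}
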