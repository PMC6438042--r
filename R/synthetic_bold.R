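#' Build a block atlas of disjoint rectangular ROIs
#'
#' Stand-in for a coregistered anatomical atlas: `n_rois` identical
#' rectangular ROIs laid out on a 3D grid, separated by `gap` background
#' voxels and surrounded by a `margin` background border (so in-plane
#' smoothing does not mix neighbouring ROIs).
#'
#' @param n_rois number of ROIs (labels 1..n_rois).
#' @param roi_shape voxel triple, the shape of every ROI block.
#' @param layout grid dims (gx, gy, gz) with `prod(layout) >= n_rois`.
#' @param voxel_size mm triple (default in-plane 0.182 mm, 0.5 mm slices, a
#'   typical mouse EPI resolution).
#' @param gap background voxels between blocks (default 1).
#' @param margin background border around the grid (default 1).
#' @param roi_names optional names (default `roi1..roiN`).
#' @param hemisphere optional hemisphere tags for the ROI table.
#' @return An [atlas_labels()].
#' @export
make_block_atlas <- function(n_rois, roi_shape = c(4, 4, 2),
                             layout = NULL, voxel_size = c(0.182, 0.182, 0.5),
                             gap = 1L, margin = 1L, roi_names = NULL,
                             hemisphere = NULL) {
  n_rois <- as.integer(n_rois)
  roi_shape <- as.integer(roi_shape)
  if (is.null(layout)) {
    gx <- ceiling(sqrt(n_rois))
    layout <- c(gx, ceiling(n_rois / gx), 1L)
  }
  layout <- as.integer(layout)
  if (prod(layout) < n_rois) stop("layout cannot hold n_rois blocks")
  dims <- 2L * margin + layout * roi_shape + (layout - 1L) * gap
  labels <- array(0L, dims)
  cells <- expand.grid(x = seq_len(layout[1]), y = seq_len(layout[2]),
                       z = seq_len(layout[3]))
  for (r in seq_len(n_rois)) {
    cell <- as.integer(cells[r, ])
    start <- margin + (cell - 1L) * (roi_shape + gap) + 1L
    labels[start[1]:(start[1] + roi_shape[1] - 1L),
           start[2]:(start[2] + roi_shape[2] - 1L),
           start[3]:(start[3] + roi_shape[3] - 1L)] <- r
  }
  if (is.null(roi_names)) roi_names <- paste0("roi", seq_len(n_rois))
  if (is.null(hemisphere)) hemisphere <- rep("both", n_rois)
  atlas_labels(labels, volume_geometry(dims, voxel_size),
               data.frame(label = seq_len(n_rois), name = roi_names,
                          hemisphere = hemisphere, stringsAsFactors = FALSE))
}

#' Default inter-ROI correlation structure
#'
#' A 12-node target correlation matrix over named mouse-brain regions,
#' generated from a two-factor model (a default-mode-like block and a
#' sensorimotor block on top of a global factor), giving within-network
#' correlations near 0.5 and between-network correlations near 0.2. Positive
#' semidefinite with unit diagonal by construction.
#'
#' @return Symmetric correlation matrix with ROI dimnames.
#' @export
default_base_corr <- function() {
  rois <- c("Hp", "Cg", "PrL", "RS", "MO", "M1", "S1", "S2", "VC", "AC",
            "Th", "CPu")
  dmn <- c("Hp", "Cg", "PrL", "RS", "MO")
  sm  <- c("M1", "S1", "S2", "VC", "AC")
  L <- cbind(global = rep(0.45, 12),
             dmn = 0.55 * (rois %in% dmn),
             sm  = 0.55 * (rois %in% sm),
             sub = 0.50 * (rois %in% c("Th", "CPu")))
  C <- L %*% t(L)
  diag(C) <- 1
  dimnames(C) <- list(rois, rois)
  C
}

#' Noise specification for BOLD simulation
#'
#' @param voxel_sd SD of white voxel noise, in units of the (unit-SD) latent
#'   network signal.
#' @param drift_amp length-2 amplitudes of the per-voxel linear and quadratic
#'   drift coefficients.
#' @param resp_freq_hz respiratory frequency in Hz (sampled at the TR, so it
#'   appears aliased, as a recorded trace would).
#' @param resp_amp amplitude of the respiratory sinusoid.
#' @param motion_amp SD of the per-voxel loadings on the six simulated
#'   motion-parameter series.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(voxel_sd = 0.5, drift_amp = c(1, 0.5),
                       resp_freq_hz = 1.2, resp_amp = 0.3,
                       motion_amp = 0.1) {
  structure(list(voxel_sd = voxel_sd, drift_amp = drift_amp,
                 resp_freq_hz = resp_freq_hz, resp_amp = resp_amp,
                 motion_amp = motion_amp), class = "noise_spec")
}

# white Gaussian series restricted to a frequency band by a frequency-domain
# (brick-wall) filter; exactly band-limited by construction
bandlimited_noise <- function(n, k, tr, band) {
  X <- matrix(stats::rnorm(n * k), n, k)
  F <- stats::mvfft(X)
  fr <- (seq_len(n) - 1) / (n * tr)
  fr <- pmin(fr, 1 / tr - fr)              # fold to two-sided frequencies
  F[fr < band[1] | fr > band[2], ] <- 0
  Re(stats::mvfft(F, inverse = TRUE)) / n
}

# band-limited latent ROI signals with the requested correlation structure:
# white noise -> brick-wall 0.01-0.08 Hz band restriction -> (optional)
# empirical whitening -> mixing by the symmetric square root of corr. With
# empirical = TRUE the sample correlation of the returned series equals corr
# exactly.
latent_network_signals <- function(corr, n_frames, tr, band = c(0.01, 0.08),
                                   empirical = TRUE) {
  k <- nrow(corr)
  ev <- eigen(corr, symmetric = TRUE)
  if (min(ev$values) < -1e-8) stop("corr is not positive semidefinite")
  X <- bandlimited_noise(n_frames, k, tr, band)
  X <- scale(X, center = TRUE, scale = FALSE)
  if (empirical) {
    S <- stats::cov(X)
    X <- X %*% solve(chol(S))   # exact identity sample covariance
  } else {
    X <- scale(X, center = FALSE, scale = apply(X, 2, stats::sd))
  }
  R <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  L <- X %*% R
  colnames(L) <- colnames(corr)
  L
}

# six smooth motion-parameter series (random walks with a moving-average
# smoother), small amplitude
simulate_motion <- function(n_frames, amp = 1) {
  m <- sapply(1:6, function(i) {
    w <- cumsum(stats::rnorm(n_frames, sd = 0.1))
    stats::filter(w, rep(1 / 5, 5), sides = 2, circular = TRUE) * amp
  })
  matrix(as.numeric(m), n_frames, 6)
}

#' Simulate one BOLD dataset with known connectivity
#'
#' Each ROI of the atlas carries a latent band-limited (0.01--0.08 Hz)
#' network signal; the latent signals are mixed so their pairwise sample
#' correlations equal `corr` exactly (`empirical = TRUE`, the default) or in
#' expectation (`empirical = FALSE`). Every in-ROI voxel receives its ROI's
#' latent signal plus white noise, polynomial drift with random per-voxel
#' coefficients, a respiratory sinusoid and small loadings on six simulated
#' motion series. Background voxels are zero. The returned nuisance set holds
#' the injected respiratory trace and motion series exactly.
#'
#' @param atlas an [atlas_labels()].
#' @param corr target ROI correlation matrix (PSD, unit diagonal, dimension
#'   = number of ROIs).
#' @param noise a [noise_spec()].
#' @param tr repetition time in seconds.
#' @param n_frames number of frames (>= 10).
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @param empirical impose `corr` on the sample exactly (default TRUE).
#' @return list with elements `bold` ([bold4d()]), `nuisance`
#'   ([nuisance_set()]) and `truth` (latent series, target corr, seed).
#' @export
simulate_bold_dataset <- function(atlas, corr, noise = noise_spec(),
                                  tr = 2.84, n_frames = 105, seed = 1,
                                  empirical = TRUE) {
  if (n_frames < 10) stop("n_frames must be >= 10")
  k <- nrow(atlas$roi_table)
  corr <- as.matrix(corr)
  if (nrow(corr) != k) stop("corr dimension does not match the atlas")
  if (max(abs(corr - t(corr))) > 1e-12 || any(abs(diag(corr) - 1) > 1e-12)) {
    stop("corr must be symmetric with unit diagonal")
  }
  set.seed(seed)
  latent <- latent_network_signals(corr, n_frames, tr, empirical = empirical)
  resp <- noise$resp_amp *
    sin(2 * pi * noise$resp_freq_hz * tr * seq_len(n_frames) +
          stats::runif(1, 0, 2 * pi))
  motion <- simulate_motion(n_frames)
  drift <- drift_basis(n_frames, 2L)
  d <- atlas$geometry$dims
  data <- array(0, c(d, n_frames))
  Y <- matrix(0, prod(d), n_frames)
  lab <- as.vector(atlas$labels)
  for (r in seq_len(k)) {
    vox <- which(lab == atlas$roi_table$label[r])
    nv <- length(vox)
    sig <- matrix(latent[, r], nv, n_frames, byrow = TRUE)
    sig <- sig + noise$voxel_sd * matrix(stats::rnorm(nv * n_frames), nv)
    coef_d <- cbind(stats::rnorm(nv, sd = noise$drift_amp[1]),
                    stats::rnorm(nv, sd = noise$drift_amp[2]))
    sig <- sig + coef_d %*% t(drift)
    sig <- sig + stats::runif(nv, 0.5, 1.5) %o% resp
    sig <- sig + matrix(stats::rnorm(nv * 6, sd = noise$motion_amp), nv) %*%
      t(motion)
    Y[vox, ] <- sig
  }
  bold <- bold4d(array(Y, c(d, n_frames)), atlas$geometry, tr)
  nuis <- nuisance_set(respiration = resp, motion = motion, drift_order = 2L,
                       n_frames = n_frames)
  list(bold = bold, nuisance = nuis,
       truth = list(corr = corr, latent = latent, seed = seed))
}

#' Study specification for a simulated cohort
#'
#' Describes a multi-group, two-time-point resting-state study. The defaults
#' mirror a regulatable-transgene design: two transgenic groups (n = 8 each)
#' whose baseline inter-ROI correlations are scaled to half strength and
#' recover fully at the second time point, and a wildtype control group
#' (n = 7) at full strength throughout; 105 frames at TR 2.84 s.
#'
#' @param groups named list; each element a numeric vector of per-time-point
#'   connectivity scale factors in (0, 1] (names become time-point labels).
#' @param n_subjects named/ordered integer vector, one count per group.
#' @param base_corr target correlation matrix (PSD, unit diagonal).
#' @param noise a [noise_spec()].
#' @param tr,n_frames acquisition parameters.
#' @param master_seed integer; all subject seeds derive from it.
#' @param empirical see [simulate_bold_dataset()].
#' @return An object of class `study_spec`.
#' @export
study_spec <- function(groups = list(pro = c(baseline = 0.5, treated = 1),
                                     anti = c(baseline = 0.5, treated = 1),
                                     control = c(baseline = 1, treated = 1)),
                       n_subjects = c(pro = 8, anti = 8, control = 7),
                       base_corr = default_base_corr(),
                       noise = noise_spec(), tr = 2.84, n_frames = 105,
                       master_seed = 1, empirical = TRUE) {
  stopifnot(length(groups) == length(n_subjects))
  for (g in names(groups)) {
    s <- groups[[g]]
    if (any(s <= 0 | s > 1)) stop("scale factors must lie in (0, 1]: ", g)
  }
  if (any(n_subjects < 1)) stop("n_subjects must be >= 1")
  structure(list(groups = groups, n_subjects = n_subjects,
                 base_corr = as.matrix(base_corr), noise = noise, tr = tr,
                 n_frames = n_frames, master_seed = as.integer(master_seed),
                 empirical = empirical),
            class = "study_spec")
}

# scale the off-diagonal of a unit-diagonal correlation matrix; always PSD
# for s in (0, 1]
scale_offdiag <- function(corr, s) {
  out <- corr * s
  diag(out) <- 1
  out
}

derive_seed <- function(master, i) {
  as.integer((as.numeric(master) + 7919 * i) %% .Machine$integer.max)
}

#' Simulate a full study cohort
#'
#' One BOLD dataset per subject and time point; group g at time point t is
#' drawn from `base_corr` with its off-diagonal multiplied by the group's
#' scale factor for t. Subject/time-point seeds derive deterministically from
#' `master_seed`, so the cohort is a pure function of (spec, atlas).
#'
#' @param spec a [study_spec()].
#' @param atlas an [atlas_labels()] whose ROI count matches `base_corr`.
#' @return list of records, each with `subject`, `group`, `time_point`,
#'   `scale`, `bold`, `nuisance`, `truth`; the spec is attached as attribute
#'   `spec` and a manifest data frame as `manifest`.
#' @export
simulate_study_cohort <- function(spec, atlas) {
  recs <- list()
  idx <- 0L
  for (g in names(spec$groups)) {
    scales <- spec$groups[[g]]
    tps <- names(scales)
    if (is.null(tps)) tps <- paste0("t", seq_along(scales))
    for (si in seq_len(spec$n_subjects[[g]])) {
      subject <- sprintf("%s_%02d", g, si)
      for (ti in seq_along(scales)) {
        idx <- idx + 1L
        corr_t <- scale_offdiag(spec$base_corr, scales[ti])
        ds <- simulate_bold_dataset(atlas, corr_t, spec$noise, spec$tr,
                                    spec$n_frames,
                                    seed = derive_seed(spec$master_seed, idx),
                                    empirical = spec$empirical)
        recs[[idx]] <- list(subject = subject, group = g,
                            time_point = tps[ti], scale = scales[ti],
                            bold = ds$bold, nuisance = ds$nuisance,
                            truth = ds$truth)
      }
    }
  }
  manifest <- do.call(rbind, lapply(recs, function(r) {
    data.frame(subject = r$subject, group = r$group,
               time_point = r$time_point, scale = r$scale,
               stringsAsFactors = FALSE)
  }))
  attr(recs, "spec") <- spec
  attr(recs, "manifest") <- manifest
  recs
}
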