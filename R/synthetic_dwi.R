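#' Build a single-shell Q-ball acquisition scheme
#'
#' Generates `n_dir` gradient directions covering half a unit sphere
#' (deterministic Fibonacci-spiral layout) at one b-value, with `n_b0`
#' non-diffusion-weighted volumes distributed evenly between the weighted
#' ones (one preceding each block), mirroring an interleaved multi-scan
#' acquisition.
#'
#' @param n_dir number of diffusion directions (default 126).
#' @param n_b0 number of b = 0 volumes (default 8).
#' @param bval shell b-value in s/mm^2 (default 2000).
#' @return A [diffusion_scheme()] of `n_dir + n_b0` volumes.
#' @export
make_qball_scheme <- function(n_dir = 126, n_b0 = 8, bval = 2000) {
  i <- seq_len(n_dir) - 0.5
  z <- i / n_dir                     # upper hemisphere only
  phi <- pi * (1 + sqrt(5)) * i
  st <- sqrt(pmax(0, 1 - z^2))
  dirs <- rbind(st * cos(phi), st * sin(phi), z)
  block <- ceiling(n_dir / n_b0)
  bvals <- numeric(0)
  bvecs <- NULL
  taken <- 0L
  for (b in seq_len(n_b0)) {
    bvals <- c(bvals, 0)
    bvecs <- cbind(bvecs, c(0, 0, 0))
    take <- min(block, n_dir - taken)
    if (take > 0) {
      bvals <- c(bvals, rep(bval, take))
      bvecs <- cbind(bvecs, dirs[, taken + seq_len(take), drop = FALSE])
      taken <- taken + take
    }
  }
  diffusion_scheme(bvals, bvecs)
}

#' Diffusion phantom specification
#'
#' Describes a small geometric phantom built from axially symmetric diffusion
#' tensors: a straight tube of coherent fibers, two tubes crossing at 90
#' degrees, or a purely isotropic volume. Default diffusivities are
#' white-matter-like (axial 1.7e-3, radial 0.3e-3 mm^2/s) with a CSF-like
#' isotropic compartment (2.0e-3 mm^2/s) outside the tubes.
#'
#' @param kind "straight_tube", "crossing" or "isotropic".
#' @param dims voxel triple (default 40 x 12 x 8).
#' @param voxel_size mm triple (default 0.5 mm isotropic).
#' @param tube_halfwidth half-width of the square tube cross-section in
#'   voxels (default 1, i.e. 3 voxels wide).
#' @param axial_d,radial_d,iso_d diffusivities in mm^2/s.
#' @param snr signal-to-noise ratio at b = 0 (`Inf` for noiseless).
#' @param s0 non-diffusion-weighted signal level.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("straight_tube", "crossing", "isotropic"),
                         dims = c(40, 12, 8), voxel_size = c(0.5, 0.5, 0.5),
                         tube_halfwidth = 1L, axial_d = 1.7e-3,
                         radial_d = 0.3e-3, iso_d = 2.0e-3, snr = 30,
                         s0 = 100) {
  kind <- match.arg(kind)
  if (snr <= 0) stop("snr must be > 0")
  dims <- as.integer(dims)
  geom <- volume_geometry(dims, voxel_size)
  cy <- round(dims[2] / 2)
  cz <- round(dims[3] / 2)
  hw <- as.integer(tube_halfwidth)
  tube_y <- max(1, cy - hw):min(dims[2], cy + hw)
  tube_z <- max(1, cz - hw):min(dims[3], cz + hw)
  masks <- list()
  fibers <- list()
  if (kind %in% c("straight_tube", "crossing")) {
    m1 <- array(FALSE, dims)
    m1[, tube_y, tube_z] <- TRUE
    masks$tube1 <- m1
    fibers$tube1 <- c(1, 0, 0)
  }
  if (kind == "crossing") {
    cx <- round(dims[1] / 2)
    tube_x <- max(1, cx - hw):min(dims[1], cx + hw)
    m2 <- array(FALSE, dims)
    m2[tube_x, , tube_z] <- TRUE
    masks$tube2 <- m2
    fibers$tube2 <- c(0, 1, 0)
  }
  structure(list(kind = kind, geometry = geom, masks = masks,
                 fibers = fibers, axial_d = axial_d, radial_d = radial_d,
                 iso_d = iso_d, snr = snr, s0 = s0),
            class = "phantom_spec")
}

# axially symmetric single-tensor attenuation: exp(-b (rad + (ax - rad)
# (g . dir)^2)) for each direction column of bvecs
tensor_attenuation <- function(bvals, bvecs, dir, axial_d, radial_d) {
  proj2 <- as.numeric(dir %*% bvecs)^2
  exp(-bvals * (radial_d + (axial_d - radial_d) * proj2))
}

#' Simulate a diffusion-weighted phantom
#'
#' Multi-tensor signal per voxel: equal-fraction anisotropic compartments for
#' every tube covering the voxel, an isotropic compartment elsewhere, then
#' Rician noise at the specified SNR (the noiseless signal is the Rician
#' location parameter; sigma = s0 / snr).
#'
#' @param spec a [phantom_spec()].
#' @param scheme a [diffusion_scheme()].
#' @param seed integer RNG seed (used only when `snr` is finite).
#' @return list with `dwi` (4D array), `geometry`, `scheme` and `truth`
#'   (per-tube masks, fiber directions, noiseless signal).
#' @export
simulate_dwi_phantom <- function(spec, scheme, seed = 1) {
  dims <- spec$geometry$dims
  nvol <- length(scheme$bvals)
  nvox <- prod(dims)
  S <- matrix(0, nvox, nvol)
  in_tube <- rep(FALSE, nvox)
  tube_idx <- lapply(spec$masks, function(m) which(as.vector(m)))
  for (i in tube_idx) in_tube[i] <- TRUE
  iso <- spec$s0 * exp(-scheme$bvals * spec$iso_d)
  if (any(!in_tube)) {
    S[!in_tube, ] <- matrix(iso, sum(!in_tube), nvol, byrow = TRUE)
  }
  # voxels covered by one or more tubes: equal-fraction mixture
  if (length(tube_idx)) {
    att <- lapply(names(spec$masks), function(nm) {
      tensor_attenuation(scheme$bvals, scheme$bvecs, spec$fibers[[nm]],
                         spec$axial_d, spec$radial_d)
    })
    names(att) <- names(spec$masks)
    member <- matrix(FALSE, nvox, length(tube_idx))
    for (j in seq_along(tube_idx)) member[tube_idx[[j]], j] <- TRUE
    ncomp <- rowSums(member)
    for (j in seq_along(tube_idx)) {
      rows <- which(member[, j])
      S[rows, ] <- S[rows, ] +
        (spec$s0 / ncomp[rows]) %o% att[[j]]
    }
  }
  if (is.finite(spec$snr)) {
    set.seed(seed)
    sigma <- spec$s0 / spec$snr
    S_noisy <- sqrt((S + stats::rnorm(length(S), sd = sigma))^2 +
                      stats::rnorm(length(S), sd = sigma)^2)
  } else {
    S_noisy <- S
  }
  list(dwi = array(S_noisy, c(dims, nvol)), geometry = spec$geometry,
       scheme = scheme,
       truth = list(masks = spec$masks, fibers = spec$fibers,
                    noiseless = array(S, c(dims, nvol))))
}
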