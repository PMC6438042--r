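#' Tracking configuration
#'
#' Numeric criteria of the deterministic streamline tracker. Defaults match
#' a standard small-animal whole-brain protocol: QA termination threshold
#' 0.03, 0.5 mm steps, 0.1 direction weighting (momentum), 55 degree maximal
#' turning angle and a 5--120 mm fiber length constraint.
#'
#' @param qa_threshold minimum (normalized) QA for seeding and propagation.
#' @param step_mm step size in mm (> 0).
#' @param weighting momentum weight w in `d_new = (1-w) peak + w d_in`,
#'   0 <= w < 1.
#' @param max_turning_deg maximal turning angle in degrees (0, 90).
#' @param length_bounds_mm length-2 retention bounds in mm.
#' @param seeds_per_voxel random subvoxel seeds per eligible voxel.
#' @param rng_seed integer seed making the tracker a pure function.
#' @return An object of class `tracking_config`.
#' @export
tracking_config <- function(qa_threshold = 0.03, step_mm = 0.5,
                            weighting = 0.1, max_turning_deg = 55,
                            length_bounds_mm = c(5, 120),
                            seeds_per_voxel = 1L, rng_seed = 1L) {
  if (step_mm <= 0) stop("step_mm must be > 0")
  if (weighting < 0 || weighting >= 1) stop("weighting must be in [0, 1)")
  if (max_turning_deg <= 0 || max_turning_deg >= 90) {
    stop("max_turning_deg must be in (0, 90)")
  }
  if (length_bounds_mm[1] <= 0 || length_bounds_mm[2] <= length_bounds_mm[1]) {
    stop("length bounds must satisfy 0 < min < max")
  }
  structure(list(qa_threshold = qa_threshold, step_mm = step_mm,
                 weighting = weighting, max_turning_deg = max_turning_deg,
                 length_bounds_mm = length_bounds_mm,
                 seeds_per_voxel = as.integer(seeds_per_voxel),
                 rng_seed = as.integer(rng_seed)),
            class = "tracking_config")
}

#' Deterministic streamline tractography
#'
#' Seeds are placed at random subvoxel positions (reproducible from
#' `rng_seed`) inside every voxel whose top QA reaches `qa_threshold`, and
#' tracked in both directions from the voxel's strongest peak. At each step
#' the peak of the current (nearest) voxel most parallel to the incoming
#' direction is selected among peaks with QA above threshold; propagation
#' stops when no such peak exists, when the turn would exceed the maximal
#' turning angle, or when the position leaves the volume. The propagation
#' direction mixes the selected peak with the incoming direction using the
#' momentum weight, and advances by the step size. The two half-tracks are
#' concatenated and only streamlines within the length bounds are retained.
#'
#' @param peaks a [evaluate_odf_peaks()] result.
#' @param cfg a [tracking_config()].
#' @return An object of class `streamline_set`: `streamlines` (list of
#'   point matrices in world mm), `lengths`, `seeds` (voxel linear index per
#'   retained streamline), `n_candidates`, `config`, `geometry`.
#' @export
track_deterministic <- function(peaks, cfg = tracking_config()) {
  geom <- peaks$geometry
  dims <- geom$dims
  thr <- cfg$qa_threshold
  w <- cfg$weighting
  cos_max <- cos(cfg$max_turning_deg * pi / 180)
  max_pts <- ceiling(cfg$length_bounds_mm[2] / cfg$step_mm) + 2L
  # per linear voxel index: column in the peak arrays (NA outside the mask)
  col_of <- rep(NA_integer_, prod(dims))
  col_of[peaks$mask] <- seq_along(peaks$mask)
  eligible <- peaks$mask[peaks$n_peaks > 0 & peaks$peak_qa[1, ] >= thr]
  if (!length(eligible)) stop("no voxels reach the seeding QA threshold")
  set.seed(cfg$rng_seed)
  seeds_vox <- rep(eligible, each = cfg$seeds_per_voxel)
  offsets <- matrix(stats::runif(3 * length(seeds_vox), -0.5, 0.5), ncol = 3)
  ijk <- arrayInd(seeds_vox, dims)
  seed_world <- voxel_to_world(geom, ijk - 1 + offsets)

  step_half <- function(pos, dir) {
    pts <- matrix(NA_real_, max_pts, 3)
    np <- 0L
    repeat {
      if (np >= max_pts) break
      vox <- voxel_index(geom, world_to_voxel(geom, pos))
      if (anyNA(vox)) break
      col <- col_of[(vox[3] - 1) * dims[1] * dims[2] +
                      (vox[2] - 1) * dims[1] + vox[1]]
      if (is.na(col)) break
      k <- peaks$n_peaks[col]
      if (k == 0L) break
      ok <- which(peaks$peak_qa[seq_len(k), col] >= thr)
      if (!length(ok)) break
      P <- matrix(peaks$peak_dirs[, ok, col], nrow = 3)
      dots <- as.numeric(dir %*% P)
      j <- which.max(abs(dots))
      p <- P[, j] * sign(dots[j])
      if (abs(dots[j]) < cos_max) break     # turn exceeds the angle limit
      dnew <- (1 - w) * p + w * dir
      dnew <- dnew / sqrt(sum(dnew^2))
      pos <- pos + cfg$step_mm * dnew
      np <- np + 1L
      pts[np, ] <- pos
      dir <- dnew
    }
    pts[seq_len(np), , drop = FALSE]
  }

  streamlines <- list()
  lengths <- numeric(0)
  seed_ids <- integer(0)
  for (s in seq_along(seeds_vox)) {
    col <- col_of[seeds_vox[s]]
    ok <- which(peaks$peak_qa[seq_len(peaks$n_peaks[col]), col] >= thr)
    d0 <- peaks$peak_dirs[, ok[1], col]
    pos0 <- seed_world[s, ]
    h1 <- step_half(pos0, d0)
    h2 <- step_half(pos0, -d0)
    pts <- rbind(h2[rev(seq_len(nrow(h2))), , drop = FALSE],
                 matrix(pos0, 1, 3), h1)
    len <- cfg$step_mm * (nrow(pts) - 1)
    if (len >= cfg$length_bounds_mm[1] && len <= cfg$length_bounds_mm[2]) {
      streamlines[[length(streamlines) + 1L]] <- pts
      lengths <- c(lengths, len)
      seed_ids <- c(seed_ids, seeds_vox[s])
    }
  }
  structure(list(streamlines = streamlines, lengths = lengths,
                 seeds = seed_ids, n_candidates = length(seeds_vox),
                 config = cfg, geometry = geom),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf(
    "<streamline_set> %d retained of %d seeded; length %.1f .. %.1f mm\n",
    length(x$streamlines), x$n_candidates,
    if (length(x$lengths)) min(x$lengths) else NA,
    if (length(x$lengths)) max(x$lengths) else NA))
  invisible(x)
}

#' Write streamlines as a plain-text polyline file
#'
#' One line per point (`id x y z`, world mm), streamlines separated by their
#' integer id; reads back with [read_streamlines()].
#'
#' @param streamlines a `streamline_set`.
#' @param path output path.
#' @export
write_streamlines <- function(streamlines, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(streamlines$streamlines)) {
    pts <- streamlines$streamlines[[i]]
    writeLines(sprintf("%d %.10g %.10g %.10g", i, pts[, 1], pts[, 2],
                       pts[, 3]), con)
  }
  invisible(path)
}

#' Read a plain-text polyline file written by [write_streamlines()]
#'
#' @param path input path.
#' @return list of point matrices (world mm).
#' @export
read_streamlines <- function(path) {
  df <- utils::read.table(path, col.names = c("id", "x", "y", "z"))
  lapply(split(df[, c("x", "y", "z")], df$id), as.matrix)
}

# set of ROI labels a streamline passes through or ends in
streamline_rois <- function(pts, atlas) {
  vox <- voxel_index(atlas$geometry, world_to_voxel(atlas$geometry, pts))
  vox <- vox[stats::complete.cases(vox), , drop = FALSE]
  if (!nrow(vox)) return(integer(0))
  d <- atlas$geometry$dims
  lin <- (vox[, 3] - 1) * d[1] * d[2] + (vox[, 2] - 1) * d[1] + vox[, 1]
  labs <- unique(as.vector(atlas$labels)[lin])
  labs[labs > 0]
}

#' Voxel-normalized fiber-density matrix
#'
#' `count(i, j)` is the number of streamlines that pass through or end in
#' both ROI i and ROI j (each streamline counted once per pair);
#' `density(i, j) = count / (n_voxels_i + n_voxels_j)`. Densities below
#' `zero_below` (default 1, i.e. less than one fiber per voxel) are set to
#' exactly zero; the raw counts and unzeroed densities are retained for
#' group averaging.
#'
#' @param streamlines a `streamline_set` (or plain list of point matrices).
#' @param atlas an [atlas_labels()] in the same world space.
#' @param rois ROI names to include (default: all).
#' @param zero_below density zeroing threshold (0 disables).
#' @return An object of class `fiber_density`: `density` (zero rule
#'   applied), `density_raw`, `counts`, `roi_order`, `zero_below`.
#' @export
fiber_density_matrix <- function(streamlines, atlas, rois = NULL,
                                 zero_below = 1) {
  sls <- if (inherits(streamlines, "streamline_set")) {
    streamlines$streamlines
  } else streamlines
  tab <- atlas$roi_table
  if (is.null(rois)) rois <- tab$name
  missing <- setdiff(rois, tab$name)
  if (length(missing)) stop("unknown ROI(s): ", paste(missing, collapse = ", "))
  labs <- tab$label[match(rois, tab$name)]
  nv <- tab$n_voxels[match(rois, tab$name)]
  k <- length(rois)
  counts <- matrix(0, k, k, dimnames = list(rois, rois))
  for (pts in sls) {
    hit <- match(streamline_rois(pts, atlas), labs)
    hit <- sort(hit[!is.na(hit)])
    if (length(hit) < 2) next
    prs <- utils::combn(hit, 2)
    for (c in seq_len(ncol(prs))) {
      counts[prs[1, c], prs[2, c]] <- counts[prs[1, c], prs[2, c]] + 1
      counts[prs[2, c], prs[1, c]] <- counts[prs[2, c], prs[1, c]] + 1
    }
  }
  denom <- outer(nv, nv, `+`)
  density_raw <- counts / denom
  density <- density_raw
  density[density < zero_below] <- 0
  structure(list(density = density, density_raw = density_raw,
                 counts = counts, roi_order = rois, zero_below = zero_below),
            class = "fiber_density")
}

#' @export
print.fiber_density <- function(x, ...) {
  ut <- upper.tri(x$density)
  cat(sprintf(
    "<fiber_density> %d ROIs, %d connections above threshold (max %.2f fibers/voxel)\n",
    length(x$roi_order), sum(x$density[ut] > 0), max(x$density[ut])))
  invisible(x)
}

#' Group-average fiber-density matrix
#'
#' Averages the unzeroed per-subject densities, then applies the
#' less-than-one-fiber-per-voxel zeroing rule to the group mean (normalize,
#' average, zero — in that order).
#'
#' @param densities list of [fiber_density_matrix()] results sharing
#'   `roi_order`.
#' @param zero_below zeroing threshold applied after averaging.
#' @return A `fiber_density` with averaged fields.
#' @export
average_fiber_density <- function(densities, zero_below = 1) {
  ord <- densities[[1]]$roi_order
  for (d in densities) {
    if (!identical(d$roi_order, ord)) stop("roi_order mismatch")
  }
  raw <- Reduce(`+`, lapply(densities, `[[`, "density_raw")) /
    length(densities)
  counts <- Reduce(`+`, lapply(densities, `[[`, "counts")) /
    length(densities)
  density <- raw
  density[density < zero_below] <- 0
  structure(list(density = density, density_raw = raw, counts = counts,
                 roi_order = ord, zero_below = zero_below),
            class = "fiber_density")
}
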