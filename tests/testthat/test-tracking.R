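# a hand-built peak field: every voxel one unit peak with QA 1, directions
# given by a function of the voxel index
manual_peak_field <- function(dims, vox_mm, dir_fun, qa = 1) {
  geom <- volume_geometry(dims, vox_mm)
  nvox <- prod(dims)
  pd <- array(NA_real_, c(3, 1, nvox))
  qa_m <- matrix(0, 1, nvox)
  np <- integer(nvox)
  for (v in seq_len(nvox)) {
    ijk <- arrayInd(v, dims)
    d <- dir_fun(ijk)
    if (is.null(d)) next
    pd[, 1, v] <- d / sqrt(sum(d^2))
    qa_m[1, v] <- qa
    np[v] <- 1L
  }
  qa_vol <- array(qa_m[1, ], dims)
  structure(list(peak_dirs = pd, peak_qa = qa_m, peak_odf = qa_m,
                 n_peaks = np, mask = seq_len(nvox), qa = qa_vol,
                 geometry = geom, K = 1),
            class = "peak_field")
}

test_that("streamlines span a straight tube and respect length bounds", {
  sch <- qball_scheme()
  sp <- phantom_spec("straight_tube", snr = Inf)   # 20 mm tube along x
  ph <- simulate_dwi_phantom(sp, sch)
  pk <- evaluate_odf_peaks(fit_qball_odf(ph, sch), shared_mesh())
  cfg <- tracking_config(rng_seed = 41)
  sls <- track_deterministic(pk, cfg)
  expect_gt(length(sls$streamlines), 0)
  spans <- vapply(sls$streamlines, function(p) max(p[, 1]) - min(p[, 1]),
                  numeric(1))
  tube_mm <- 40 * 0.5
  expect_gte(mean(spans >= tube_mm - 2 * cfg$step_mm - 1), 0.95)
  expect_gte(length(sls$streamlines) / sls$n_candidates, 0.95)
  expect_true(all(sls$lengths >= 5 & sls$lengths <= 120))
  expect_true(all(abs(sls$lengths - (tube_mm - 0.5)) <= 2 * cfg$step_mm + 1))
  # step spacing invariant: consecutive points are one step apart
  pts <- sls$streamlines[[1]]
  seg <- sqrt(rowSums(diff(pts)^2))
  expect_equal(seg, rep(cfg$step_mm, length(seg)), tolerance = 1e-9)
})

test_that("tracking is a pure function of peaks and configuration", {
  pk <- manual_peak_field(c(20, 5, 5), c(0.5, 0.5, 0.5),
                          function(ijk) c(1, 0, 0))
  a <- track_deterministic(pk, tracking_config(rng_seed = 7))
  b <- track_deterministic(pk, tracking_config(rng_seed = 7))
  expect_identical(a$streamlines, b$streamlines)
  c <- track_deterministic(pk, tracking_config(rng_seed = 8))
  expect_false(identical(a$streamlines, c$streamlines))
})

test_that("an abrupt 90-degree interface terminates every track", {
  # left half points along x, right half along y: the 55-degree rule fires
  pk <- manual_peak_field(c(30, 9, 5), c(0.5, 0.5, 0.5), function(ijk) {
    if (ijk[1] <= 15) c(1, 0, 0) else c(0, 1, 0)
  })
  sls <- track_deterministic(pk, tracking_config(rng_seed = 42))
  # no streamline contains both a long x-run and a long y-run
  expect_true(all(vapply(sls$streamlines, function(pts) {
    max(pts[, 1]) - min(pts[, 1]) < 8 || max(pts[, 2]) - min(pts[, 2]) < 8
  }, logical(1))))
  # x-seeded tracks stop at the interface: they never reach deep right side
  left_tracks <- Filter(function(p) max(p[, 2]) - min(p[, 2]) < 2,
                        sls$streamlines)
  expect_gt(length(left_tracks), 0)
  expect_true(all(vapply(left_tracks, function(pts) max(pts[, 1]),
                         numeric(1)) < 15 * 0.5 + 1))
})

test_that("tubes below the length floor yield no streamlines", {
  sch <- qball_scheme()
  sp <- phantom_spec("straight_tube", dims = c(6, 8, 8), snr = Inf)  # 3 mm
  ph <- simulate_dwi_phantom(sp, sch)
  pk <- evaluate_odf_peaks(fit_qball_odf(ph, sch), shared_mesh())
  sls <- track_deterministic(pk, tracking_config())
  expect_length(sls$streamlines, 0)
  expect_gt(sls$n_candidates, 0)
})

test_that("momentum weighting keeps tracks in their tube at a crossing", {
  sch <- qball_scheme()
  sp <- phantom_spec("crossing", dims = c(24, 24, 6), snr = Inf)
  ph <- simulate_dwi_phantom(sp, sch)
  pk <- evaluate_odf_peaks(fit_qball_odf(ph, sch), shared_mesh())
  sls <- track_deterministic(pk, tracking_config(rng_seed = 5))
  # tracks seeded in tube 1 (but outside the crossing) stay x-dominant
  t1 <- which(as.vector(sp$masks$tube1 & !sp$masks$tube2))
  sel <- which(sls$seeds %in% t1)
  expect_gt(length(sel), 0)
  expect_true(all(vapply(sel, function(i) {
    pts <- sls$streamlines[[i]]
    (max(pts[, 1]) - min(pts[, 1])) > 3 * (max(pts[, 2]) - min(pts[, 2]))
  }, logical(1))))
})

test_that("streamline files round-trip through the text format", {
  pk <- manual_peak_field(c(16, 4, 4), c(0.5, 0.5, 0.5),
                          function(ijk) c(1, 0, 0))
  sls <- track_deterministic(pk, tracking_config(rng_seed = 3))
  f <- withr::local_tempfile()
  write_streamlines(sls, f)
  back <- read_streamlines(f)
  expect_length(back, length(sls$streamlines))
  expect_equal(unname(back[[1]]), unname(sls$streamlines[[1]]),
               tolerance = 1e-9)
})

test_that("fiber density matches brute-force counting and the zero rule", {
  sch <- qball_scheme()
  sp <- phantom_spec("straight_tube", snr = Inf)
  ph <- simulate_dwi_phantom(sp, sch)
  pk <- evaluate_odf_peaks(fit_qball_odf(ph, sch), shared_mesh())
  sls <- track_deterministic(pk, tracking_config(rng_seed = 6))
  atlas <- phantom_endpoint_atlas(sp)
  fd <- fiber_density_matrix(sls, atlas)
  counts <- oracle_fiber_counts(sls, atlas, fd$roi_order)
  expect_equal(fd$counts, counts)
  nv <- atlas$roi_table$n_voxels
  expect_equal(fd$density_raw, counts / outer(nv, nv, `+`),
               tolerance = 1e-12)
  # all tube-spanning fibers touch both ends: density is count/(27+27)
  n_span <- counts["tube1_A", "tube1_B"]
  expect_equal(fd$density["tube1_A", "tube1_B"], n_span / 54)
  expect_gt(fd$density["tube1_A", "tube1_B"], 1)
  # zeroing: thin the streamlines so density drops below 1 fiber/voxel
  few <- sls; few$streamlines <- sls$streamlines[1:30]
  fd2 <- fiber_density_matrix(few, atlas)
  expect_equal(fd2$density["tube1_A", "tube1_B"], 0)
  expect_equal(fd2$density_raw["tube1_A", "tube1_B"], 30 / 54,
               tolerance = 1e-12)
  expect_error(fiber_density_matrix(sls, atlas, rois = "nope"), "unknown")
})

test_that("group averaging of densities applies the zero rule afterwards", {
  mk <- function(c12) {
    structure(list(density = NULL,
                   density_raw = matrix(c(0, c12, c12, 0), 2,
                                        dimnames = list(c("A", "B"),
                                                        c("A", "B"))),
                   counts = matrix(0, 2, 2), roi_order = c("A", "B"),
                   zero_below = 1), class = "fiber_density")
  }
  # per-subject densities 0.8 and 1.4: mean 1.1 survives, though one
  # subject alone is sub-threshold
  avg <- average_fiber_density(list(mk(0.8), mk(1.4)))
  expect_equal(avg$density["A", "B"], 1.1)
  avg2 <- average_fiber_density(list(mk(0.8), mk(0.9)))
  expect_equal(avg2$density["A", "B"], 0)
  expect_equal(avg2$density_raw["A", "B"], 0.85)
})
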