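#' Full functional-connectivity group analysis
#'
#' Runs the functional arm on a simulated (or otherwise assembled) cohort:
#' preprocessing per dataset, ROI time-series extraction, per-subject
#' Fisher-z connectivity matrices, group stacks and group averages per time
#' point, within-group Friedman tests between the two time points,
#' between-group Kruskal-Wallis + Dunn tests per time point, and the
#' origin-constrained slope of each group's average matrices.
#'
#' @param cohort list of records from [simulate_study_cohort()] (each with
#'   `subject`, `group`, `time_point`, `bold`, `nuisance`).
#' @param atlas the [atlas_labels()] the cohort was simulated on.
#' @param config a [preproc_config()].
#' @param exact_friedman use the exact sign-permutation Friedman p
#'   (default TRUE, appropriate for small groups).
#' @return list with `conn` (per-subject `conn_matrix`), `stacks`
#'   (group x time `group_stack`s), `averages` (group x time average
#'   matrices), `friedman` (per group), `kruskal` (per time point), `slopes`
#'   (per group `slope_fit`), `manifest`.
#' @export
run_functional_pipeline <- function(cohort, atlas, config = preproc_config(),
                                    exact_friedman = TRUE) {
  manifest <- attr(cohort, "manifest")
  if (is.null(manifest)) {
    manifest <- do.call(rbind, lapply(cohort, function(r) {
      data.frame(subject = r$subject, group = r$group,
                 time_point = r$time_point, stringsAsFactors = FALSE)
    }))
  }
  conn <- lapply(cohort, function(r) {
    pp <- preprocess_bold(r$bold, r$nuisance, config)
    ts <- extract_roi_timeseries(pp, atlas)
    connectivity_matrix(ts, subject = r$subject, group = r$group,
                        time_point = r$time_point)
  })
  groups <- unique(manifest$group)
  tps <- unique(manifest$time_point)
  stacks <- list()
  averages <- list()
  for (g in groups) {
    for (tp in tps) {
      sel <- which(manifest$group == g & manifest$time_point == tp)
      if (!length(sel)) next
      key <- paste(g, tp, sep = ".")
      stacks[[key]] <- group_stack(conn[sel], g, tp,
                                   subjects = manifest$subject[sel])
      averages[[key]] <- group_average_matrix(conn[sel], group = g,
                                              time_point = tp)
    }
  }
  friedman <- list()
  slopes <- list()
  if (length(tps) == 2) {
    for (g in groups) {
      k1 <- paste(g, tps[1], sep = ".")
      k2 <- paste(g, tps[2], sep = ".")
      friedman[[g]] <- friedman_within_group(stacks[[k1]], stacks[[k2]],
                                             exact = exact_friedman)
      slopes[[g]] <- origin_slope_fit(averages[[k1]], averages[[k2]])
    }
  }
  kruskal <- list()
  if (length(groups) >= 2) {
    for (tp in tps) {
      kruskal[[tp]] <- kruskal_dunn_between_groups(
        lapply(groups, function(g) stacks[[paste(g, tp, sep = ".")]]))
    }
  }
  list(conn = conn, stacks = stacks, averages = averages,
       friedman = friedman, kruskal = kruskal, slopes = slopes,
       manifest = manifest)
}

#' Endpoint atlas for a tube phantom
#'
#' Labels the first and last `end_len` in-tube slabs of every tube of a
#' phantom as ROIs (tube 1: A/B along x, tube 2: C/D along y), giving the
#' fiber-density stage known endpoint regions.
#'
#' @param spec a [phantom_spec()] with at least one tube.
#' @param end_len slab thickness in voxels (default 3).
#' @return An [atlas_labels()] in the phantom's geometry.
#' @export
phantom_endpoint_atlas <- function(spec, end_len = 3L) {
  if (!length(spec$masks)) stop("phantom has no tubes")
  dims <- spec$geometry$dims
  labels <- array(0L, dims)
  nm <- character(0)
  lbl <- 0L
  for (t in seq_along(spec$masks)) {
    m <- spec$masks[[t]]
    axis <- which.max(abs(spec$fibers[[t]]))
    idx <- which(m, arr.ind = TRUE)
    lo <- min(idx[, axis])
    hi <- max(idx[, axis])
    for (side in 1:2) {
      rng <- if (side == 1) lo:(lo + end_len - 1L) else (hi - end_len + 1L):hi
      sel <- m & (slice.index(m, axis) %in% rng)
      lbl <- lbl + 1L
      labels[sel] <- lbl
      nm <- c(nm, paste0("tube", t, "_", c("A", "B")[side]))
    }
  }
  atlas_labels(labels, spec$geometry,
               data.frame(label = seq_len(lbl), name = nm,
                          hemisphere = "both", stringsAsFactors = FALSE))
}

#' Full diffusion arm on a simulated phantom
#'
#' Simulates the phantom, reconstructs Q-ball ODFs, extracts peaks, tracks
#' streamlines and builds the voxel-normalized fiber-density matrix over the
#' phantom's endpoint ROIs.
#'
#' @param spec a [phantom_spec()].
#' @param scheme a [diffusion_scheme()] (default the 126-direction b = 2000
#'   scheme).
#' @param cfg a [tracking_config()].
#' @param L,lambda Q-ball reconstruction parameters.
#' @param tessellation ODF mesh tessellation factor.
#' @param seed simulation RNG seed.
#' @return list with `phantom`, `odf`, `peaks`, `streamlines`, `density`.
#' @export
run_diffusion_pipeline <- function(spec, scheme = make_qball_scheme(),
                                   cfg = tracking_config(), L = 8,
                                   lambda = 0.006, tessellation = 8,
                                   seed = 1) {
  ph <- simulate_dwi_phantom(spec, scheme, seed = seed)
  odf <- fit_qball_odf(ph, scheme, L = L, lambda = lambda)
  mesh <- odf_mesh(tessellation)
  peaks <- evaluate_odf_peaks(odf, mesh)
  sls <- track_deterministic(peaks, cfg)
  atlas <- phantom_endpoint_atlas(spec)
  dens <- fiber_density_matrix(sls, atlas)
  list(phantom = ph, odf = odf, peaks = peaks, streamlines = sls,
       density = dens)
}

#' Read a run configuration from a YAML key-value file
#'
#' Recognized top-level blocks: `preproc` (fields of [preproc_config()]) and
#' `tracking` (fields of [tracking_config()]); missing fields keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return list with `preproc` and `tracking` config objects.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read run configurations")
  }
  raw <- yaml::read_yaml(path)
  pp <- do.call(preproc_config, raw$preproc %||% list())
  tk <- do.call(tracking_config, raw$tracking %||% list())
  list(preproc = pp, tracking = tk)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
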