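# Shared fixtures and independent oracles. Everything is generated in code;
# expensive shared objects are built once per test run.

tiny_geometry <- function(dims = c(4, 4, 2), vox = c(0.182, 0.182, 0.5)) {
  volume_geometry(dims, vox)
}

# 12-ROI atlas matching the default correlation structure
study_atlas <- function() {
  make_block_atlas(12, c(4, 4, 2), c(4, 3, 1),
                   roi_names = rownames(default_base_corr()))
}

# small cohort for fast pipeline tests: 2 groups x 2 subjects x 2 time points
small_spec <- function(seed = 1) {
  study_spec(groups = list(tg = c(baseline = 0.5, treated = 1),
                           ctrl = c(baseline = 1, treated = 1)),
             n_subjects = c(tg = 2, ctrl = 2),
             master_seed = seed)
}

cached <- local({
  env <- new.env()
  function(key, expr) {
    if (is.null(env[[key]])) env[[key]] <- force(expr)
    env[[key]]
  }
})

qball_scheme <- function() cached("scheme", make_qball_scheme())
shared_mesh <- function() cached("mesh", odf_mesh(8))

# ---- independent oracles -------------------------------------------------

# brute-force double-loop Pearson + atanh connectivity
oracle_conn_z <- function(ts) {
  k <- nrow(ts)
  z <- matrix(NA_real_, k, k, dimnames = list(rownames(ts), rownames(ts)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      num <- sum((ts[i, ] - mean(ts[i, ])) * (ts[j, ] - mean(ts[j, ])))
      den <- sqrt(sum((ts[i, ] - mean(ts[i, ]))^2) *
                    sum((ts[j, ] - mean(ts[j, ]))^2))
      z[i, j] <- atanh(num / den)
    }
  }
  z
}

# exact sign-flip enumeration of the paired two-condition Friedman test:
# tied subjects are fixed, every non-tied subject's order is flipped, and
# the tie-corrected statistic is recomputed each time
oracle_friedman_exact <- function(y1, y2) {
  d <- sign(y2 - y1)
  free <- which(d != 0)
  m <- length(free)
  if (m == 0) return(NA_real_)
  stat <- function(s) sum(s)^2 / length(s)   # tie-corrected Q, k = 2
  obs <- stat(d[free])
  hits <- 0L
  for (mask in 0:(2^m - 1)) {
    s <- d[free] * ifelse(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0, -1, 1)
    if (stat(s) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / 2^m
}

# atanh via the logarithm identity, independent of base atanh
oracle_atanh <- function(r) 0.5 * log((1 + r) / (1 - r))

# brute-force fiber counting: for each streamline, collect the ROI labels
# under its points, then increment every unordered pair
oracle_fiber_counts <- function(streamlines, atlas, rois) {
  tab <- atlas$roi_table
  labs <- tab$label[match(rois, tab$name)]
  k <- length(rois)
  counts <- matrix(0, k, k, dimnames = list(rois, rois))
  for (pts in streamlines$streamlines) {
    touched <- logical(k)
    for (p in seq_len(nrow(pts))) {
      v <- floor(world_to_voxel(atlas$geometry, pts[p, ]) + 0.5) + 1
      if (any(v < 1) || any(v > atlas$geometry$dims)) next
      l <- atlas$labels[v[1], v[2], v[3]]
      if (l > 0 && l %in% labs) touched[match(l, labs)] <- TRUE
    }
    w <- which(touched)
    if (length(w) >= 2) {
      for (a in w) for (b in w) if (a < b) {
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
      }
    }
  }
  counts
}

# fraction of spectral power of a series inside a frequency band
band_power_fraction <- function(x, tr, band) {
  n <- length(x)
  sp <- abs(fft(x - mean(x)))^2
  fr <- (seq_len(n) - 1) / (n * tr)
  half <- fr <= 1 / (2 * tr)
  inband <- half & fr >= band[1] & fr <= band[2]
  sum(sp[inband]) / sum(sp[half])
}
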