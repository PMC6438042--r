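#' Extract ROI-average time series
#'
#' Row i of the result is the arithmetic mean, per frame, of all voxel series
#' labelled with ROI i.
#'
#' @param bold a [bold4d()].
#' @param atlas an [atlas_labels()] sharing the BOLD geometry.
#' @param rois ROI names to extract, in the requested order (default: all,
#'   in ROI-table order).
#' @return numeric matrix (n_rois x n_frames) with ROI names as rownames.
#' @export
extract_roi_timeseries <- function(bold, atlas, rois = NULL) {
  if (!geometry_equal(bold$geometry, atlas$geometry)) {
    stop("BOLD and atlas geometries differ")
  }
  tab <- atlas$roi_table
  if (is.null(rois)) rois <- tab$name
  missing <- setdiff(rois, tab$name)
  if (length(missing)) stop("unknown ROI(s): ", paste(missing, collapse = ", "))
  lab <- as.vector(atlas$labels)
  Y <- matrix(bold$data, length(lab), bold$n_frames)
  out <- matrix(NA_real_, length(rois), bold$n_frames,
                dimnames = list(rois, NULL))
  for (i in seq_along(rois)) {
    l <- tab$label[tab$name == rois[i]]
    vox <- which(lab == l)
    if (!length(vox)) stop("ROI has no voxels: ", rois[i])
    out[i, ] <- colMeans(Y[vox, , drop = FALSE])
  }
  out
}

#' Fisher z-transformation of correlation coefficients
#'
#' `z = atanh(r)`, with `|r|` clipped to `1 - 1e-7` so degenerate
#' (perfectly correlated) inputs stay finite; the number of clipped values is
#' attached as attribute `n_clipped`.
#'
#' @param r numeric vector/matrix of correlations with `|r| <= 1`.
#' @return Fisher z values of the same shape.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r) & !is.na(r))) stop("non-finite correlation input")
  eps <- 1e-7
  clip <- !is.na(r) & abs(r) >= 1 - eps
  r[clip] <- sign(r[clip]) * (1 - eps)
  out <- atanh(r)
  attr(out, "n_clipped") <- sum(clip)
  out
}

#' Inter-node Fisher-z connectivity matrix
#'
#' Full Pearson correlation between every pair of ROI-average time series,
#' Fisher z-transformed. The diagonal is undefined (NA).
#'
#' @param ts ROI x frames matrix from [extract_roi_timeseries()].
#' @param subject,group,time_point optional metadata carried on the result.
#' @return An object of class `conn_matrix` with fields `z` (symmetric, NA
#'   diagonal), `roi_order`, `meta` and `n_clipped`.
#' @export
connectivity_matrix <- function(ts, subject = NA, group = NA,
                                time_point = NA) {
  ts <- as.matrix(ts)
  sds <- apply(ts, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance ROI series: ",
         paste(rownames(ts)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(t(ts))
  z <- fisher_z(r)
  n_clipped <- attr(z, "n_clipped") - nrow(ts)   # diagonal r = 1 not counted
  attr(z, "n_clipped") <- NULL
  diag(z) <- NA_real_
  structure(list(z = z, roi_order = rownames(ts),
                 meta = list(subject = subject, group = group,
                             time_point = time_point, n = 1L),
                 n_clipped = n_clipped),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  off <- x$z[upper.tri(x$z)]
  cat(sprintf("<conn_matrix> %d ROIs", length(x$roi_order)))
  if (!is.na(x$meta$subject)) cat(", subject", x$meta$subject)
  if (!is.na(x$meta$group)) {
    cat(sprintf(", %s/%s (n = %d)", x$meta$group, x$meta$time_point,
                x$meta$n))
  }
  cat(sprintf("\n  mean off-diagonal z = %.3f (range %.3f .. %.3f)\n",
              mean(off, na.rm = TRUE), min(off, na.rm = TRUE),
              max(off, na.rm = TRUE)))
  invisible(x)
}

#' Intra-node connectivity strength of one ROI
#'
#' Mean, over all unordered pairs of voxels inside the ROI, of the Fisher
#' z-transformed Pearson correlation of the voxel series (transform first,
#' average afterwards). Constant voxels are excluded; pairs lost that way are
#' reported in attribute `n_excluded_voxels`.
#'
#' @param bold a [bold4d()] (typically preprocessed).
#' @param atlas an [atlas_labels()].
#' @param roi ROI name.
#' @return scalar strength (mean within-ROI z).
#' @export
intra_node_strength <- function(bold, atlas, roi) {
  tab <- atlas$roi_table
  if (!roi %in% tab$name) stop("unknown ROI: ", roi)
  l <- tab$label[tab$name == roi]
  vox <- which(as.vector(atlas$labels) == l)
  Y <- matrix(bold$data, prod(dim(bold$data)[1:3]), bold$n_frames)[vox, ,
                                                                   drop = FALSE]
  sds <- apply(Y, 1, stats::sd)
  usable <- sds > 0
  if (sum(usable) < 2) stop("ROI ", roi, " has < 2 usable voxels")
  r <- stats::cor(t(Y[usable, , drop = FALSE]))
  z <- fisher_z(r)
  out <- mean(z[upper.tri(z)])
  attr(out, "n_excluded_voxels") <- sum(!usable)
  attr(out, "n_pairs") <- sum(upper.tri(z))
  out
}

#' Intra-node strength for a set of ROIs
#'
#' @inheritParams intra_node_strength
#' @param rois ROI names (default: all ROIs with at least 2 voxels).
#' @return An object of class `node_strength`: named numeric vector of mean
#'   within-ROI z values.
#' @export
node_strength_vector <- function(bold, atlas, rois = NULL) {
  tab <- atlas$roi_table
  if (is.null(rois)) rois <- tab$name[tab$n_voxels >= 2]
  s <- vapply(rois, function(r) as.numeric(intra_node_strength(bold, atlas, r)),
              numeric(1))
  structure(s, names = rois, class = "node_strength")
}

#' Group-average connectivity matrix
#'
#' Elementwise arithmetic mean of per-subject Fisher z matrices (z-transform
#' first, then average — never the reverse).
#'
#' @param matrices list of [connectivity_matrix()] results sharing
#'   `roi_order`.
#' @param group,time_point metadata for the averaged matrix.
#' @return A `conn_matrix` with `meta$n = length(matrices)`.
#' @export
group_average_matrix <- function(matrices, group = NA, time_point = NA) {
  if (!length(matrices)) stop("need at least one matrix")
  ord <- matrices[[1]]$roi_order
  for (m in matrices) {
    if (!identical(m$roi_order, ord)) stop("roi_order mismatch")
  }
  zs <- lapply(matrices, `[[`, "z")
  zbar <- Reduce(`+`, zs) / length(zs)
  structure(list(z = zbar, roi_order = ord,
                 meta = list(subject = NA, group = group,
                             time_point = time_point,
                             n = length(matrices)),
                 n_clipped = sum(vapply(matrices, `[[`, 0, "n_clipped"))),
            class = "conn_matrix")
}

# pull the z matrix out of a conn_matrix or accept a plain matrix
as_z_matrix <- function(m) {
  if (inherits(m, "conn_matrix")) m$z else as.matrix(m)
}
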