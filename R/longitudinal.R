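#' Origin-constrained slope between two connectivity matrices
#'
#' Scatter of every unordered off-diagonal edge of the later time point (y)
#' against the earlier one (x), fitted by least squares with a line through
#' the origin: `slope = sum(x y) / sum(x^2)`. A slope above 1 means an
#' overall increase of the edge values from the first to the second time
#' point; the deviation from the identity line (slope = 1) quantifies the
#' global change.
#'
#' @param m1 earlier-time-point matrix ([connectivity_matrix()] result or
#'   plain symmetric matrix); provides the x axis.
#' @param m2 later-time-point matrix (y axis), same ROI order.
#' @return An object of class `slope_fit` with `slope`, `n_points`,
#'   `rms_residual` and the edge scatter (`x`, `y`).
#' @export
origin_slope_fit <- function(m1, m2) {
  z1 <- as_z_matrix(m1)
  z2 <- as_z_matrix(m2)
  if (!identical(dimnames(z1), dimnames(z2)) ||
      !all(dim(z1) == dim(z2))) {
    stop("matrices must share ROI order")
  }
  ut <- upper.tri(z1)
  x <- z1[ut]
  y <- z2[ut]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need >= 2 edges")
  sxx <- sum(x^2)
  if (sxx == 0) stop("all earlier-time-point edges are zero")
  slope <- sum(x * y) / sxx
  rms <- sqrt(mean((y - slope * x)^2))
  structure(list(slope = slope, n_points = length(x), rms_residual = rms,
                 x = x, y = y, axis = "x = earlier time point"),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf(
    "<slope_fit> slope = %.4f over %d edges (rms residual %.4f; %s)\n",
    x$slope, x$n_points, x$rms_residual, x$axis))
  invisible(x)
}

#' @export
coef.slope_fit <- function(object, ...) c(slope = object$slope)

#' Elementwise difference of two matched matrices
#'
#' Later minus earlier, preserving dimnames; used for longitudinal
#' difference matrices of connectivity or fiber density.
#'
#' @param m_late,m_early conn/density objects or plain matrices with
#'   identical ROI order.
#' @return numeric matrix `m_late - m_early`.
#' @export
matrix_difference <- function(m_late, m_early) {
  a <- as_z_matrix(m_late)
  b <- as_z_matrix(m_early)
  if (!all(dim(a) == dim(b)) || !identical(dimnames(a), dimnames(b))) {
    stop("ROI order mismatch")
  }
  a - b
}

#' Edge profile of a single node
#'
#' The connectivity values of one node to an ordered list of target nodes
#' (e.g. hippocampus to all cortical and default-mode regions).
#'
#' @param m a [connectivity_matrix()] result (or named symmetric matrix).
#' @param node source ROI name.
#' @param targets ordered target ROI names, not containing `node`.
#' @return named numeric vector of z values, in target order.
#' @export
node_edge_profile <- function(m, node, targets) {
  z <- as_z_matrix(m)
  ord <- rownames(z)
  if (!node %in% ord) stop("unknown node: ", node)
  bad <- setdiff(targets, ord)
  if (length(bad)) stop("unknown target(s): ", paste(bad, collapse = ", "))
  if (node %in% targets) stop("node must not appear among targets")
  stats::setNames(z[node, targets], targets)
}
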