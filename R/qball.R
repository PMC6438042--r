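#' Index table of the real even spherical-harmonic basis
#'
#' @param L maximum (even) order.
#' @return data frame with one row per basis function, columns `l`, `m`;
#'   `(L+1)(L+2)/2` rows.
#' @export
sh_index_table <- function(L) {
  if (L %% 2 != 0) stop("L must be even")
  do.call(rbind, lapply(seq(0, L, by = 2), function(l) {
    data.frame(l = l, m = -l:l)
  }))
}

#' Evaluate the real, even-order spherical-harmonic basis
#'
#' Modified real basis standard in analytic Q-ball work: for order l and
#' `m > 0` the cosine harmonic, `m < 0` the sine harmonic (both scaled by
#' sqrt(2)), `m = 0` the zonal harmonic; only even l, so every basis
#' function is antipodally symmetric. Associated Legendre functions include
#' the Condon-Shortley phase.
#'
#' @param dirs n x 3 matrix of unit direction vectors.
#' @param L maximum even order.
#' @return n x (L+1)(L+2)/2 design matrix.
#' @export
sh_basis <- function(dirs, L) {
  dirs <- rbind3(dirs)
  z <- pmin(1, pmax(-1, dirs[, 3]))
  phi <- atan2(dirs[, 2], dirs[, 1])
  tab <- sh_index_table(L)
  B <- matrix(0, nrow(dirs), nrow(tab))
  for (l in seq(0, L, by = 2)) {
    P <- pracma::legendre(l, z)            # (l+1) x n, rows m = 0..l
    if (is.null(dim(P))) P <- matrix(P, nrow = 1)
    for (m in -l:l) {
      am <- abs(m)
      K <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      col <- which(tab$l == l & tab$m == m)
      if (m == 0) {
        B[, col] <- K * P[1, ]
      } else if (m > 0) {
        B[, col] <- sqrt(2) * K * P[am + 1, ] * cos(am * phi)
      } else {
        B[, col] <- sqrt(2) * K * P[am + 1, ] * sin(am * phi)
      }
    }
  }
  B
}

# Legendre polynomial at zero: P_l(0) = (-1)^(l/2) (l-1)!! / l!!, l even
legendre_p0 <- function(l) {
  vapply(l, function(li) {
    if (li == 0) return(1)
    (-1)^(li / 2) * prod(seq(1, li - 1, by = 2)) / prod(seq(2, li, by = 2))
  }, numeric(1))
}

#' Analytic Q-ball ODF reconstruction
#'
#' Per voxel: the diffusion signal is normalized by the mean b = 0 image,
#' fitted with the real even spherical-harmonic basis up to order `L` by
#' regularized least squares with the Laplace-Beltrami penalty
#' `lambda * sum l^2 (l+1)^2 c^2`, and the Funk-Radon transform is applied
#' analytically by scaling each order-l coefficient with `2 pi P_l(0)`
#' (Legendre polynomial at zero). Odd-order content is implicitly zero, so
#' the ODF is antipodally symmetric by construction.
#'
#' @param dwi 4D array of diffusion volumes (or the list returned by
#'   [simulate_dwi_phantom()], whose geometry is then used).
#' @param scheme the matching [diffusion_scheme()].
#' @param L maximum even spherical-harmonic order (default 8; needs at least
#'   `(L+1)(L+2)/2` distinct diffusion directions).
#' @param lambda Laplace-Beltrami regularization weight (default 0.006).
#' @param mask logical 3D array or linear voxel indices (default: voxels
#'   with positive mean b0 signal).
#' @param geometry [volume_geometry()]; required when `dwi` is a bare array.
#' @return An object of class `odf_field`: `coefficients` (basis x voxel
#'   matrix of ODF coefficients, masked voxels only), `signal_coefficients`,
#'   `sh` (index table), `L`, `lambda`, `mask` (linear indices), `geometry`.
#' @export
fit_qball_odf <- function(dwi, scheme, L = 8, lambda = 0.006, mask = NULL,
                          geometry = NULL) {
  if (is.list(dwi)) {
    geometry <- dwi$geometry
    dwi <- dwi$dwi
  }
  if (is.null(geometry)) stop("geometry required")
  d <- dim(dwi)
  if (length(d) != 4L || d[4] != length(scheme$bvals)) {
    stop("dwi volume count does not match the scheme")
  }
  tab <- sh_index_table(L)
  dw <- scheme$bvals > 0
  if (sum(dw) < nrow(tab)) {
    stop(sprintf("need >= %d diffusion directions for L = %d, have %d",
                 nrow(tab), L, sum(dw)))
  }
  Y <- matrix(dwi, prod(d[1:3]), d[4])
  s0 <- rowMeans(Y[, !dw, drop = FALSE])
  if (is.null(mask)) {
    mask_idx <- which(s0 > 0)
  } else if (is.logical(mask) || is.array(mask)) {
    mask_idx <- which(as.vector(mask) != 0)
  } else {
    mask_idx <- as.integer(mask)
  }
  if (!length(mask_idx)) stop("empty mask")
  if (any(s0[mask_idx] <= 0)) stop("zero b0 signal inside the mask")
  E <- Y[mask_idx, dw, drop = FALSE] / s0[mask_idx]
  E <- pmin(pmax(E, 1e-6), 1)
  B <- sh_basis(t(scheme$bvecs[, dw, drop = FALSE]), L)
  lb <- tab$l^2 * (tab$l + 1)^2
  W <- solve(crossprod(B) + lambda * diag(lb), t(B))
  C_sig <- W %*% t(E)                      # basis x voxel
  frt <- 2 * pi * legendre_p0(tab$l)
  structure(list(coefficients = frt * C_sig, signal_coefficients = C_sig,
                 sh = tab, L = L, lambda = lambda, mask = mask_idx,
                 geometry = geometry),
            class = "odf_field")
}

#' @export
print.odf_field <- function(x, ...) {
  cat(sprintf("<odf_field> order %d (%d coefficients), lambda = %g, %d voxels\n",
              x$L, nrow(x$coefficients), x$lambda, length(x$mask)))
  invisible(x)
}

# unit icosahedron
.icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

.subdivide_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  cache <- new.env(parent = emptyenv())
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- v[i, ] + v[j, ]
    p <- p / sqrt(sum(p^2))
    v <<- rbind(v, p)
    cache[[key]] <- nrow(v)
    nrow(v)
  }
  nf <- matrix(0L, 0, 3)
  for (k in seq_len(nrow(f))) {
    a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
  }
  list(vertices = v, faces = nf)
}

#' Subdivided icosahedral sphere mesh for ODF sampling
#'
#' Vertices of an icosahedron subdivided `log2(tessellation)` times
#' (tessellation 8 gives 642 directions on the full sphere, 321 per
#' hemisphere). The mesh is centrally symmetric; each vertex knows its
#' antipode and its triangle-edge neighbours, which drives discrete peak
#' detection.
#'
#' @param tessellation edge subdivision factor, a power of two (default 8).
#' @return An object of class `odf_mesh`: `vertices` (n x 3 unit rows),
#'   `adjacency` (list of neighbour indices), `antipode` (index vector),
#'   `hemi` (logical: canonical hemisphere representative), `tessellation`.
#' @export
odf_mesh <- function(tessellation = 8) {
  lv <- log2(tessellation)
  if (lv %% 1 != 0 || lv < 0) stop("tessellation must be a power of 2")
  mesh <- .icosahedron()
  for (i in seq_len(lv)) mesh <- .subdivide_mesh(mesh)
  v <- unname(mesh$vertices)
  n <- nrow(v)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[k, ]
    adj[[f[1]]] <- c(adj[[f[1]]], f[2], f[3])
    adj[[f[2]]] <- c(adj[[f[2]]], f[1], f[3])
    adj[[f[3]]] <- c(adj[[f[3]]], f[1], f[2])
  }
  adj <- lapply(adj, unique)
  dots <- v %*% t(v)
  antipode <- unname(apply(dots, 1, which.min))
  eps <- 1e-9
  hemi <- v[, 3] > eps |
    (abs(v[, 3]) <= eps & v[, 2] > eps) |
    (abs(v[, 3]) <= eps & abs(v[, 2]) <= eps & v[, 1] > 0)
  structure(list(vertices = v, adjacency = adj, antipode = antipode,
                 hemi = hemi, faces = mesh$faces,
                 tessellation = tessellation),
            class = "odf_mesh")
}

#' @export
print.odf_mesh <- function(x, ...) {
  cat(sprintf("<odf_mesh> tessellation %d: %d directions (%d per hemisphere)\n",
              x$tessellation, nrow(x$vertices), sum(x$hemi)))
  invisible(x)
}

#' Extract ODF peaks and quantitative anisotropy
#'
#' The ODF is sampled at the mesh directions; discrete local maxima over the
#' triangle-edge adjacency are the candidate peaks (antipodal duplicates are
#' collapsed to the canonical hemisphere). Quantitative anisotropy of a peak
#' is its ODF value minus the voxel's ODF minimum, normalized by the largest
#' such value over the mask, so QA lies in [0, 1] and the strongest voxel of
#' the field scores 1. Up to `K` peaks per voxel are kept, in descending QA
#' order.
#'
#' @param odf an [fit_qball_odf()] result.
#' @param mesh an [odf_mesh()].
#' @param K maximum peaks per voxel (default 3).
#' @return An object of class `peak_field`: `peak_dirs` (3 x K x voxel),
#'   `peak_qa`, `peak_odf` (K x voxel), `n_peaks`, `mask`, `qa` (3D array of
#'   the per-voxel top QA), `geometry`.
#' @export
evaluate_odf_peaks <- function(odf, mesh, K = 3) {
  B <- sh_basis(mesh$vertices, odf$L)
  vals <- B %*% odf$coefficients           # directions x voxels
  nv <- ncol(vals)
  nd <- nrow(vals)
  nbr_max <- matrix(-Inf, nd, nv)
  for (d in seq_len(nd)) {
    nb <- mesh$adjacency[[d]]
    nbr_max[d, ] <- do.call(pmax, lapply(nb, function(j) vals[j, ]))
  }
  is_peak <- vals > nbr_max & mesh$hemi    # strict: flat ODFs give no peaks
  odf_min <- apply(vals, 2, min)
  qa_raw <- sweep(vals, 2, odf_min, "-")
  # numerically flat ODFs (isotropic voxels) carry no meaningful peaks
  floor_abs <- 1e-8 * max(abs(vals), 1e-300)
  is_peak <- is_peak & qa_raw > floor_abs
  global <- if (any(is_peak)) max(qa_raw[is_peak]) else 0
  peak_dirs <- array(NA_real_, c(3, K, nv))
  peak_qa <- matrix(0, K, nv)
  peak_odf <- matrix(NA_real_, K, nv)
  n_peaks <- integer(nv)
  for (v in seq_len(nv)) {
    idx <- which(is_peak[, v])
    if (!length(idx)) next
    ordp <- idx[order(vals[idx, v], decreasing = TRUE)]
    ordp <- utils::head(ordp, K)
    n_peaks[v] <- length(ordp)
    for (j in seq_along(ordp)) {
      peak_dirs[, j, v] <- mesh$vertices[ordp[j], ]
      peak_qa[j, v] <- if (global > 0) qa_raw[ordp[j], v] / global else 0
      peak_odf[j, v] <- vals[ordp[j], v]
    }
  }
  qa_vol <- array(0, odf$geometry$dims)
  qa_vol[odf$mask] <- peak_qa[1, ]
  structure(list(peak_dirs = peak_dirs, peak_qa = peak_qa,
                 peak_odf = peak_odf, n_peaks = n_peaks, mask = odf$mask,
                 qa = qa_vol, geometry = odf$geometry, K = K),
            class = "peak_field")
}

#' @export
print.peak_field <- function(x, ...) {
  cat(sprintf("<peak_field> %d voxels, %d with peaks, max QA = %.3f\n",
              length(x$mask), sum(x$n_peaks > 0), max(x$qa)))
  invisible(x)
}
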