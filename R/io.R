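#' 4D BOLD container
#'
#' @param data numeric 4D array (nx, ny, nz, n_frames) of finite values.
#' @param geometry a [volume_geometry()] matching the first three dims.
#' @param tr repetition time in seconds (> 0).
#' @return An object of class `bold4d` with fields `data`, `geometry`, `tr`
#'   and `n_frames`.
#' @export
bold4d <- function(data, geometry, tr) {
  data <- as.array(data)
  stopifnot(length(dim(data)) == 4L)
  if (!all(dim(data)[1:3] == geometry$dims)) {
    stop("data dimensions do not match geometry")
  }
  if (dim(data)[4] < 2L) stop("a BOLD series needs at least 2 frames")
  if (tr <= 0) stop("tr must be > 0")
  if (!all(is.finite(data))) stop("BOLD data must be finite")
  structure(list(data = data, geometry = geometry, tr = as.numeric(tr),
                 n_frames = dim(data)[4]),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  cat(sprintf("<bold4d> %d x %d x %d voxels, %d frames, TR = %.3g s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$n_frames, x$tr))
  invisible(x)
}

#' Per-scan nuisance records
#'
#' Holds the confound series regressed out of each voxel: a recorded
#' respiratory trace sampled once per frame, six rigid-body motion parameter
#' series, and the polynomial drift order (drifts themselves are generated
#' from the frame index at regression time).
#'
#' @param respiration numeric series of length `n_frames` (or NULL for none).
#' @param motion `n_frames` x 6 matrix of motion parameters (or NULL).
#' @param drift_order 0, 1 or 2 (default 2).
#' @param n_frames frame count the series must match.
#' @return An object of class `nuisance_set`.
#' @export
nuisance_set <- function(respiration = NULL, motion = NULL, drift_order = 2L,
                         n_frames = NULL) {
  drift_order <- as.integer(drift_order)
  if (!drift_order %in% 0:2) stop("drift_order must be 0, 1 or 2")
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(ncol(motion) == 6L)
  }
  if (is.null(n_frames)) {
    n_frames <- if (!is.null(respiration)) length(respiration)
                else if (!is.null(motion)) nrow(motion)
                else stop("n_frames required when no series given")
  }
  if (!is.null(respiration) && length(respiration) != n_frames) {
    stop("respiration length does not match n_frames")
  }
  if (!is.null(motion) && nrow(motion) != n_frames) {
    stop("motion rows do not match n_frames")
  }
  structure(list(respiration = respiration, motion = motion,
                 drift_order = drift_order, n_frames = as.integer(n_frames)),
            class = "nuisance_set")
}

#' Write a 3D or 4D volume to NIfTI-1
#'
#' @param data numeric array (3D or 4D), or a [bold4d()].
#' @param geometry [volume_geometry()]; ignored when `data` is a `bold4d`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param tr repetition time in seconds stored in the header (4D only).
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, geometry = NULL, path, tr = 1) {
  if (inherits(data, "bold4d")) {
    geometry <- data$geometry
    tr <- data$tr
    data <- data$data
  }
  stopifnot(!is.null(geometry))
  pix <- c(geometry$voxel_size, tr)[seq_len(length(dim(data)))]
  img <- RNifti::asNifti(data)
  img <- RNifti::`pixdim<-`(img, pix)
  # RNifti derives the qform/sform from pixdim; impose our affine explicitly
  img <- RNifti::`sform<-`(img, structure(geometry$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(geometry$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 image and wraps it in the matching container: a 4D image
#' becomes a [bold4d()] (or a plain diffusion stack with `as_bold = FALSE`),
#' a 3D image a plain array with a `geometry` attribute. Use [read_atlas()]
#' for integer label images.
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @param expected_frames optional frame count to enforce for 4D images.
#' @param as_bold wrap 4D data as `bold4d` (default TRUE).
#' @return `bold4d`, or an array with attributes `geometry` (and `tr` if 4D).
#' @export
read_volume <- function(path, expected_frames = NULL, as_bold = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  geom <- .geometry_from_nifti(img)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))   # drop NIfTI header attributes
  nd <- length(dim(arr))
  if (nd == 4L) {
    if (!is.null(expected_frames) && dim(arr)[4] != expected_frames) {
      stop(sprintf("expected %d frames, found %d", expected_frames,
                   dim(arr)[4]))
    }
    tr <- RNifti::pixdim(img)[4]
    if (!is.finite(tr) || tr <= 0) tr <- 1
    if (as_bold) return(bold4d(arr, geom, tr))
    attr(arr, "geometry") <- geom
    attr(arr, "tr") <- tr
    return(arr)
  }
  if (nd != 3L) stop("expected a 3D or 4D image, got ", nd, "D")
  if (!is.null(expected_frames) && expected_frames != 1L) {
    stop("expected a 4D image with ", expected_frames, " frames, got 3D")
  }
  attr(arr, "geometry") <- geom
  arr
}

.geometry_from_nifti <- function(img) {
  pd <- as.numeric(RNifti::pixdim(img))
  aff <- RNifti::xform(img)
  volume_geometry(dim(img)[1:3], pd[1:3],
                  matrix(as.numeric(aff), 4, 4))
}

#' Atlas label volume with ROI table
#'
#' @param labels integer 3D array; 0 is background.
#' @param geometry [volume_geometry()].
#' @param roi_table data frame with columns `label`, `name`, `hemisphere`
#'   (free tag, e.g. "L"/"R"/"both"); a `n_voxels` column is recomputed from
#'   the volume. If NULL, names `roi<label>` are generated.
#' @return An object of class `atlas_labels`.
#' @export
atlas_labels <- function(labels, geometry, roi_table = NULL) {
  labels <- as.array(labels)
  stopifnot(length(dim(labels)) == 3L)
  if (!all(dim(labels) == geometry$dims)) stop("labels do not match geometry")
  if (any(labels != round(labels))) stop("labels must be integers")
  storage.mode(labels) <- "integer"
  present <- sort(unique(labels[labels != 0L]))
  counts <- tabulate(labels[labels != 0L], nbins = max(c(present, 0L)))
  if (is.null(roi_table)) {
    roi_table <- data.frame(label = present,
                            name = paste0("roi", present),
                            hemisphere = "both",
                            stringsAsFactors = FALSE)
  }
  roi_table <- as.data.frame(roi_table)
  if (anyDuplicated(roi_table$name)) stop("duplicate ROI names")
  missing <- setdiff(present, roi_table$label)
  if (length(missing)) {
    stop("labels present in volume but absent from roi_table: ",
         paste(missing, collapse = ", "))
  }
  roi_table$n_voxels <- counts[roi_table$label]
  roi_table <- roi_table[roi_table$label %in% present, , drop = FALSE]
  rownames(roi_table) <- NULL
  structure(list(labels = labels, geometry = geometry, roi_table = roi_table),
            class = "atlas_labels")
}

#' @export
print.atlas_labels <- function(x, ...) {
  cat(sprintf("<atlas_labels> %d ROIs in a %d x %d x %d volume\n",
              nrow(x$roi_table), dim(x$labels)[1], dim(x$labels)[2],
              dim(x$labels)[3]))
  invisible(x)
}

#' Read an integer atlas label image
#'
#' @param path path to a 3D NIfTI label image (integer-valued).
#' @param roi_table optional ROI table, see [atlas_labels()].
#' @export
read_atlas <- function(path, roi_table = NULL) {
  arr <- read_volume(path)
  if (any(arr != round(arr))) {
    stop("label image contains non-integer values: ", path)
  }
  atlas_labels(arr, attr(arr, "geometry"), roi_table)
}

#' Diffusion gradient scheme
#'
#' @param bvals numeric b-values in s/mm^2, one per volume.
#' @param bvecs 3 x N matrix of gradient directions (unit where bval > 0,
#'   zero where bval = 0); an N x 3 matrix is transposed automatically.
#' @return An object of class `diffusion_scheme` with unit-normalized `bvecs`.
#' @export
diffusion_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  if (nrow(bvecs) != 3L) stop("bvecs must be 3 x N or N x 3")
  if (ncol(bvecs) != length(bvals)) {
    stop(sprintf("bval/bvec length mismatch: %d vs %d", length(bvals),
                 ncol(bvecs)))
  }
  if (any(bvals < 0)) stop("b-values must be >= 0")
  nrm <- sqrt(colSums(bvecs^2))
  dw <- bvals > 0
  if (any(dw & nrm < 1e-12)) {
    stop("zero-norm gradient vector with positive b-value")
  }
  bvecs[, dw] <- sweep(bvecs[, dw, drop = FALSE], 2, nrm[dw], "/")
  bvecs[, !dw] <- 0
  if (!any(!dw)) stop("scheme needs at least one b = 0 volume")
  structure(list(bvals = bvals, bvecs = bvecs), class = "diffusion_scheme")
}

#' @export
print.diffusion_scheme <- function(x, ...) {
  cat(sprintf("<diffusion_scheme> %d volumes (%d b0, %d diffusion-weighted)\n",
              length(x$bvals), sum(x$bvals == 0), sum(x$bvals > 0)))
  invisible(x)
}

#' Read a bval/bvec file pair
#'
#' Accepts the common 3-row (3 x N) whitespace-separated bvec layout, or
#' N x 3, auto-detected by shape. Gradient vectors with positive b-value are
#' normalized to unit length; entries keep file order.
#'
#' @param bval_path one-row (or one-column) whitespace-separated b-values.
#' @param bvec_path whitespace-separated gradient table.
#' @return A [diffusion_scheme()].
#' @export
read_diffusion_scheme <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  rows <- readLines(bvec_path)
  rows <- rows[nzchar(trimws(rows))]
  vals <- lapply(rows, function(r) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(r), "\\s+")[[1]]))
    if (anyNA(v)) stop("non-numeric token in ", bvec_path)
    v
  })
  n <- lengths(vals)
  if (length(unique(n)) != 1L) stop("ragged bvec file: ", bvec_path)
  m <- do.call(rbind, vals)
  if (nrow(m) == 3L && ncol(m) != 3L) {
    bvecs <- m
  } else if (ncol(m) == 3L) {
    bvecs <- t(m)
  } else if (nrow(m) == 3L) {
    bvecs <- m   # ambiguous 3 x 3: treat as 3 rows of x/y/z (FSL layout)
  } else {
    stop("bvec file is neither 3 x N nor N x 3")
  }
  diffusion_scheme(bvals, bvecs)
}

#' Write a bval/bvec file pair (FSL-style 3-row bvec)
#'
#' @param scheme a [diffusion_scheme()].
#' @param bval_path,bvec_path output paths.
#' @export
write_diffusion_scheme <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "),
             bval_path)
  writeLines(apply(scheme$bvecs, 1, function(r) {
    paste(format(r, trim = TRUE, digits = 15), collapse = " ")
  }), bvec_path)
  invisible(NULL)
}

#' Write a square ROI matrix as delimited text
#'
#' CSV with ROI names as both header row and first column; undefined entries
#' (e.g. the diagonal of a connectivity matrix) are written as `NA`.
#' Round-trips through [read_matrix_table()] losslessly to full double
#' precision.
#'
#' @param matrix square numeric matrix.
#' @param roi_names names, one per row/column, unique.
#' @param path output path.
#' @export
write_matrix_table <- function(matrix, roi_names, path) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("matrix must be square")
  if (length(roi_names) != nrow(matrix)) {
    stop("roi_names length must equal matrix dimension")
  }
  if (anyDuplicated(roi_names)) stop("duplicate ROI names")
  dimnames(matrix) <- list(roi_names, roi_names)
  df <- data.frame(roi = roi_names,
                   format(matrix, digits = 17, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = TRUE,
                     na = "NA")
  invisible(path)
}

#' Read a square ROI matrix written by [write_matrix_table()]
#'
#' @param path path to the CSV table.
#' @return numeric matrix with ROI names as dimnames.
#' @export
read_matrix_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  if (nrow(m) != ncol(m)) stop("table is not square: ", path)
  m
}
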