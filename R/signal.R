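#' Framewise displacement from realignment parameters
#'
#' Power-style framewise displacement: backward differences of the six
#' realignment parameters, rotations converted to arc length on a sphere of
#' `head_radius` mm, summed as absolute values.  The first volume has FD = 0
#' by convention; the reported mean FD averages volumes 2..T.
#'
#' @param motion T x 6 matrix: translations x, y, z (mm) then rotations
#'   (radians).  Use `rotations_first = TRUE` and/or `degrees = TRUE` for the
#'   other common file dialect.
#' @param head_radius sphere radius in mm used for the rotation arc length.
#' @param rotations_first are columns 1..3 the rotations?
#' @param degrees are rotations in degrees?
#' @return list with `fd` (per-volume FD, mm) and `mean_fd`.
#' @export
compute_fd <- function(motion, head_radius = 50,
                       rotations_first = FALSE, degrees = FALSE) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have 6 columns")
  if (nrow(motion) < 2) stop("need at least 2 volumes")
  if (!all(is.finite(motion))) stop("invalid motion trace: non-finite values")
  if (rotations_first) motion <- motion[, c(4:6, 1:3)]
  trans <- motion[, 1:3, drop = FALSE]
  rot <- motion[, 4:6, drop = FALSE]
  if (degrees) rot <- rot * pi / 180
  dtrans <- abs(diff(trans))
  drot <- abs(diff(rot)) * head_radius
  fd <- c(0, rowSums(dtrans) + rowSums(drot))
  list(fd = fd, mean_fd = mean(fd[-1]))
}

#' Build the nuisance regressor matrix
#'
#' Columns: the six realignment parameters and their temporal derivatives
#' (backward differences, leading zero), the top `n_components` principal
#' component time courses of the column-demeaned tissue (CSF+WM) signal
#' matrix (unit-norm, ordered by variance), an intercept and a centered
#' first-order (linear) trend.
#'
#' @param motion T x 6 realignment parameters.
#' @param tissue T x V matrix of noise-tissue voxel time series.
#' @param n_components number of tissue components (default 5).
#' @return T x K labeled regressor matrix; columns that are identically zero
#'   because motion is constant are flagged in `attr(, "zero_derivative")`.
#' @export
build_nuisance <- function(motion, tissue, n_components = 5) {
  motion <- as.matrix(motion); tissue <- as.matrix(tissue)
  T <- nrow(motion)
  if (nrow(tissue) != T) stop("motion and tissue must have matching T")
  if (ncol(tissue) < n_components) {
    stop("insufficient tissue voxels: ", ncol(tissue), " < ", n_components)
  }
  stopifnot_finite(motion, "motion"); stopifnot_finite(tissue, "tissue")

  deriv <- rbind(0, diff(motion))
  tis <- sweep(tissue, 2, colMeans(tissue))
  sv <- svd(tis, nu = n_components, nv = 0)
  comp <- sv$u[, seq_len(n_components), drop = FALSE]
  trend <- seq_len(T) - (T + 1) / 2
  X <- cbind(motion, deriv, comp, 1, trend)
  colnames(X) <- c(paste0("motion", 1:6), paste0("dmotion", 1:6),
                   paste0("compcor", seq_len(n_components)),
                   "intercept", "trend")
  zd <- which(colSums(abs(deriv)) == 0)
  attr(X, "zero_derivative") <- if (length(zd)) paste0("dmotion", zd) else character()
  X
}

#' Regress nuisance signals out of ROI time series
#'
#' Ordinary least squares per ROI; returns the residual time series.
#' Collinear regressors are dropped (with a warning) rather than failing.
#'
#' @param ts T x R matrix of ROI time series.
#' @param nuisance T x K regressor matrix (see [build_nuisance()]).
#' @export
denoise <- function(ts, nuisance) {
  ts <- as.matrix(ts); X <- as.matrix(nuisance)
  if (nrow(ts) != nrow(X)) stop("time dimension mismatch")
  if (nrow(X) <= ncol(X)) stop("need T > number of regressors")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[-seq_len(qrX$rank)]
    warning("dropping ", length(drop), " collinear nuisance column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
    qrX <- qr(X)
  }
  res <- qr.resid(qrX, ts)
  dimnames(res) <- dimnames(ts)
  res
}

#' Ideal discrete-frequency band-pass filter
#'
#' FFT-based: spectral bins whose frequency lies in `[low, high]` (inclusive)
#' are retained, all others -- including DC -- are zeroed; the output is
#' real-valued.  Exact on-bin sinusoids pass (or vanish) exactly, which makes
#' the filter behavior directly testable.
#'
#' @param ts T x R matrix (or vector) of time series.
#' @param tr repetition time in seconds.
#' @param low,high band edges in Hz (defaults 0.01 and 0.1).
#' @export
bandpass <- function(ts, tr, low = 0.01, high = 0.1) {
  ts <- as.matrix(ts)
  T <- nrow(ts)
  nyq <- 1 / (2 * tr)
  if (!(low >= 0 && low < high)) stop("need 0 <= low < high")
  if (high > nyq + 1e-12) stop("band exceeds Nyquist (", nyq, " Hz)")
  freq <- (seq_len(T) - 1) / (T * tr)
  fold <- pmin(freq, 1 / tr - freq)   # two-sided spectrum, folded
  keep <- fold >= low - 1e-12 & fold <= high + 1e-12
  ft <- stats::mvfft(ts)
  ft[!keep, ] <- 0
  out <- Re(stats::mvfft(ft, inverse = TRUE)) / T
  dimnames(out) <- dimnames(ts)
  out
}

#' Extract spherical-ROI time series from a 4D volume
#'
#' For each ROI, averages the time series of in-mask voxels whose world-space
#' center lies within `radius` mm (Euclidean) of the ROI's MNI coordinate.
#' No partial-volume weighting.
#'
#' @param volume 4D array or RNifti image; `affine` maps 0-based voxel
#'   indices to world mm (taken from the image if available).
#' @param roi_set an [roi_set()].
#' @param mask 3D array (nonzero = in brain).
#' @param affine 4 x 4 voxel-to-world matrix, required for plain arrays.
#' @return T x R matrix with ROI names as columns.
#' @export
extract_roi_timeseries <- function(volume, roi_set, mask, affine = NULL) {
  if (is.null(affine)) {
    affine <- tryCatch(structure(RNifti::xform(volume), class = NULL),
                       error = function(e) NULL)
    if (is.null(affine)) stop("affine required for plain arrays")
  }
  affine <- unclass(affine)
  vol <- as.array(volume)
  if (length(dim(vol)) != 4) stop("volume must be 4D")
  d <- dim(vol)
  mask <- as.array(mask)
  if (!all(dim(mask) == d[1:3])) stop("mask not aligned with volume")
  if (abs(det(affine)) < 1e-12) stop("affine not invertible")

  idx <- which(mask != 0, arr.ind = TRUE) - 1  # 0-based voxel indices
  world <- cbind(idx, 1) %*% t(affine)         # world coords of voxel centers
  world <- world[, 1:3, drop = FALSE]

  Tn <- d[4]
  out <- matrix(NA_real_, Tn, nrow(roi_set$roi))
  colnames(out) <- roi_set$roi$name
  tsmat <- matrix(vol, prod(d[1:3]), Tn)
  lin <- (idx[, 1] + 1) + idx[, 2] * d[1] + idx[, 3] * d[1] * d[2]
  for (j in seq_len(nrow(roi_set$roi))) {
    cen <- as.numeric(roi_set$roi[j, c("x", "y", "z")])
    dist2 <- rowSums(sweep(world, 2, cen)^2)
    sel <- dist2 <= roi_set$roi$radius[j]^2
    if (!any(sel)) stop("empty ROI: ", roi_set$roi$name[j])
    out[, j] <- colMeans(tsmat[lin[sel], , drop = FALSE])
  }
  out
}

#' Seed-based Fisher-z connectivity for one subject
#'
#' Pearson correlation between each seed's time course and every other
#' node's, Fisher z-transformed.  Correlations are clipped to
#' +/- (1 - 1e-7) before `atanh` so perfect correlations stay finite.
#'
#' @param ts T x R matrix with ROI names as columns.
#' @param roi_set an [roi_set()]; its edge list defines the feature order.
#' @return named vector of Fisher-z values (one per edge) with the per-edge
#'   group tags in `attr(, "group")`.
#' @export
seed_fc <- function(ts, roi_set) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 8) stop("need at least 8 time points")
  need <- unique(c(roi_set$edges$seed, roi_set$edges$target))
  if (!all(need %in% colnames(ts))) {
    stop("time-series columns do not match ROI names: missing ",
         paste(setdiff(need, colnames(ts)), collapse = ", "))
  }
  sds <- apply(ts[, need, drop = FALSE], 2, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate ROI signal: ", paste(need[sds == 0], collapse = ", "))
  }
  rmax <- 1 - 1e-7
  z <- vapply(seq_len(nrow(roi_set$edges)), function(e) {
    r <- stats::cor(ts[, roi_set$edges$seed[e]], ts[, roi_set$edges$target[e]])
    atanh(min(rmax, max(-rmax, r)))
  }, numeric(1))
  names(z) <- roi_set$edges$label
  attr(z, "group") <- roi_set$edges$group
  z
}

#' Denoise, band-pass and correlate a whole cohort
#'
#' Fixed pipeline order per subject: nuisance regression, then band-pass of
#' the residuals, then seed connectivity.
#'
#' @param ts_list list of T x R ROI time-series matrices (one per subject).
#' @param roi_set an [roi_set()].
#' @param nuisance_list optional list of nuisance matrices; when NULL the
#'   denoising step is skipped (already-clean input).
#' @param tr repetition time (s); `low`, `high`: band in Hz.
#' @return `fc_features`: subjects x edges matrix of Fisher-z values with
#'   edge metadata attributes.
#' @export
fc_features <- function(ts_list, roi_set, nuisance_list = NULL,
                        tr = 2, low = 0.01, high = 0.1) {
  rows <- lapply(seq_along(ts_list), function(i) {
    ts <- ts_list[[i]]
    if (!is.null(nuisance_list)) ts <- denoise(ts, nuisance_list[[i]])
    ts <- bandpass(ts, tr = tr, low = low, high = high)
    seed_fc(ts, roi_set)
  })
  fc <- do.call(rbind, rows)
  rownames(fc) <- names(ts_list) %||% paste0("sub", seq_along(ts_list))
  structure(fc, group = roi_set$edges$group, class = "fc_features")
}

#' @export
print.fc_features <- function(x, ...) {
  cat("Fisher-z seed connectivity:", nrow(x), "subjects x", ncol(x), "edges\n")
  tab <- table(attr(x, "group"))
  cat(paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  invisible(x)
}
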