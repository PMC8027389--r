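#' Canonical upper-triangle edge index
#'
#' Row-major enumeration of the upper triangle: (1,2), (1,3), ...,
#' (1,R), (2,3), ... 1-based ROI indices, i < j. This ordering is the
#' feature-space contract shared by vectorization, the classifier and the
#' reliability map.
#'
#' @param n_rois number of ROIs.
#' @return data.frame with columns `edge` (1..R(R-1)/2), `i`, `j`.
#' @export
edge_index_table <- function(n_rois) {
  i <- rep(seq_len(n_rois - 1), times = (n_rois - 1):1)
  j <- unlist(lapply(seq_len(n_rois - 1), function(k) (k + 1):n_rois))
  data.frame(edge = seq_along(i), i = i, j = j)
}

#' Expand a 6-parameter motion trace to Friston-24 regressors
#'
#' Columns ordered as the 6 rigid-body parameters, their squares, their
#' one-frame lags, and the squared lags; lagged rows at the first timepoint
#' are zeros.
#'
#' @param motion T x 6 matrix (3 translations mm, 3 rotations rad).
#' @return T x 24 regressor matrix.
#' @export
friston24_expand <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion trace must have 6 columns")
  if (nrow(motion) < 2) stop("motion trace must have at least 2 rows")
  lag <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, motion^2, lag, lag^2)
  colnames(out) <- c(paste0("m", 1:6), paste0("m", 1:6, "_sq"),
                     paste0("m", 1:6, "_lag"), paste0("m", 1:6, "_lagsq"))
  out
}

#' Framewise displacement and motion-based inclusion
#'
#' Power-style FD: per frame, the sum of absolute backward differences of
#' the translations plus `head_radius_mm` times the sum of absolute rotation
#' differences (rotations in radians converted to arc length at the head
#' radius). FD at the first frame is 0. A scan is included when mean FD is
#' below the threshold.
#'
#' @param motion T x 6 matrix.
#' @param head_radius_mm rotation-to-displacement radius (default 50 mm).
#' @param fd_threshold_mm mean-FD inclusion threshold (default 0.5 mm).
#' @return list with `fd` (length T), `mean_fd`, `max_fd`, `included`.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50,
                                   fd_threshold_mm = 0.5) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2) stop("motion trace must have at least 2 rows")
  if (!all(is.finite(motion))) stop("non-finite motion values")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  list(fd = fd, mean_fd = mean(fd), max_fd = max(fd),
       included = mean(fd) < fd_threshold_mm)
}

#' Zero-phase temporal band-pass filter
#'
#' Fourth-order Butterworth band-pass applied forward-backward
#' (zero phase) to every column. Removes the DC component, so output
#' columns have mean approximately zero.
#'
#' @param values T x R numeric matrix.
#' @param tr_seconds repetition time (s).
#' @param low_hz,high_hz passband edges (default 0.01-0.08 Hz).
#' @return filtered matrix of the same shape.
#' @export
bandpass_filter <- function(values, tr_seconds, low_hz = 0.01,
                            high_hz = 0.08) {
  values <- as.matrix(values)
  nyquist <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz))
    stop("require 0 < low_hz < high_hz")
  if (high_hz >= nyquist)
    stop(sprintf("high cutoff %.3f Hz is at or above Nyquist %.3f Hz",
                 high_hz, nyquist))
  if (nrow(values) < 32) stop("too few timepoints for a stable band-pass")
  bf <- signal::butter(4, c(low_hz, high_hz) / nyquist, type = "pass")
  # demean first: the filter's DC gain is zero but its startup transients
  # at these low cutoffs would otherwise leak large offsets into the output
  values <- sweep(values, 2, colMeans(values))
  apply(values, 2, function(col) signal::filtfilt(bf, col))
}

#' Regress nuisance signals out of a time series
#'
#' Column-wise least-squares residualization against the given regressors
#' plus an internally added intercept. Rank-deficient designs are handled by
#' pivoted QR (collinear directions dropped) with a warning.
#'
#' @param values T x R matrix.
#' @param regressors T x K matrix of nuisance signals.
#' @return residual matrix, orthogonal to the regressors.
#' @export
regress_nuisance <- function(values, regressors) {
  values <- as.matrix(values); regressors <- as.matrix(regressors)
  stopifnot(nrow(values) == nrow(regressors))
  if (ncol(regressors) + 1 >= nrow(values))
    stop("more regressors than timepoints")
  X <- cbind(1, regressors)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    warning(sprintf("nuisance design rank-deficient (%d of %d); collinear columns dropped",
                    qx$rank, ncol(X)))
  qr.resid(qx, values)
}

#' Median-filter spike attenuation stub
#'
#' Optional running-median (window `k`) attenuation of transient spikes,
#' occupying the despiking slot of the preprocessing chain. Off by default;
#' it is a simple robust smoother, not a wavelet despiker.
#'
#' @param values T x R matrix.
#' @param k odd window length.
#' @export
despike_median <- function(values, k = 5) {
  apply(as.matrix(values), 2, function(col) stats::runmed(col, k))
}

#' ROI-pairwise Pearson correlation matrix
#'
#' Zero-variance columns are flagged and carried as missing rows/columns
#' (attribute `zero_variance`) rather than producing silent NaN; downstream
#' zero-variance pruning removes the corresponding edges.
#'
#' @param values T x R matrix, T >= 3.
#' @return R x R symmetric matrix, unit diagonal on valid ROIs, with
#'   attribute `zero_variance` (logical per ROI).
#' @export
correlation_matrix <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 3) stop("need at least 3 timepoints for correlation")
  sds <- apply(values, 2, stats::sd)
  zv <- !is.finite(sds) | sds < 1e-12
  n_rois <- ncol(values)
  out <- matrix(NA_real_, n_rois, n_rois)
  if (any(!zv)) {
    out[!zv, !zv] <- stats::cor(values[, !zv, drop = FALSE])
    diag(out)[!zv] <- 1
  }
  attr(out, "zero_variance") <- zv
  out
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Returns the length R(R-1)/2 feature vector in the canonical row-major
#' edge order of [edge_index_table()].
#'
#' @param mat square symmetric matrix.
#' @return numeric vector with attribute `n_rois`.
#' @export
vectorize_upper <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("input must be square")
  v <- t(mat)[lower.tri(mat)]
  attr(v, "n_rois") <- nrow(mat)
  v
}

#' Rebuild a symmetric matrix from an upper-triangle vector
#'
#' Inverse of [vectorize_upper()]; the diagonal is set to 1.
#'
#' @param v edge vector of length R(R-1)/2.
#' @export
devectorize_upper <- function(v) {
  p <- length(v)
  n_rois <- (1 + sqrt(1 + 8 * p)) / 2
  if (n_rois != round(n_rois)) stop("length is not R(R-1)/2 for integer R")
  m <- matrix(0, n_rois, n_rois)
  m[lower.tri(m)] <- v      # fills column-major lower = row-major upper
  m <- t(m)
  m <- m + t(m)
  diag(m) <- 1
  m
}

#' Preprocess one scan into a connectivity feature vector
#'
#' Fixed pipeline: optional despike stub, zero-phase band-pass of the time
#' series, nuisance regression against identically band-passed Friston-24
#' motion regressors plus WM/CSF traces, Pearson correlation and
#' upper-triangle vectorization. Motion QC (framewise displacement) is
#' computed on the raw trace. The applied stage order is recorded in the
#' result.
#'
#' @param scan a `sim_scan` or any list with `timeseries`, `motion`,
#'   `nuisance`, `tr_seconds`, `subject_id`, `session`.
#' @param low_hz,high_hz band-pass edges.
#' @param fd_threshold_mm mean-FD inclusion threshold.
#' @param head_radius_mm FD rotation radius.
#' @param despike logical; apply the median-filter stub.
#' @return list of class `connectivity_vector`: `subject_id`, `session`,
#'   `values` (length R(R-1)/2, NA on zero-variance edges), `edge_index`,
#'   `qc` (mean/max FD, included flag, zero-variance ROI count), `pipeline`.
#' @export
preprocess_scan <- function(scan, low_hz = 0.01, high_hz = 0.08,
                            fd_threshold_mm = 0.5, head_radius_mm = 50,
                            despike = FALSE) {
  ts <- scan$timeseries
  stopifnot(!anyNA(ts))
  stages <- character(0)
  if (despike) {
    ts <- despike_median(ts)
    stages <- c(stages, "despike_median")
  }
  fdres <- framewise_displacement(scan$motion, head_radius_mm,
                                  fd_threshold_mm)
  regressors <- cbind(friston24_expand(scan$motion), scan$nuisance)
  ts_f <- bandpass_filter(ts, scan$tr_seconds, low_hz, high_hz)
  reg_f <- bandpass_filter(regressors, scan$tr_seconds, low_hz, high_hz)
  stages <- c(stages, "bandpass", "nuisance_regression_bandpassed")
  resid <- regress_nuisance(ts_f, reg_f)
  cm <- correlation_matrix(resid)
  stages <- c(stages, "pearson_correlation", "vectorize_upper")
  structure(list(
    subject_id = scan$subject_id, session = scan$session,
    values = vectorize_upper(cm),
    edge_index = edge_index_table(ncol(ts)),
    qc = list(mean_fd = fdres$mean_fd, max_fd = fdres$max_fd,
              included = fdres$included,
              n_zero_variance_rois = sum(attr(cm, "zero_variance"))),
    pipeline = stages
  ), class = "connectivity_vector")
}

#' Connectivity feature matrix for a list of scans
#'
#' Runs [preprocess_scan()] on each scan and stacks the edge vectors into a
#' subjects-by-edges matrix, alongside a QC table.
#'
#' @param scans list of scans.
#' @param ... passed to [preprocess_scan()].
#' @return list with `features` (n x R(R-1)/2 matrix, rownames
#'   `subject_id.session`), `qc` (data.frame), `edge_index`.
#' @export
cohort_connectivity <- function(scans, ...) {
  cvs <- lapply(scans, preprocess_scan, ...)
  features <- do.call(rbind, lapply(cvs, function(v) as.numeric(v$values)))
  rownames(features) <- vapply(cvs, function(v)
    paste(v$subject_id, v$session, sep = "."), "")
  qc <- do.call(rbind, lapply(cvs, function(v)
    data.frame(subject_id = v$subject_id, session = v$session,
               mean_fd = v$qc$mean_fd, max_fd = v$qc$max_fd,
               included = v$qc$included,
               n_zero_variance_rois = v$qc$n_zero_variance_rois)))
  list(features = features, qc = qc, edge_index = cvs[[1]]$edge_index)
}
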