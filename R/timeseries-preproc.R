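# Conditioning of ROI time series: volume discard, framewise displacement,
# spike detection, nuisance regression, band-pass filtering. The pipeline
# starts where ROI signals and realignment parameters already exist; no
# voxel-level operations are performed.

#' Discard initial volumes
#'
#' Removes the first `k` volumes of a time series (signal-equilibration
#' period), e.g. 180 volumes with `k = 10` leave 170.
#'
#' @param ts A [subject_timeseries()].
#' @param k Number of leading volumes to drop; must be < the volume count.
#' @return A [subject_timeseries()] with `k` fewer volumes.
#' @export
discard_initial_volumes <- function(ts, k = 10L) {
  stopifnot(inherits(ts, "subject_timeseries"))
  stop_if_not_scalar_count(k, "k", 0L)
  if (k >= n_volumes(ts)) {
    stop(sprintf("cannot discard %d of %d volumes", k, n_volumes(ts)),
         call. = FALSE)
  }
  if (k == 0L) return(ts)
  subject_timeseries(ts$values[, -seq_len(k), drop = FALSE], tr = ts$tr)
}

# Trim companion per-volume objects to match a discard.
discard_rows <- function(m, k) {
  if (k == 0L) return(m)
  m[-seq_len(k), , drop = FALSE]
}

#' Framewise displacement (FD)
#'
#' Power-style scalar head-motion index:
#' `fd[t] = sum |delta translation| + radius * sum |delta rotation|`,
#' with rotations converted to arc length at `rotation_radius_mm` (default
#' 50 mm). The first volume has no predecessor and is defined as 0.
#'
#' @param motion A [motion_trace()].
#' @param rotation_radius_mm Sphere radius for the rotation-to-mm
#'   conversion.
#' @return Numeric vector of per-volume FD values in mm (class `fd_series`).
#' @export
framewise_displacement <- function(motion, rotation_radius_mm = 50) {
  stopifnot(inherits(motion, "motion_trace"))
  if (anyNA(motion$translations) || any(!is.finite(motion$translations)) ||
      anyNA(motion$rotations) || any(!is.finite(motion$rotations))) {
    stop("motion parameters contain non-finite values", call. = FALSE)
  }
  if (nrow(motion$translations) < 2L) {
    stop("need at least 2 volumes to compute FD", call. = FALSE)
  }
  dt <- abs(diff(motion$translations))
  dr <- abs(diff(motion$rotations))
  fd <- c(0, rowSums(dt) + rotation_radius_mm * rowSums(dr))
  structure(fd, class = "fd_series")
}

#' Detect spike volumes
#'
#' Volumes whose FD strictly exceeds the threshold (default 0.5 mm) are
#' flagged for spike regression.
#'
#' @param fd An `fd_series` (or numeric vector of FD values).
#' @param threshold FD threshold in mm.
#' @return Integer vector of spike volume indices (possibly empty).
#' @export
detect_spike_volumes <- function(fd, threshold = 0.5) {
  fd <- as.numeric(fd)
  if (anyNA(fd) || any(fd < 0)) stop("invalid FD series", call. = FALSE)
  which(fd > threshold)
}

# Mean FD for QC reporting, excluding the undefined first volume.
mean_fd <- function(fd) mean(as.numeric(fd)[-1L])

#' Build the nuisance design matrix
#'
#' Columns: 6 motion parameters, their first differences (backward, leading
#' 0), global signal, white-matter signal, CSF signal, plus one one-hot
#' indicator column per spike volume — 15 continuous columns + spikes.
#'
#' @param motion A [motion_trace()].
#' @param global_sig,wm_sig,csf_sig Per-volume nuisance signal vectors.
#' @param spikes Integer vector of spike volume indices (may be empty).
#' @return Numeric matrix (volumes x regressors) with descriptive column
#'   names.
#' @export
build_nuisance_matrix <- function(motion, global_sig, wm_sig, csf_sig,
                                  spikes = integer(0)) {
  stopifnot(inherits(motion, "motion_trace"))
  mp <- cbind(motion$translations, motion$rotations)
  nv <- nrow(mp)
  if (length(global_sig) != nv || length(wm_sig) != nv ||
      length(csf_sig) != nv) {
    stop(sprintf("nuisance signal lengths (%d, %d, %d) do not match %d volumes",
                 length(global_sig), length(wm_sig), length(csf_sig), nv),
         call. = FALSE)
  }
  dmp <- rbind(0, diff(mp))
  colnames(dmp) <- paste0("d_", colnames(mp))
  x <- cbind(mp, dmp, global = as.numeric(global_sig),
             wm = as.numeric(wm_sig), csf = as.numeric(csf_sig))
  if (length(spikes)) {
    spikes <- sort(unique(as.integer(spikes)))
    if (any(spikes < 1L) || any(spikes > nv)) {
      stop("spike indices outside the volume range", call. = FALSE)
    }
    s <- matrix(0, nv, length(spikes))
    s[cbind(spikes, seq_along(spikes))] <- 1
    colnames(s) <- sprintf("spike_%03d", spikes)
    x <- cbind(x, s)
  }
  x
}

#' Regress nuisance covariates out of a time series
#'
#' Replaces each ROI series by its least-squares residual against the
#' nuisance columns plus an intercept. Exactly collinear columns are
#' dropped (with a warning naming them) before fitting, so residuals are
#' orthogonal to every retained regressor.
#'
#' @param ts A [subject_timeseries()].
#' @param nuisance Numeric matrix (volumes x regressors), e.g. from
#'   [build_nuisance_matrix()].
#' @return A [subject_timeseries()] of residuals.
#' @export
regress_nuisance <- function(ts, nuisance) {
  stopifnot(inherits(ts, "subject_timeseries"))
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != n_volumes(ts)) {
    stop(sprintf("nuisance matrix has %d rows but time series has %d volumes",
                 nrow(nuisance), n_volumes(ts)), call. = FALSE)
  }
  if (is.null(colnames(nuisance))) {
    colnames(nuisance) <- sprintf("x%d", seq_len(ncol(nuisance)))
  }
  x <- cbind(`(Intercept)` = 1, nuisance)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    warning(sprintf("dropping collinear nuisance column(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
    x <- x[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(x)
    if (qx$rank < ncol(x)) {
      stop(sprintf("nuisance design remains rank deficient after pruning (%s)",
                   paste(colnames(x), collapse = ", ")), call. = FALSE)
    }
  }
  resid <- t(qr.resid(qx, t(ts$values)))
  dimnames(resid) <- dimnames(ts$values)
  subject_timeseries(resid, tr = ts$tr)
}

#' Ideal band-pass filter
#'
#' Removes frequency components outside `[low, high]` Hz with a rectangular
#' mask on the discrete Fourier spectrum. The 0 Hz (mean) component is
#' always removed.
#'
#' @param ts A [subject_timeseries()].
#' @param low,high Band edges in Hz; requires `low < high < 1/(2 tr)`.
#' @return A filtered [subject_timeseries()].
#' @export
bandpass_filter <- function(ts, low = 0.01, high = 0.08) {
  stopifnot(inherits(ts, "subject_timeseries"))
  nyquist <- 1 / (2 * ts$tr)
  if (high <= low) stop("`high` must exceed `low`", call. = FALSE)
  if (high >= nyquist) {
    stop(sprintf("`high` (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 high, nyquist), call. = FALSE)
  }
  nv <- n_volumes(ts)
  k <- seq_len(nv) - 1L
  freq <- pmin(k, nv - k) / (nv * ts$tr)
  keep <- freq >= low & freq <= high & freq > 0
  filt <- t(apply(ts$values, 1L, function(x) {
    xf <- fft(x)
    xf[!keep] <- 0
    Re(fft(xf, inverse = TRUE)) / nv
  }))
  dimnames(filt) <- dimnames(ts$values)
  subject_timeseries(filt, tr = ts$tr)
}

#' Full preprocessing pipeline for one subject
#'
#' Fixed order: discard initial volumes, compute FD and detect spikes,
#' joint nuisance + spike regression, band-pass filter.
#'
#' @param ts A [subject_timeseries()] (pre-discard).
#' @param motion A [motion_trace()] covering the same volumes.
#' @param nuisance_signals Volumes x 3 matrix with columns global, wm, csf.
#' @param k Leading volumes to discard.
#' @param fd_threshold Spike threshold in mm.
#' @param band Length-2 numeric: band-pass edges in Hz.
#' @return List with the conditioned `timeseries`, `fd` series, `spikes`
#'   indices and QC summary `qc` (mean FD, spike count).
#' @export
preprocess_subject <- function(ts, motion, nuisance_signals, k = 10L,
                               fd_threshold = 0.5, band = c(0.01, 0.08)) {
  stopifnot(inherits(ts, "subject_timeseries"),
            inherits(motion, "motion_trace"))
  if (nrow(motion$translations) != n_volumes(ts)) {
    stop("motion trace and time series cover different numbers of volumes",
         call. = FALSE)
  }
  ts2 <- discard_initial_volumes(ts, k)
  motion2 <- motion_trace(discard_rows(motion$translations, k),
                          discard_rows(motion$rotations, k))
  nuis2 <- discard_rows(as.matrix(nuisance_signals), k)
  fd <- framewise_displacement(motion2)
  spikes <- detect_spike_volumes(fd, fd_threshold)
  design <- build_nuisance_matrix(motion2, nuis2[, 1L], nuis2[, 2L],
                                  nuis2[, 3L], spikes)
  clean <- regress_nuisance(ts2, design)
  filtered <- bandpass_filter(clean, band[1L], band[2L])
  list(timeseries = filtered, fd = fd, spikes = spikes,
       qc = c(mean_fd = mean_fd(fd), n_spikes = length(spikes)))
}
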