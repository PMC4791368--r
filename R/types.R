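#' Subject ROI time-series container
#'
#' Holds one subject's region-of-interest (ROI) signal matrix together with
#' the sampling interval. Rows are ROIs, columns are volumes (time points).
#'
#' @param values Numeric matrix, ROIs in rows, volumes in columns. Must be
#'   finite with at least 2 volumes.
#' @param tr Repetition time (sampling interval) in seconds; must be > 0.
#' @return An object of class `subject_timeseries` with elements `values`
#'   and `tr`.
#' @export
subject_timeseries <- function(values, tr) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (ROIs x volumes)", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("time series contains missing or non-finite values", call. = FALSE)
  }
  if (ncol(values) < 2L) stop("need at least 2 volumes", call. = FALSE)
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0) {
    stop("`tr` must be a single positive number (seconds)", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("ROI%03d", seq_len(nrow(values)))
  }
  structure(list(values = values, tr = as.numeric(tr)),
            class = "subject_timeseries")
}

#' @export
print.subject_timeseries <- function(x, ...) {
  cat(sprintf("<subject_timeseries> %d ROIs x %d volumes, TR = %g s\n",
              nrow(x$values), ncol(x$values), x$tr))
  invisible(x)
}

n_volumes <- function(ts) ncol(ts$values)

#' Rigid-body motion trace
#'
#' Per-volume head-motion parameters: three translations (mm) and three
#' rotations (radians), as produced by fMRI realignment.
#'
#' @param translations Numeric matrix, volumes x 3, in mm.
#' @param rotations Numeric matrix, volumes x 3, in radians.
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(translations, rotations) {
  translations <- as.matrix(translations)
  rotations <- as.matrix(rotations)
  if (ncol(translations) != 3L || ncol(rotations) != 3L) {
    stop("translations and rotations must each have 3 columns", call. = FALSE)
  }
  if (nrow(translations) != nrow(rotations)) {
    stop("translations and rotations must cover the same volumes",
         call. = FALSE)
  }
  colnames(translations) <- c("trans_x", "trans_y", "trans_z")
  colnames(rotations) <- c("rot_x", "rot_y", "rot_z")
  structure(list(translations = translations, rotations = rotations),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d volumes\n", nrow(x$translations)))
  invisible(x)
}

#' Undirected weighted graph over labeled brain regions
#'
#' The common currency of both pipeline arms: a symmetric non-negative
#' weight matrix with zero diagonal; `weights[i, j] > 0` iff the edge is
#' present.
#'
#' @param weights Symmetric non-negative numeric matrix with zero diagonal.
#' @param modality `"functional"` or `"structural"`.
#' @param nodes Optional character vector of node labels (defaults to the
#'   matrix dimnames or ROI labels).
#' @return An object of class `weighted_graph`.
#' @export
weighted_graph <- function(weights, modality = c("functional", "structural"),
                           nodes = NULL) {
  modality <- match.arg(modality)
  if (!is_square_numeric(weights)) {
    stop("`weights` must be a square numeric matrix", call. = FALSE)
  }
  if (anyNA(weights) || any(!is.finite(weights))) {
    stop("weights contain missing or non-finite values", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (max(abs(weights - t(weights))) > 1e-10) {
    stop("weight matrix must be symmetric", call. = FALSE)
  }
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) {
    stop("self-loops are not allowed (diagonal must be zero)", call. = FALSE)
  }
  if (is.null(nodes)) {
    nodes <- rownames(weights)
    if (is.null(nodes)) nodes <- sprintf("ROI%03d", seq_len(nrow(weights)))
  }
  dimnames(weights) <- list(nodes, nodes)
  structure(list(weights = weights, nodes = nodes, modality = modality),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  e <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<weighted_graph> %s, %d nodes, %d edges\n",
              x$modality, length(x$nodes), e))
  invisible(x)
}

n_edges <- function(g) sum(g$weights[upper.tri(g$weights)] > 0)

graph_degrees <- function(g) rowSums(g$weights > 0)
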