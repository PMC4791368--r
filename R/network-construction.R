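# Network construction: Pearson correlation matrices with significance
# levels for the functional arm; fiber-count thresholding for the
# structural arm.

#' Pairwise Pearson correlation matrix with significance levels
#'
#' Computes all ROI-pair Pearson correlations and their two-tailed
#' p-values from the t distribution with `n - 2` degrees of freedom.
#'
#' @param ts A [subject_timeseries()] with at least 3 volumes.
#' @return An object of class `correlation_matrix` with elements `r`
#'   (correlations), `p` (two-tailed p-values) and `n_samples`.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "subject_timeseries"))
  nv <- n_volumes(ts)
  if (nv < 3L) stop("need at least 3 volumes for correlation", call. = FALSE)
  sds <- apply(ts$values, 1L, sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance ROI(s): %s",
                 paste(rownames(ts$values)[sds == 0], collapse = ", ")),
         call. = FALSE)
  }
  r <- cor(t(ts$values))
  df <- nv - 2L
  r_clip <- pmin(pmax(r, -1), 1)
  tstat <- r_clip * sqrt(df / pmax(1 - r_clip^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  p[abs(r_clip) >= 1] <- 0
  diag(p) <- 0
  structure(list(r = r, p = p, n_samples = nv),
            class = "correlation_matrix")
}

#' Significance threshold scheme
#'
#' @param alpha Significance level in (0, 1).
#' @param correction `"bonferroni"` (divide `alpha` by `n_tests`) or
#'   `"none"`.
#' @param n_tests Number of unique ROI pairs tested (default
#'   `90 * 89 / 2 = 4005`).
#' @return A `threshold_scheme` list.
#' @export
threshold_scheme <- function(alpha = 0.05,
                             correction = c("bonferroni", "none"),
                             n_tests = 4005L) {
  correction <- match.arg(correction)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)",
                                     call. = FALSE)
  stop_if_not_scalar_count(n_tests, "n_tests", 1L)
  structure(list(alpha = alpha, correction = correction,
                 n_tests = as.integer(n_tests)),
            class = "threshold_scheme")
}

scheme_label <- function(scheme) {
  sprintf("p%g_%s", scheme$alpha, scheme$correction)
}

effective_alpha <- function(scheme) {
  if (scheme$correction == "bonferroni") scheme$alpha / scheme$n_tests
  else scheme$alpha
}

#' Build a functional weighted network by significance thresholding
#'
#' An edge is retained with weight `r[i, j]` iff the correlation is
#' positive and its p-value falls below the scheme's effective threshold.
#' Negative correlations are excluded regardless of significance. The
#' conventional schemes are P < 0.05 Bonferroni (default), P < 0.001
#' uncorrected, and P < 0.01 Bonferroni.
#'
#' @param corr A [correlation_matrix()].
#' @param scheme A [threshold_scheme()].
#' @return A [weighted_graph()] with modality `"functional"`.
#' @export
threshold_functional <- function(corr, scheme = threshold_scheme()) {
  stopifnot(inherits(corr, "correlation_matrix"),
            inherits(scheme, "threshold_scheme"))
  keep <- corr$r > 0 & corr$p < effective_alpha(scheme)
  w <- ifelse(keep, corr$r, 0)
  diag(w) <- 0
  weighted_graph(w, modality = "functional")
}

#' Build a structural weighted network by fiber-count thresholding
#'
#' An edge is retained with weight `fn[i, j]` iff at least `min_fibers`
#' fibers connect the two regions (default 3).
#'
#' @param fnm Symmetric non-negative integer matrix of fiber counts with
#'   zero diagonal.
#' @param min_fibers Minimum fiber count for an edge.
#' @return A [weighted_graph()] with modality `"structural"`.
#' @export
threshold_structural <- function(fnm, min_fibers = 3L) {
  fnm <- as.matrix(fnm)
  if (!is_square_numeric(fnm)) {
    stop("`fnm` must be a square numeric matrix", call. = FALSE)
  }
  if (any(fnm < 0) || any(fnm != round(fnm))) {
    stop("fiber counts must be non-negative integers", call. = FALSE)
  }
  if (any(diag(fnm) != 0)) stop("fiber-count diagonal must be zero",
                                call. = FALSE)
  if (max(abs(fnm - t(fnm))) > 0) {
    stop("fiber-count matrix must be symmetric", call. = FALSE)
  }
  stop_if_not_scalar_count(min_fibers, "min_fibers", 0L)
  w <- ifelse(fnm >= min_fibers, fnm, 0)
  weighted_graph(w, modality = "structural")
}
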