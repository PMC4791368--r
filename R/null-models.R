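# Degree-preserving null ensembles and null-normalized metrics. The null
# model matches node count, edge count and degree sequence by repeated
# double-edge swaps; weights travel with their edges, so the edge-weight
# multiset (and hence the maximum weight used for normalization) is
# preserved exactly.

#' Degree-preserving rewiring of a weighted graph
#'
#' Repeated double-edge swaps (rejecting swaps that would create
#' self-loops or multi-edges); `swaps_per_edge * |E|` swaps are attempted.
#' Weights ride along with their edges, so node count, edge count, degree
#' sequence and the edge-weight multiset are all preserved exactly.
#'
#' @param g A [weighted_graph()] with at least 2 edges.
#' @param swaps_per_edge Attempted swaps per edge (burn-in length).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return A rewired [weighted_graph()]. Graphs where no valid swap exists
#'   are returned unchanged with a warning.
#' @export
rewire_preserving_degrees <- function(g, swaps_per_edge = 10L, seed = NULL) {
  stopifnot(inherits(g, "weighted_graph"))
  stop_if_not_scalar_count(swaps_per_edge, "swaps_per_edge", 1L)
  w <- g$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  e <- nrow(idx)
  if (e < 2L) {
    warning("graph has fewer than 2 edges; returned unchanged",
            call. = FALSE)
    return(g)
  }
  wts <- w[idx]
  run <- function() {
    double_edge_swap(idx[, 1L] - 1L, idx[, 2L] - 1L, nrow(w),
                     as.integer(swaps_per_edge) * e)
  }
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  if (res$accepted == 0L) {
    warning("no valid degree-preserving swap exists; returned unchanged",
            call. = FALSE)
    return(g)
  }
  w2 <- matrix(0, nrow(w), ncol(w))
  ii <- res$i + 1L
  jj <- res$j + 1L
  w2[cbind(ii, jj)] <- wts
  w2[cbind(jj, ii)] <- wts
  weighted_graph(w2, modality = g$modality, nodes = g$nodes)
}

#' Null ensemble specification
#'
#' @param n_null Number of matched random networks (default 1000).
#' @param swaps_per_edge Attempted swaps per edge per null network.
#' @param seed Integer seed for the ensemble.
#' @return A `null_ensemble_spec` list.
#' @export
null_ensemble_spec <- function(n_null = 1000L, swaps_per_edge = 10L,
                               seed = 1L) {
  stop_if_not_scalar_count(n_null, "n_null", 1L)
  stop_if_not_scalar_count(swaps_per_edge, "swaps_per_edge", 1L)
  structure(list(n_null = as.integer(n_null),
                 swaps_per_edge = as.integer(swaps_per_edge),
                 seed = as.integer(seed)),
            class = "null_ensemble_spec")
}

#' Null-normalized small-world and efficiency metrics
#'
#' Scales the raw metrics of a graph against the means of a
#' degree-preserving null ensemble: `gamma = Cp / <Cp_null>`,
#' `lambda = Lp / <Lp_null>`, small-worldness `sigma = gamma / lambda`,
#' and normalized efficiencies `neg`, `neloc` defined analogously.
#' Deterministic given the ensemble seed.
#'
#' @param g A [weighted_graph()] whose largest component has >= 2 nodes.
#' @param spec A [null_ensemble_spec()].
#' @param keep_samples If `TRUE`, the per-null metric samples are attached
#'   for audit.
#' @return A list of class `normalized_metrics` with elements `gamma`,
#'   `lambda`, `sigma`, `neg`, `neloc`, the raw metrics `raw`, the null
#'   means/SDs, and (optionally) `samples`.
#' @export
normalized_metrics <- function(g, spec = null_ensemble_spec(),
                               keep_samples = FALSE) {
  stopifnot(inherits(g, "weighted_graph"),
            inherits(spec, "null_ensemble_spec"))
  raw <- global_metrics(g)
  if (is.na(raw[["lp"]])) {
    stop("largest component has fewer than 2 nodes; cannot normalize",
         call. = FALSE)
  }
  seeds <- spawn_seeds(spec$seed, spec$n_null)
  samples <- matrix(NA_real_, spec$n_null, 4L,
                    dimnames = list(NULL, c("cp", "lp", "eg", "eloc")))
  for (b in seq_len(spec$n_null)) {
    gb <- rewire_preserving_degrees(g, spec$swaps_per_edge, seeds[b])
    samples[b, ] <- global_metrics(gb)
  }
  null_mean <- colMeans(samples)
  null_sd <- apply(samples, 2L, sd)
  zero <- names(null_mean)[null_mean == 0 | is.na(null_mean)]
  if (length(zero)) {
    stop(sprintf("null-ensemble mean of %s is zero or undefined",
                 paste(zero, collapse = ", ")), call. = FALSE)
  }
  gamma <- raw[["cp"]] / null_mean[["cp"]]
  lambda <- raw[["lp"]] / null_mean[["lp"]]
  out <- list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
              neg = raw[["eg"]] / null_mean[["eg"]],
              neloc = raw[["eloc"]] / null_mean[["eloc"]],
              raw = raw, null_mean = null_mean, null_sd = null_sd,
              n_null = spec$n_null)
  if (keep_samples) out$samples <- samples
  structure(out, class = "normalized_metrics")
}

#' @export
print.normalized_metrics <- function(x, ...) {
  cat(sprintf(paste0("<normalized_metrics> gamma = %.3f, lambda = %.3f, ",
                     "sigma = %.3f, nEg = %.3f, nEloc = %.3f (n_null = %d)\n"),
              x$gamma, x$lambda, x$sigma, x$neg, x$neloc, x$n_null))
  invisible(x)
}
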