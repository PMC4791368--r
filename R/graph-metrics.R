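# Global topology metrics on weighted undirected graphs. Weights are
# max-normalized internally (w / max(w)), shortest-path edge lengths are
# 1 / normalized weight, so all metrics are invariant to a global rescaling
# of the weights.

normalize_weights <- function(g) {
  m <- max(g$weights)
  if (m <= 0) return(g$weights)
  g$weights / m
}

length_matrix <- function(wn) {
  len <- ifelse(wn > 0, 1 / wn, Inf)
  diag(len) <- 0
  len
}

graph_distances <- function(g) {
  fw_distances(length_matrix(normalize_weights(g)))
}

component_membership <- function(g) {
  reach <- is.finite(graph_distances(g))
  comp <- integer(nrow(reach))
  cid <- 0L
  for (i in seq_along(comp)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

#' Weighted clustering coefficient
#'
#' Geometric-mean (Onnela-type) weighted clustering on max-normalized
#' weights:
#' `C_i = 1 / (k_i (k_i - 1)) * sum_{j != h} (w_ij w_ih w_jh)^(1/3)`.
#' Nodes with fewer than 2 neighbors contribute 0; `cp` is the unweighted
#' mean over all nodes (isolates included).
#'
#' @param g A [weighted_graph()].
#' @return List with `per_node` values and the mean `cp`.
#' @export
clustering_coefficient <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  if (n_edges(g) == 0L) {
    warning("graph has no edges; clustering coefficient is 0", call. = FALSE)
    per_node <- rep(0, length(g$nodes))
    names(per_node) <- g$nodes
    return(list(per_node = per_node, cp = 0))
  }
  per_node <- onnela_clustering(normalize_weights(g))
  names(per_node) <- g$nodes
  list(per_node = per_node, cp = mean(per_node))
}

#' Characteristic path length
#'
#' Mean shortest-path distance over ordered node pairs within the largest
#' connected component, with edge lengths equal to the reciprocal of the
#' max-normalized weight.
#'
#' @param g A [weighted_graph()].
#' @return The characteristic path length `lp` (scalar, >= 1).
#' @export
characteristic_path_length <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  d <- graph_distances(g)
  comp <- component_membership(g)
  main <- which(comp == which.max(tabulate(comp)))
  if (length(main) < 2L) {
    stop("graph has no connected pair of nodes; Lp undefined", call. = FALSE)
  }
  dm <- d[main, main]
  mean(dm[row(dm) != col(dm)])
}

#' Global efficiency
#'
#' `Eg = 1 / (N (N - 1)) * sum_{i != j} 1 / d_ij` over all nodes, with
#' `1 / Inf = 0` for disconnected pairs.
#'
#' @param g A [weighted_graph()].
#' @return Global efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  d <- graph_distances(g)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- nrow(d)
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by
#' each node's neighbors (the node itself excluded); nodes with fewer than
#' 2 neighbors contribute 0.
#'
#' @param g A [weighted_graph()].
#' @return Local efficiency in `[0, 1]`.
#' @export
local_efficiency <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  local_efficiency_mean(normalize_weights(g))
}

#' All raw global metrics at once
#'
#' Computes `cp`, `lp`, `eg`, `eloc` sharing one distance computation.
#'
#' @param g A [weighted_graph()].
#' @return Named numeric vector `c(cp, lp, eg, eloc)`.
#' @export
global_metrics <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  wn <- normalize_weights(g)
  n <- nrow(wn)
  cp <- if (max(wn) <= 0) 0 else mean(onnela_clustering(wn))
  d <- fw_distances(length_matrix(wn))
  fin <- is.finite(d)
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[fin[i, ]] <- cid
    }
  }
  main <- which(comp == which.max(tabulate(comp)))
  lp <- if (length(main) < 2L) NA_real_ else {
    dm <- d[main, main]
    mean(dm[row(dm) != col(dm)])
  }
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  eg <- sum(inv) / (n * (n - 1))
  eloc <- local_efficiency_mean(wn)
  c(cp = cp, lp = lp, eg = eg, eloc = eloc)
}

#' Basic network properties
#'
#' Density (fraction of possible edges present), connectivity strength
#' (mean over nodes of summed un-normalized edge weights) and the node
#' count of the largest connected component.
#'
#' @param g A [weighted_graph()].
#' @return Named numeric vector `c(density, strength, largest_component)`.
#' @export
basic_properties <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  n <- length(g$nodes)
  e <- n_edges(g)
  comp <- component_membership(g)
  c(density = 2 * e / (n * (n - 1)),
    strength = mean(rowSums(g$weights)),
    largest_component = max(tabulate(comp)))
}
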