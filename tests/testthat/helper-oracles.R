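# Independent brute-force oracles for the graph metrics, used only in
# tests. All operate on a weight matrix `w` (symmetric, non-negative,
# zero diagonal) and apply the same definitions as the package: weights
# max-normalized, edge length = 1 / normalized weight.

bf_normalize <- function(w) {
  m <- max(w)
  if (m > 0) w / m else w
}

# Shortest path distances by exhaustive enumeration of simple paths
# (depth-first, pruned only on provably dominated prefixes). For n <= 7.
bf_distances <- function(w) {
  wn <- bf_normalize(w)
  len <- ifelse(wn > 0, 1 / wn, Inf)
  n <- nrow(len)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    visited <- rep(FALSE, n)
    walk <- function(v, dist) {
      if (dist > d[s, v]) return(invisible(NULL))
      d[s, v] <<- min(d[s, v], dist)
      visited[v] <<- TRUE
      for (u in seq_len(n)) {
        if (!visited[u] && is.finite(len[v, u])) {
          walk(u, dist + len[v, u])
        }
      }
      visited[v] <<- FALSE
      invisible(NULL)
    }
    walk(s, 0)
  }
  d
}

bf_lp <- function(w) {
  d <- bf_distances(w)
  # largest connected component
  n <- nrow(d)
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[is.finite(d[i, ])] <- cid
    }
  }
  main <- which(comp == which.max(tabulate(comp)))
  if (length(main) < 2L) return(NA_real_)
  dm <- d[main, main]
  mean(dm[row(dm) != col(dm)])
}

bf_eg <- function(w) {
  d <- bf_distances(w)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- nrow(d)
  sum(inv) / (n * (n - 1))
}

bf_eloc <- function(w) {
  wn <- bf_normalize(w)
  n <- nrow(wn)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(wn[i, ] > 0)
    if (length(nb) < 2L) return(0)
    sub <- wn[nb, nb, drop = FALSE]
    # efficiency of the induced subgraph, same normalized weights
    len <- ifelse(sub > 0, 1 / sub, Inf)
    diag(len) <- 0
    m <- nrow(len)
    d <- matrix(Inf, m, m)
    diag(d) <- 0
    for (s in seq_len(m)) {
      visited <- rep(FALSE, m)
      walk <- function(v, dist) {
        if (dist > d[s, v]) return(invisible(NULL))
        d[s, v] <<- min(d[s, v], dist)
        visited[v] <<- TRUE
        for (u in seq_len(m)) {
          if (!visited[u] && is.finite(len[v, u])) walk(u, dist + len[v, u])
        }
        visited[v] <<- FALSE
        invisible(NULL)
      }
      walk(s, 0)
    }
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    sum(inv) / (m * (m - 1))
  }, numeric(1))
  mean(vals)
}

# Direct triple-loop Onnela clustering.
bf_clustering <- function(w) {
  wn <- bf_normalize(w)
  n <- nrow(wn)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(wn[i, ] > 0)
    k <- length(nb)
    if (k < 2L) next
    s <- 0
    for (j in nb) for (h in nb) {
      if (j != h) s <- s + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
    }
    cc[i] <- s / (k * (k - 1))
  }
  mean(cc)
}

# Random connected-ish weighted graph for property tests.
random_weighted_graph <- function(n, p = 0.5, modality = "functional") {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on <- ut[runif(length(ut)) < p]
  w[on] <- runif(length(on), 0.1, 1)
  w <- w + t(w)
  weighted_graph(w, modality = modality)
}

# Unweighted ring lattice with k neighbors per side, plus random rewiring
# (small-world test bed).
ring_lattice_graph <- function(n = 90, k = 5, p_rewire = 0.1) {
  w <- matrix(0, n, n)
  for (i in seq_len(n)) for (s in seq_len(k)) {
    j <- ((i + s - 1L) %% n) + 1L
    w[i, j] <- w[j, i] <- 1
  }
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  for (e in seq_len(nrow(idx))) {
    if (runif(1) < p_rewire) {
      i <- idx[e, 1L]
      cand <- which(w[i, ] == 0 & seq_len(n) != i)
      if (length(cand)) {
        j_new <- cand[sample.int(length(cand), 1L)]
        w[idx[e, 1L], idx[e, 2L]] <- w[idx[e, 2L], idx[e, 1L]] <- 0
        w[i, j_new] <- w[j_new, i] <- 1
      }
    }
  }
  weighted_graph(w, modality = "structural")
}

tiny_spec <- function(...) {
  cohort_spec(group_sizes = c(AVH = 4L, nAVH = 4L, HC = 4L), ...)
}
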