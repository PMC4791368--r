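# Permutation-based group inference on network metrics and
# symptom-severity correlations.

one_way_f <- function(values, labels) {
  # closed-form one-way ANOVA F
  n <- length(values)
  k <- nlevels(labels)
  grand <- mean(values)
  ni <- tabulate(labels)
  gm <- tapply(values, labels, mean)
  ssb <- sum(ni * (gm - grand)^2)
  sst <- sum((values - grand)^2)
  ssw <- sst - ssb
  list(f = (ssb / (k - 1)) / (ssw / (n - k)), ssb = ssb, ssw = ssw,
       sst = sst)
}

check_groups <- function(values, labels, min_levels) {
  if (length(values) != length(labels)) {
    stop("`values` and `labels` must have the same length", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be finite", call. = FALSE)
  }
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != min_levels) {
    stop(sprintf("expected %d groups, found %d", min_levels,
                 nlevels(labels)), call. = FALSE)
  }
  if (any(tabulate(labels) < 2L)) {
    stop("every group needs at least 2 subjects", call. = FALSE)
  }
  labels
}

#' One-way permutation ANOVA
#'
#' Observed statistic is the classical one-way F (between-group mean
#' square over within-group mean square). Group labels are permuted
#' uniformly `n_perm` times and the p-value uses the add-one convention:
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`, guaranteeing
#' `p in (0, 1]`.
#'
#' @param values Numeric vector of per-subject metric values.
#' @param labels Three-group factor (or coercible).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return List of class `group_test` with `f_obs`, `p_perm`, `n_perm`,
#'   `seed`, and `degenerate` flag. Zero within-group variance gives a
#'   degenerate result: `p_perm = 1/(n_perm + 1)` if the groups differ,
#'   else 1.
#' @export
permutation_anova <- function(values, labels, n_perm = 10000L, seed = 1L) {
  labels <- check_groups(values, labels, 3L)
  stop_if_not_scalar_count(n_perm, "n_perm", 1L)
  n <- length(values)
  obs <- one_way_f(values, labels)
  eps <- .Machine$double.eps * max(obs$sst, 1)
  if (obs$ssw <= eps) {
    p <- if (obs$ssb > eps) 1 / (n_perm + 1) else 1
    return(structure(list(f_obs = if (obs$ssb > eps) Inf else 0,
                          p_perm = p, n_perm = as.integer(n_perm),
                          seed = as.integer(seed), degenerate = TRUE),
                     class = "group_test"))
  }
  k <- nlevels(labels)
  ni <- tabulate(labels)
  gmat <- outer(labels, levels(labels), "==") * 1  # n x k indicator
  grand_ss <- sum(values)^2 / n
  sst <- obs$sst
  f_perm <- with_seed(seed, {
    vperm <- vapply(seq_len(n_perm),
                    function(i) values[sample.int(n)], numeric(n))
    s <- crossprod(gmat, vperm)                     # k x n_perm group sums
    ssb <- colSums(s^2 / ni) - grand_ss
    (ssb / (k - 1)) / ((sst - ssb) / (n - k))
  })
  p <- (1 + sum(f_perm >= obs$f)) / (1 + n_perm)
  structure(list(f_obs = obs$f, p_perm = p, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), degenerate = FALSE),
            class = "group_test")
}

#' Pairwise permutation test on the mean difference
#'
#' Two-group permutation p-value for the absolute difference of means,
#' with the add-one convention.
#'
#' @param values Numeric vector.
#' @param labels Two-group factor (or coercible).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `delta_obs`, `p_perm`, `n_perm`, `seed`.
#' @export
permutation_pairwise <- function(values, labels, n_perm = 10000L,
                                 seed = 1L) {
  labels <- check_groups(values, labels, 2L)
  stop_if_not_scalar_count(n_perm, "n_perm", 1L)
  n <- length(values)
  in1 <- labels == levels(labels)[1L]
  n1 <- sum(in1)
  n2 <- n - n1
  total <- sum(values)
  delta_obs <- sum(values[in1]) / n1 - sum(values[!in1]) / n2
  d_perm <- with_seed(seed, {
    vperm <- vapply(seq_len(n_perm),
                    function(i) values[sample.int(n)], numeric(n))
    s1 <- colSums(vperm[in1, , drop = FALSE])
    s1 / n1 - (total - s1) / n2
  })
  p <- (1 + sum(abs(d_perm) >= abs(delta_obs))) / (1 + n_perm)
  list(delta_obs = delta_obs, p_perm = p, n_perm = as.integer(n_perm),
       seed = as.integer(seed))
}

#' Spearman rank correlation with large-sample p-value
#'
#' Pearson correlation of mid-ranks (ties averaged), with a two-tailed
#' p-value from the t approximation `t = rho * sqrt((n - 2)/(1 - rho^2))`.
#'
#' @param x,y Paired numeric vectors, `n >= 3`, finite.
#' @return List of class `correlation_result` with `rho`, `p`, `n`, and a
#'   `degenerate` flag (constant input leaves `rho` undefined).
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired",
                                   call. = FALSE)
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    stop("inputs must be finite", call. = FALSE)
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    return(structure(list(rho = NA_real_, p = NA_real_, n = n,
                          degenerate = TRUE), class = "correlation_result"))
  }
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), n - 2)
  }
  structure(list(rho = rho, p = p, n = n, degenerate = FALSE),
            class = "correlation_result")
}

#' Group comparison of every metric in a metric table
#'
#' Runs the three-group permutation ANOVA plus the three pairwise post-hoc
#' permutation tests (AVH vs HC, nAVH vs HC, AVH vs nAVH) on each metric
#' column, per modality and threshold scheme.
#'
#' @param metric_table A `data.table`/data.frame with columns
#'   `subject_id`, `group`, `modality`, `scheme` and metric columns.
#' @param metrics Character vector of metric column names to test.
#' @param n_perm Number of permutations per test.
#' @param seed Master seed; per-test seeds are derived from it.
#' @return A `data.table` with one row per metric x modality x scheme:
#'   `f_obs`, `p_perm` and the three pairwise p-values.
#' @export
group_differences <- function(metric_table,
                              metrics = c("cp", "lp", "eg", "eloc"),
                              n_perm = 10000L, seed = 1L) {
  dt <- as.data.table(metric_table)
  stopifnot(all(c("group", "modality", "scheme") %in% names(dt)))
  metrics <- intersect(metrics, names(dt))
  combos <- unique(dt[, .(modality, scheme)])
  pairs <- list(c("AVH", "HC"), c("nAVH", "HC"), c("AVH", "nAVH"))
  pair_names <- c("p_avh_hc", "p_navh_hc", "p_avh_navh")
  n_tests <- nrow(combos) * length(metrics)
  seeds <- spawn_seeds(seed, n_tests * 4L)
  out <- vector("list", n_tests)
  si <- 0L
  ti <- 0L
  for (ci in seq_len(nrow(combos))) {
    sub <- dt[combos[ci], on = c("modality", "scheme")]
    for (m in metrics) {
      ti <- ti + 1L
      v <- sub[[m]]
      ok <- is.finite(v)
      res <- permutation_anova(v[ok], sub$group[ok], n_perm,
                               seed = seeds[si + 1L])
      pw <- vapply(seq_along(pairs), function(pi) {
        sel <- ok & sub$group %in% pairs[[pi]]
        permutation_pairwise(v[sel], sub$group[sel], n_perm,
                             seed = seeds[si + 1L + pi])$p_perm
      }, numeric(1))
      si <- si + 4L
      row <- data.table(modality = combos$modality[ci],
                        scheme = combos$scheme[ci], metric = m,
                        f_obs = res$f_obs, p_perm = res$p_perm,
                        n_perm = as.integer(n_perm))
      row[, (pair_names) := as.list(pw)]
      out[[ti]] <- row
    }
  }
  rbindlist(out)
}

#' Metric-symptom correlations in the AVH group
#'
#' Spearman correlation between each metric column and the AHRS total
#' score, restricted to AVH subjects.
#'
#' @param metric_table Metric table including an `ahrs_total` column (NA
#'   outside the AVH group).
#' @param metrics Character vector of metric column names.
#' @return A `data.table` with `modality`, `scheme`, `metric`, `rho`, `p`,
#'   `n`.
#' @export
ahrs_correlations <- function(metric_table,
                              metrics = c("cp", "lp", "eg", "eloc")) {
  dt <- as.data.table(metric_table)
  stopifnot("ahrs_total" %in% names(dt))
  avh <- dt[group == "AVH" & is.finite(ahrs_total)]
  metrics <- intersect(metrics, names(dt))
  combos <- unique(avh[, .(modality, scheme)])
  out <- list()
  for (ci in seq_len(nrow(combos))) {
    sub <- avh[combos[ci], on = c("modality", "scheme")]
    for (m in metrics) {
      v <- sub[[m]]
      ok <- is.finite(v)
      res <- spearman_correlation(v[ok], sub$ahrs_total[ok])
      out[[length(out) + 1L]] <-
        data.table(modality = combos$modality[ci],
                   scheme = combos$scheme[ci], metric = m,
                   rho = res$rho, p = res$p, n = res$n)
    }
  }
  rbindlist(out)
}
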