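#' Specification of a synthetic three-group cohort
#'
#' Describes the study design the generator emulates: three groups (AVH,
#' nAVH, HC), an AAL-style 90-ROI parcellation with a modular community
#' structure, 180 volumes at TR = 2 s for the functional arm, and
#' overdispersed integer fiber-count matrices for the structural arm.
#' Group effects enter only through the named per-group parameters
#' (`rho_within`, `shortcut_density`); there are no hidden effects.
#'
#' @param n_rois Number of network nodes (ROIs); must be divisible by
#'   `n_modules`.
#' @param n_volumes Number of fMRI volumes per subject.
#' @param tr Repetition time in seconds.
#' @param group_sizes Named integer vector of subjects per group
#'   (`AVH`, `nAVH`, `HC`), each >= 2.
#' @param n_modules Number of signal modules (communities).
#' @param rho_within Baseline within-module signal correlation, one value
#'   per group (recycled if scalar); each in `[0, 1)` and above
#'   `rho_between`.
#' @param rho_between Between-module signal correlation in `[0, 1)`.
#' @param rho_homotopic Correlation of the homotopic (left-right homologue)
#'   ROI pairs nested inside each bilateral module; identical across
#'   groups, so these strong pairs anchor the top of every subject's
#'   weight distribution the way homotopic functional connections do in
#'   real connectomes. Must satisfy `rho_within <= rho_homotopic < 1`;
#'   set equal to `rho_within` to disable.
#' @param rho_subject_sd SD of the per-subject jitter added to the group's
#'   `rho_within` (between-subject heterogeneity; identical across groups).
#' @param fn_mean_within,fn_mean_between Expected fiber counts for
#'   within-module and between-module ROI pairs.
#' @param fn_dispersion Negative-binomial size (overdispersion) parameter
#'   for fiber counts; smaller values = more overdispersion.
#' @param shortcut_density Probability that a between-module pair carries a
#'   long-range structural shortcut, one value per group (recycled if
#'   scalar). Shortcuts are strong edges (mean `fn_mean_within`), so a
#'   lower density lengthens structural paths.
#' @param spike_rate Expected fraction of high-motion volumes.
#' @param ahrs_mean,ahrs_sd Mean and SD of the AHRS total-score
#'   distribution (truncated at 0) for the AVH group.
#' @param seed Master seed; all randomness is derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_rois = 90L, n_volumes = 180L, tr = 2,
                        group_sizes = c(AVH = 35L, nAVH = 41L, HC = 50L),
                        n_modules = 6L,
                        rho_within = c(AVH = 0.42, nAVH = 0.42, HC = 0.50),
                        rho_between = 0.20, rho_homotopic = 0.90,
                        rho_subject_sd = 0.025,
                        fn_mean_within = 25, fn_mean_between = 0.5,
                        fn_dispersion = 3,
                        shortcut_density = c(AVH = 0.02, nAVH = 0.05,
                                             HC = 0.05),
                        spike_rate = 0.02,
                        ahrs_mean = 23.9, ahrs_sd = 8.4, seed = 1L) {
  groups <- c("AVH", "nAVH", "HC")
  stop_if_not_scalar_count(n_rois, "n_rois", 2L)
  stop_if_not_scalar_count(n_volumes, "n_volumes", 2L)
  stop_if_not_scalar_count(n_modules, "n_modules", 1L)
  if (n_rois %% n_modules != 0) {
    stop("`n_rois` must be divisible by `n_modules`", call. = FALSE)
  }
  if (length(group_sizes) == 1L) group_sizes <- rep(group_sizes, 3L)
  if (length(group_sizes) != 3L || any(group_sizes < 2) ||
      any(group_sizes != round(group_sizes))) {
    stop("`group_sizes` must be three integers, each >= 2", call. = FALSE)
  }
  names(group_sizes) <- groups
  expand3 <- function(x, name) {
    if (length(x) == 1L) x <- rep(x, 3L)
    if (length(x) != 3L) {
      stop(sprintf("`%s` must have length 1 or 3", name), call. = FALSE)
    }
    names(x) <- groups
    x
  }
  rho_within <- expand3(rho_within, "rho_within")
  shortcut_density <- expand3(shortcut_density, "shortcut_density")
  if (!is.numeric(rho_between) || length(rho_between) != 1L ||
      rho_between < 0 || rho_between >= 1) {
    stop("`rho_between` must lie in [0, 1)", call. = FALSE)
  }
  if (any(rho_within >= 1) || any(rho_within < rho_between) ||
      (rho_between > 0 && any(rho_within <= rho_between))) {
    stop(sprintf(paste0("correlation structure requires ",
                        "0 <= rho_between < rho_within < 1; got ",
                        "rho_within = (%s), rho_between = %g"),
                 paste(signif(rho_within, 3), collapse = ", "), rho_between),
         call. = FALSE)
  }
  if (!is.numeric(rho_subject_sd) || rho_subject_sd < 0) {
    stop("`rho_subject_sd` must be >= 0", call. = FALSE)
  }
  if (fn_mean_within < 0 || fn_mean_between < 0) {
    stop("fiber-count means must be non-negative", call. = FALSE)
  }
  if (fn_dispersion <= 0) {
    stop("`fn_dispersion` must be positive", call. = FALSE)
  }
  if (any(shortcut_density < 0) || any(shortcut_density >= 1)) {
    stop("`shortcut_density` must lie in [0, 1)", call. = FALSE)
  }
  if (spike_rate < 0 || spike_rate >= 1) {
    stop("`spike_rate` must lie in [0, 1)", call. = FALSE)
  }
  if (tr <= 0) stop("`tr` must be positive", call. = FALSE)
  if (!is.numeric(rho_homotopic) || length(rho_homotopic) != 1L ||
      rho_homotopic >= 1 || rho_homotopic < max(rho_within)) {
    stop("`rho_homotopic` must satisfy rho_within <= rho_homotopic < 1",
         call. = FALSE)
  }
  # defensive positive-definiteness check of the requested block structure
  for (g in groups) {
    check_block_pd(n_rois, n_modules, rho_within[[g]], rho_between,
                   rho_homotopic)
  }
  structure(list(
    n_rois = as.integer(n_rois), n_volumes = as.integer(n_volumes),
    tr = as.numeric(tr), group_sizes = group_sizes,
    n_modules = as.integer(n_modules), rho_within = rho_within,
    rho_between = rho_between, rho_homotopic = rho_homotopic,
    rho_subject_sd = rho_subject_sd,
    fn_mean_within = fn_mean_within, fn_mean_between = fn_mean_between,
    fn_dispersion = fn_dispersion, shortcut_density = shortcut_density,
    spike_rate = spike_rate, ahrs_mean = ahrs_mean, ahrs_sd = ahrs_sd,
    seed = as.integer(seed)), class = "cohort_spec")
}

# Module assignment vector for the block-exchangeable structure.
module_of <- function(n_rois, n_modules) {
  rep(seq_len(n_modules), each = n_rois %/% n_modules)
}

# Homotopic pairing: consecutive ROI pairs (1,2), (3,4), ... nested inside
# each module (modules are bilateral, so homologue pairs live within them).
homotopic_pairs <- function(n_rois, n_modules) {
  mod <- module_of(n_rois, n_modules)
  k <- seq(1L, n_rois - 1L, by = 2L)
  k <- k[mod[k] == mod[k + 1L]]
  cbind(k, k + 1L)
}

# Exchangeable block correlation matrix: rho_w inside modules, rho_b
# across, rho_h on the homotopic pairs nested inside modules.
block_correlation <- function(n_rois, n_modules, rho_w, rho_b,
                              rho_h = rho_w) {
  mod <- module_of(n_rois, n_modules)
  sigma <- matrix(rho_b, n_rois, n_rois)
  same <- outer(mod, mod, "==")
  sigma[same] <- rho_w
  if (rho_h != rho_w) {
    hp <- homotopic_pairs(n_rois, n_modules)
    sigma[hp] <- rho_h
    sigma[hp[, 2:1, drop = FALSE]] <- rho_h
  }
  diag(sigma) <- 1
  sigma
}

check_block_pd <- function(n_rois, n_modules, rho_w, rho_b,
                           rho_h = rho_w) {
  sigma <- block_correlation(n_rois, n_modules, rho_w, rho_b, rho_h)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop(sprintf(paste0("requested correlation structure is not positive ",
                        "definite (rho_within = %g, rho_between = %g)"),
                 rho_w, rho_b), call. = FALSE)
  }
  invisible(TRUE)
}

subject_roster <- function(spec) {
  groups <- rep(names(spec$group_sizes), spec$group_sizes)
  data.frame(subject_id = sprintf("sub-%03d", seq_along(groups)),
             group = groups, stringsAsFactors = FALSE)
}

#' Generate a functional-arm synthetic cohort
#'
#' Each subject's ROI x volume matrix is drawn from a zero-mean
#' multivariate normal whose correlation matrix is block-exchangeable:
#' `rho_within` (group-specific, with per-subject jitter) inside modules and
#' `rho_between` across modules. Motion traces, fabricated global/white
#' matter/CSF signals, and AHRS scores (AVH group only) are attached.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A list of subject records (class `cohort`), each with elements
#'   `subject_id`, `group`, `timeseries`, `motion`, `nuisance` (volumes x 3
#'   matrix: global, wm, csf) and, for AVH subjects, `ahrs_total`.
#' @export
generate_functional_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  roster <- subject_roster(spec)
  n <- nrow(roster)
  seeds <- spawn_seeds(spec$seed, 3L * n + 1L)
  ahrs <- generate_symptom_scores(spec$group_sizes[["AVH"]],
                                  seed = seeds[3L * n + 1L],
                                  mean = spec$ahrs_mean, sd = spec$ahrs_sd)
  cohort <- vector("list", n)
  avh_i <- 0L
  for (i in seq_len(n)) {
    g <- roster$group[i]
    ts <- with_seed(seeds[i], {
      rho_i <- spec$rho_within[[g]]
      if (spec$rho_subject_sd > 0) {
        rho_i <- rho_i + rnorm(1, 0, spec$rho_subject_sd)
        rho_i <- min(max(rho_i, spec$rho_between + 0.01),
                     spec$rho_homotopic)
      }
      # hierarchical coupling: between-module correlation scales with the
      # subject's overall connectivity level (module factors shared), so
      # rho_between is attained exactly at the HC baseline rho_within
      rho_b_i <- if (spec$rho_within[["HC"]] > 0) {
        spec$rho_between * rho_i / spec$rho_within[["HC"]]
      } else {
        spec$rho_between
      }
      sigma <- block_correlation(spec$n_rois, spec$n_modules, rho_i,
                                 rho_b_i, spec$rho_homotopic)
      z <- matrix(rnorm(spec$n_rois * spec$n_volumes), spec$n_rois)
      subject_timeseries(crossprod(chol(sigma), z), tr = spec$tr)
    })
    motion <- generate_motion_trace(spec$n_volumes, spec$spike_rate,
                                    seed = seeds[n + i])
    nuis <- with_seed(seeds[2L * n + i], {
      m <- vapply(1:3, function(k) {
        as.numeric(stats::filter(rnorm(spec$n_volumes), 0.9,
                                 method = "recursive"))
      }, numeric(spec$n_volumes))
      colnames(m) <- c("global", "wm", "csf")
      m
    })
    rec <- list(subject_id = roster$subject_id[i], group = g,
                timeseries = ts, motion = motion, nuisance = nuis)
    if (g == "AVH") {
      avh_i <- avh_i + 1L
      rec$ahrs_total <- ahrs[avh_i]
    }
    cohort[[i]] <- rec
  }
  structure(cohort, class = "cohort", spec = spec)
}

#' Generate a structural-arm synthetic cohort
#'
#' Per subject, a symmetric non-negative integer fiber-count matrix with
#' zero diagonal. Counts are negative-binomial (mean `fn_mean_within`
#' inside modules, `fn_mean_between` across; size `fn_dispersion`).
#' Between-module pairs additionally receive strong long-range shortcut
#' edges with group-specific probability `shortcut_density`; the AVH
#' group's reduced density lengthens its shortest paths.
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort` list; each record has `subject_id`, `group`,
#'   `fiber_counts` (integer matrix) and, for AVH subjects, `ahrs_total`.
#' @export
generate_structural_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  roster <- subject_roster(spec)
  n <- nrow(roster)
  seeds <- spawn_seeds(spec$seed + 1L, n + 1L)
  ahrs <- generate_symptom_scores(spec$group_sizes[["AVH"]],
                                  seed = seeds[n + 1L],
                                  mean = spec$ahrs_mean, sd = spec$ahrs_sd)
  mod <- module_of(spec$n_rois, spec$n_modules)
  ut <- which(upper.tri(matrix(0, spec$n_rois, spec$n_rois)), arr.ind = TRUE)
  within <- mod[ut[, 1L]] == mod[ut[, 2L]]
  cohort <- vector("list", n)
  avh_i <- 0L
  for (i in seq_len(n)) {
    g <- roster$group[i]
    fn_vec <- with_seed(seeds[i], {
      mu <- ifelse(within, spec$fn_mean_within, spec$fn_mean_between)
      counts <- ifelse(mu > 0,
                       rnbinom(length(mu), mu = mu, size = spec$fn_dispersion),
                       0L)
      sc_p <- spec$shortcut_density[[g]]
      if (sc_p > 0) {
        is_shortcut <- !within & runif(length(mu)) < sc_p
        if (any(is_shortcut)) {
          counts[is_shortcut] <- rnbinom(sum(is_shortcut),
                                         mu = spec$fn_mean_within,
                                         size = spec$fn_dispersion)
        }
      }
      counts
    })
    fn <- matrix(0L, spec$n_rois, spec$n_rois)
    fn[upper.tri(fn)] <- as.integer(fn_vec)
    fn <- fn + t(fn)
    rownames(fn) <- colnames(fn) <- sprintf("ROI%03d", seq_len(spec$n_rois))
    rec <- list(subject_id = roster$subject_id[i], group = g,
                fiber_counts = fn)
    if (g == "AVH") {
      avh_i <- avh_i + 1L
      rec$ahrs_total <- ahrs[avh_i]
    }
    cohort[[i]] <- rec
  }
  structure(cohort, class = "cohort", spec = spec)
}

#' Generate a synthetic rigid-body motion trace
#'
#' Smooth low-amplitude drift (random-walk translations and rotations) plus
#' step displacements at randomly selected spike volumes. Spike steps are
#' translations of 1 mm, large enough to push framewise displacement above
#' 0.5 mm at exactly the spiked volumes.
#'
#' @param n_volumes Number of volumes (>= 2).
#' @param spike_rate Per-volume spike probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return A [motion_trace()].
#' @export
generate_motion_trace <- function(n_volumes, spike_rate = 0.02, seed = 1L) {
  stop_if_not_scalar_count(n_volumes, "n_volumes", 2L)
  if (spike_rate < 0 || spike_rate >= 1) {
    stop("`spike_rate` must lie in [0, 1)", call. = FALSE)
  }
  with_seed(seed, {
    trans_inc <- matrix(rnorm(3L * n_volumes, 0, 0.02), n_volumes, 3L)
    rot_inc <- matrix(rnorm(3L * n_volumes, 0, 2e-4), n_volumes, 3L)
    trans_inc[1L, ] <- 0
    rot_inc[1L, ] <- 0
    trans <- apply(trans_inc, 2L, cumsum)
    rot <- apply(rot_inc, 2L, cumsum)
    if (spike_rate > 0 && n_volumes > 2L) {
      spikes <- which(runif(n_volumes) < spike_rate)
      spikes <- spikes[spikes >= 2L]
      for (t in spikes) {
        axis <- sample.int(3L, 1L)
        trans[t:n_volumes, axis] <- trans[t:n_volumes, axis] +
          sample(c(-1, 1), 1L) * 1.0
      }
    }
    motion_trace(trans, rot)
  })
}

#' Generate synthetic AHRS total scores
#'
#' Scores are drawn from a normal distribution truncated at 0. The default
#' mean 23.9 and SD 8.4 reproduce the AVH group's reported score summary.
#'
#' @param n Number of scores (>= 1).
#' @param seed Integer seed.
#' @param mean,sd Pre-truncation mean and SD.
#' @return Numeric vector of `n` non-negative scores.
#' @export
generate_symptom_scores <- function(n, seed = 1L, mean = 23.9, sd = 8.4) {
  stop_if_not_scalar_count(n, "n", 1L)
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      x <- rnorm(max(2L * n, 10L), mean, sd)
      out <- c(out, x[x >= 0])
    }
    out[seq_len(n)]
  })
}

#' @export
print.cohort <- function(x, ...) {
  grp <- table(vapply(x, `[[`, "", "group"))
  cat(sprintf("<cohort> %d subjects (%s)\n", length(x),
              paste(sprintf("%s: %d", names(grp), grp), collapse = ", ")))
  invisible(x)
}
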