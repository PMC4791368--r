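# Orchestration of both pipeline arms, configuration, TSV/JSON I/O and
# provenance records.

utils::globalVariables(c("modality", "scheme", "group", "ahrs_total",
                         ".", "subject_id"))

#' Pipeline run configuration
#'
#' All tunables with their conventional defaults: discard 10 volumes, FD
#' spike threshold 0.5 mm, band 0.01-0.08 Hz, significance schemes P<0.05
#' Bonferroni / P<0.001 uncorrected / P<0.01 Bonferroni, fiber threshold 3,
#' 1000 matched random networks, 10000 permutations.
#'
#' @param discard_k Leading volumes to discard.
#' @param fd_threshold Spike FD threshold (mm).
#' @param band Band-pass edges (Hz).
#' @param schemes List of [threshold_scheme()]s for the functional arm.
#' @param min_fibers Structural edge threshold (fiber count).
#' @param n_null Null networks per subject (0 disables normalization).
#' @param swaps_per_edge Rewiring burn-in per null network.
#' @param n_perm Permutations per group test.
#' @param seed Master seed; every stage derives sub-seeds from it.
#' @param output_dir Optional directory; when set, all result tables and a
#'   provenance record are persisted there.
#' @return A `run_config` list.
#' @export
run_config <- function(discard_k = 10L, fd_threshold = 0.5,
                       band = c(0.01, 0.08),
                       schemes = list(
                         threshold_scheme(0.05, "bonferroni"),
                         threshold_scheme(0.001, "none"),
                         threshold_scheme(0.01, "bonferroni")),
                       min_fibers = 3L, n_null = 1000L,
                       swaps_per_edge = 10L, n_perm = 10000L, seed = 1L,
                       output_dir = NULL) {
  stopifnot(length(band) == 2L, band[1L] < band[2L])
  structure(list(discard_k = as.integer(discard_k),
                 fd_threshold = fd_threshold, band = band,
                 schemes = schemes, min_fibers = as.integer(min_fibers),
                 n_null = as.integer(n_null),
                 swaps_per_edge = as.integer(swaps_per_edge),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Read a labeled numeric matrix from TSV
#'
#' Expects a header row of column labels and a first column of row labels.
#' Ragged rows and non-numeric cells are rejected with their coordinates.
#'
#' @param path File path.
#' @param expected_labels Optional label vector; if the file's labels are a
#'   permutation of it, rows/columns are reordered to match (with a
#'   warning).
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path, expected_labels = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop(sprintf("%s is empty", path), call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_expected <- length(fields[[1L]])
  bad <- which(lengths(fields) != ncol_expected)
  if (length(bad)) {
    stop(sprintf("%s: ragged row(s) %s (expected %d fields)", path,
                 paste(bad, collapse = ", "), ncol_expected), call. = FALSE)
  }
  header <- fields[[1L]][-1L]
  body <- fields[-1L]
  row_labels <- vapply(body, `[[`, "", 1L)
  m <- matrix(NA_real_, length(body), length(header),
              dimnames = list(row_labels, header))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1L]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("%s: non-numeric cell at row %d, column %d ('%s')",
                   path, i + 1L, j + 1L, body[[i]][j + 1L]), call. = FALSE)
    }
    m[i, ] <- v
  }
  if (!is.null(expected_labels) &&
      !identical(colnames(m), expected_labels) &&
      setequal(colnames(m), expected_labels)) {
    warning(sprintf("%s: labels out of order; reordering to match", path),
            call. = FALSE)
    m <- m[, expected_labels, drop = FALSE]
    if (setequal(rownames(m), expected_labels)) {
      m <- m[expected_labels, , drop = FALSE]
    }
  }
  m
}

#' Write a labeled numeric matrix as TSV
#'
#' Full double precision (round-trips through [read_matrix_tsv()] to
#' better than 1e-12).
#'
#' @param m Numeric matrix with dimnames (defaults are generated).
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("R%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("C%03d", seq_len(ncol(m)))
  lines <- c(paste(c("label", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i],
                       formatC(m[i, ], format = "g", digits = 17)),
                     collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Export a weighted graph as an edge list
#'
#' @param g A [weighted_graph()].
#' @return A `data.table` with columns `node_i`, `node_j`, `weight`.
#' @export
graph_to_edgelist <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  idx <- which(upper.tri(g$weights) & g$weights > 0, arr.ind = TRUE)
  data.table(node_i = g$nodes[idx[, 1L]], node_j = g$nodes[idx[, 2L]],
             weight = g$weights[idx])
}

#' Write a synthetic cohort to disk
#'
#' One TSV per subject per modality, a cohort manifest
#' (`manifest.tsv`: subject_id, group, ahrs_total, file paths) and the
#' generating spec echoed to `spec.cfg` (key = value lines).
#'
#' @param cohort A `cohort` from the generators.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a `data.table`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(rec) {
    row <- data.table(subject_id = rec$subject_id, group = rec$group,
                      ahrs_total = if (is.null(rec$ahrs_total)) NA_real_
                                   else rec$ahrs_total,
                      ts_path = NA_character_, motion_path = NA_character_,
                      nuisance_path = NA_character_, fn_path = NA_character_)
    if (!is.null(rec$timeseries)) {
      p <- file.path(dir, paste0(rec$subject_id, "_timeseries.tsv"))
      write_matrix_tsv(t(rec$timeseries$values), p)  # volumes x ROIs
      row$ts_path <- basename(p)
    }
    if (!is.null(rec$motion)) {
      p <- file.path(dir, paste0(rec$subject_id, "_motion.tsv"))
      write_matrix_tsv(cbind(rec$motion$translations, rec$motion$rotations),
                       p)
      row$motion_path <- basename(p)
    }
    if (!is.null(rec$nuisance)) {
      p <- file.path(dir, paste0(rec$subject_id, "_nuisance.tsv"))
      write_matrix_tsv(rec$nuisance, p)
      row$nuisance_path <- basename(p)
    }
    if (!is.null(rec$fiber_counts)) {
      p <- file.path(dir, paste0(rec$subject_id, "_fn.tsv"))
      write_matrix_tsv(rec$fiber_counts, p)
      row$fn_path <- basename(p)
    }
    row
  })
  manifest <- rbindlist(rows)
  fwrite(manifest, file.path(dir, "manifest.tsv"), sep = "\t")
  spec <- attr(cohort, "spec")
  if (!is.null(spec)) {
    kv <- vapply(names(unclass(spec)), function(nm) {
      sprintf("%s = %s", nm,
              paste(format(spec[[nm]], digits = 15), collapse = ","))
    }, "")
    writeLines(kv, file.path(dir, "spec.cfg"))
  }
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.tsv` and subject files.
#' @param tr Sampling interval for functional series (seconds); read from
#'   `spec.cfg` when present.
#' @return A `cohort` list.
#' @export
read_cohort <- function(dir, tr = NULL) {
  mpath <- file.path(dir, "manifest.tsv")
  if (!file.exists(mpath)) stop(sprintf("no manifest.tsv in %s", dir),
                                call. = FALSE)
  manifest <- fread(mpath, sep = "\t")
  if (is.null(tr)) {
    cfg <- file.path(dir, "spec.cfg")
    tr <- 2
    if (file.exists(cfg)) {
      ln <- grep("^tr *=", readLines(cfg), value = TRUE)
      if (length(ln)) tr <- as.numeric(sub(".*= *", "", ln[1L]))
    }
  }
  cohort <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i]
    rec <- list(subject_id = row$subject_id, group = row$group)
    if (is.finite(row$ahrs_total)) rec$ahrs_total <- row$ahrs_total
    if (!is.na(row$ts_path)) {
      m <- read_matrix_tsv(file.path(dir, row$ts_path))
      rec$timeseries <- subject_timeseries(t(m), tr = tr)
    }
    if (!is.na(row$motion_path)) {
      m <- read_matrix_tsv(file.path(dir, row$motion_path))
      rec$motion <- motion_trace(m[, 1:3, drop = FALSE],
                                 m[, 4:6, drop = FALSE])
    }
    if (!is.na(row$nuisance_path)) {
      rec$nuisance <- read_matrix_tsv(file.path(dir, row$nuisance_path))
    }
    if (!is.na(row$fn_path)) {
      rec$fiber_counts <- read_matrix_tsv(file.path(dir, row$fn_path))
    }
    rec
  })
  structure(cohort, class = "cohort")
}

cohort_groups <- function(cohort) vapply(cohort, `[[`, "", "group")

check_group_sizes <- function(cohort) {
  tab <- table(cohort_groups(cohort))
  if (any(tab < 2L)) {
    stop(sprintf("group(s) below 2 subjects: %s",
                 paste(names(tab)[tab < 2L], collapse = ", ")),
         call. = FALSE)
  }
  invisible(tab)
}

subject_metric_row <- function(rec, g, scheme_name, norm) {
  raw <- global_metrics(g)
  bp <- basic_properties(g)
  row <- data.table(subject_id = rec$subject_id, group = rec$group,
                    modality = g$modality, scheme = scheme_name,
                    cp = raw[["cp"]], lp = raw[["lp"]], eg = raw[["eg"]],
                    eloc = raw[["eloc"]],
                    gamma = NA_real_, lambda = NA_real_, sigma = NA_real_,
                    neg = NA_real_, neloc = NA_real_,
                    density = bp[["density"]], strength = bp[["strength"]],
                    largest_component = bp[["largest_component"]],
                    ahrs_total = if (is.null(rec$ahrs_total)) NA_real_
                                 else rec$ahrs_total)
  if (!is.null(norm)) {
    row[, `:=`(gamma = norm$gamma, lambda = norm$lambda,
               sigma = norm$sigma, neg = norm$neg, neloc = norm$neloc)]
  }
  row
}

persist_arm <- function(result, config, arm) {
  if (is.null(config$output_dir)) return(invisible(NULL))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(result$metrics,
         file.path(config$output_dir, sprintf("%s_metrics.tsv", arm)),
         sep = "\t")
  fwrite(result$tests,
         file.path(config$output_dir, sprintf("%s_group_tests.tsv", arm)),
         sep = "\t")
  if (!is.null(result$correlations) && nrow(result$correlations)) {
    fwrite(result$correlations,
           file.path(config$output_dir,
                     sprintf("%s_ahrs_correlations.tsv", arm)), sep = "\t")
  }
  rec <- list(arm = arm,
              config = config[setdiff(names(unclass(config)), "schemes")],
              schemes = lapply(config$schemes, unclass),
              package_version = as.character(packageVersion("cohortnet")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(rec,
                       file.path(config$output_dir,
                                 sprintf("%s_run_record.json", arm)),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

#' Compute the per-subject metric table for the functional arm
#'
#' Preprocesses each subject, builds the correlation matrix, thresholds at
#' each configured scheme and computes raw (and, if `config$n_null > 0`,
#' null-normalized) metrics. This is the metrics stage of
#' [run_functional_arm()], usable on its own for small cohorts.
#'
#' @param cohort A `cohort` (or directory path for [read_cohort()]).
#' @param config A [run_config()].
#' @return List with `metrics` (`data.table`) and `qc` per subject;
#'   per-subject failures are collected in `errors`.
#' @export
functional_metric_table <- function(cohort, config = run_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  n <- length(cohort)
  seeds <- spawn_seeds(config$seed + 101L, n)
  rows <- list()
  qc <- list()
  errors <- character(0)
  for (i in seq_len(n)) {
    rec <- cohort[[i]]
    res <- tryCatch({
      pre <- preprocess_subject(rec$timeseries, rec$motion, rec$nuisance,
                                k = config$discard_k,
                                fd_threshold = config$fd_threshold,
                                band = config$band)
      corr <- correlation_matrix(pre$timeseries)
      out <- list()
      for (scheme in config$schemes) {
        g <- threshold_functional(corr, scheme)
        norm <- if (config$n_null > 0L) {
          normalized_metrics(g, null_ensemble_spec(config$n_null,
                                                   config$swaps_per_edge,
                                                   seed = seeds[i]))
        }
        out[[scheme_label(scheme)]] <-
          subject_metric_row(rec, g, scheme_label(scheme), norm)
      }
      list(rows = rbindlist(out), qc = pre$qc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("%s: %s", rec$subject_id,
                                  conditionMessage(res)))
    } else {
      rows[[length(rows) + 1L]] <- res$rows
      qc[[rec$subject_id]] <- res$qc
    }
  }
  list(metrics = if (length(rows)) rbindlist(rows) else data.table(),
       qc = qc, errors = errors)
}

#' Compute the per-subject metric table for the structural arm
#'
#' @inheritParams functional_metric_table
#' @return As [functional_metric_table()], with scheme label
#'   `fn>=<min_fibers>`.
#' @export
structural_metric_table <- function(cohort, config = run_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  n <- length(cohort)
  seeds <- spawn_seeds(config$seed + 202L, n)
  label <- sprintf("fn>=%d", config$min_fibers)
  rows <- list()
  errors <- character(0)
  for (i in seq_len(n)) {
    rec <- cohort[[i]]
    res <- tryCatch({
      g <- threshold_structural(rec$fiber_counts, config$min_fibers)
      norm <- if (config$n_null > 0L) {
        normalized_metrics(g, null_ensemble_spec(config$n_null,
                                                 config$swaps_per_edge,
                                                 seed = seeds[i]))
      }
      subject_metric_row(rec, g, label, norm)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("%s: %s", rec$subject_id,
                                  conditionMessage(res)))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  list(metrics = if (length(rows)) rbindlist(rows) else data.table(),
       errors = errors)
}

arm_statistics <- function(metrics, config) {
  metric_cols <- c("cp", "lp", "eg", "eloc", "gamma", "lambda", "sigma",
                   "neg", "neloc", "density", "strength",
                   "largest_component")
  metric_cols <- metric_cols[vapply(metric_cols, function(m) {
    m %in% names(metrics) && any(is.finite(metrics[[m]]))
  }, logical(1))]
  tests <- group_differences(metrics, metric_cols, n_perm = config$n_perm,
                             seed = config$seed + 303L)
  correlations <- if (any(is.finite(metrics$ahrs_total))) {
    ahrs_correlations(metrics, metric_cols)
  }
  list(tests = tests, correlations = correlations)
}

run_arm <- function(cohort, config, arm) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  check_group_sizes(cohort)
  stage <- if (arm == "functional") functional_metric_table(cohort, config)
           else structural_metric_table(cohort, config)
  if (length(stage$errors)) {
    ok_groups <- table(stage$metrics$group) / max(1L,
      length(unique(stage$metrics$scheme)))
    if (length(ok_groups) < 3L || any(ok_groups < 2)) {
      stop(sprintf("per-subject failures left a group below 2 subjects:\n%s",
                   paste(stage$errors, collapse = "\n")), call. = FALSE)
    }
    warning(sprintf("per-subject failures (excluded):\n%s",
                    paste(stage$errors, collapse = "\n")), call. = FALSE)
  }
  stats <- arm_statistics(stage$metrics, config)
  result <- list(metrics = stage$metrics, tests = stats$tests,
                 correlations = stats$correlations, qc = stage$qc,
                 errors = stage$errors)
  persist_arm(result, config, arm)
  result
}

#' Run the full functional pipeline arm
#'
#' Executes, per subject: volume discard, FD/spike detection, nuisance
#' regression, band-pass filtering, correlation, thresholding at every
#' configured scheme, raw and null-normalized metrics; then permutation
#' group statistics and AHRS correlations. Fully reproducible from
#' `config$seed`; result tables are persisted when `config$output_dir` is
#' set.
#'
#' @param cohort A `cohort` (or cohort directory path).
#' @param config A [run_config()].
#' @return List with `metrics`, `tests`, `correlations`, `qc`, `errors`.
#' @export
run_functional_arm <- function(cohort, config = run_config()) {
  run_arm(cohort, config, "functional")
}

#' Run the full structural pipeline arm
#'
#' Fiber-count thresholding, raw and null-normalized metrics, permutation
#' group statistics and AHRS correlations.
#'
#' @inheritParams run_functional_arm
#' @return As [run_functional_arm()].
#' @export
run_structural_arm <- function(cohort, config = run_config()) {
  run_arm(cohort, config, "structural")
}
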