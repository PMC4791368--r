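test_that("matrix TSV I/O round-trips at full precision", {
  set.seed(15)
  m <- matrix(rnorm(90 * 90), 90,
              dimnames = list(sprintf("ROI%03d", 1:90),
                              sprintf("ROI%03d", 1:90)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, path)
  back <- read_matrix_tsv(path)
  expect_identical(dimnames(back), dimnames(m))
  expect_lt(max(abs(back - m)), 1e-12)
})

test_that("malformed matrix files are rejected with coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("label\ta\tb", "r1\t1\t2", "r2\t3"), path)
  expect_error(read_matrix_tsv(path), "ragged row\\(s\\) 3")
  writeLines(c("label\ta\tb", "r1\t1\tx", "r2\t3\t4"), path)
  expect_error(read_matrix_tsv(path), "row 2, column 3")
})

test_that("out-of-order labels are reordered against the expected set", {
  m <- matrix(1:4, 2, dimnames = list(c("B", "A"), c("B", "A")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, path)
  expect_warning(back <- read_matrix_tsv(path, expected_labels = c("A", "B")),
                 "reordering")
  expect_identical(colnames(back), c("A", "B"))
  expect_equal(back["A", "B"], m["A", "B"], ignore_attr = TRUE)
})

test_that("cohorts round-trip through the on-disk manifest layout", {
  spec <- tiny_spec(seed = 44L, n_rois = 12L, n_modules = 3L,
                    n_volumes = 40L)
  fc <- generate_functional_cohort(spec)
  sc <- generate_structural_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(fc, dir)
  manifest <- data.table::fread(file.path(dir, "manifest.tsv"))
  expect_identical(nrow(manifest), 12L)
  expect_true(file.exists(file.path(dir, "spec.cfg")))
  back <- read_cohort(dir)
  expect_identical(length(back), 12L)
  expect_equal(back[[1]]$timeseries$values, fc[[1]]$timeseries$values,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back[[1]]$group, "AVH")
  expect_equal(back[[1]]$ahrs_total, fc[[1]]$ahrs_total, tolerance = 1e-12)
  dir2 <- withr::local_tempdir()
  write_cohort(sc, dir2)
  back2 <- read_cohort(dir2)
  expect_equal(back2[[5]]$fiber_counts, sc[[5]]$fiber_counts,
               tolerance = 0, ignore_attr = TRUE)
})

test_that("a tiny hand-sized cohort flows through the metrics stage", {
  spec <- cohort_spec(group_sizes = c(AVH = 2L, nAVH = 2L, HC = 2L),
                      n_rois = 4L, n_modules = 2L, n_volumes = 60L,
                      rho_within = 0.5, rho_between = 0.1,
                      rho_homotopic = 0.8, seed = 50L)
  fc <- generate_functional_cohort(spec)
  cfg <- run_config(n_null = 0L, discard_k = 5L,
                    schemes = list(threshold_scheme(0.999, "none")),
                    seed = 2L)
  st <- functional_metric_table(fc[1:3], cfg)
  expect_identical(nrow(st$metrics), 3L)
  expect_true(all(c("cp", "lp", "eg", "eloc", "density", "strength",
                    "largest_component") %in% names(st$metrics)))
})

test_that("arm runs are deterministic and persist their provenance", {
  spec <- tiny_spec(seed = 60L)
  sc <- generate_structural_cohort(spec)
  dir <- withr::local_tempdir()
  cfg <- run_config(n_null = 5L, n_perm = 100L, seed = 77L,
                    output_dir = dir)
  r1 <- run_structural_arm(sc, cfg)
  r2 <- run_structural_arm(sc, cfg)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$tests, r2$tests)
  expect_true(file.exists(file.path(dir, "structural_metrics.tsv")))
  expect_true(file.exists(file.path(dir, "structural_group_tests.tsv")))
  expect_true(file.exists(file.path(dir, "structural_run_record.json")))
  rec <- jsonlite::read_json(file.path(dir, "structural_run_record.json"))
  expect_identical(rec$config$seed, 77L)
})

test_that("identical fiber matrices across subjects give null group tests", {
  spec <- tiny_spec(seed = 61L)
  sc <- generate_structural_cohort(spec)
  for (i in seq_along(sc)) sc[[i]]$fiber_counts <- sc[[1]]$fiber_counts
  cfg <- run_config(n_null = 0L, n_perm = 200L, seed = 5L)
  res <- run_structural_arm(sc, cfg)
  expect_true(all(res$tests$p_perm > 0.9))
})

test_that("group collapse below two subjects aborts the run", {
  spec <- tiny_spec(seed = 62L)
  sc <- generate_structural_cohort(spec)
  sc_small <- structure(sc[c(1, 5, 6, 7, 8, 9, 10, 11, 12)],
                        class = "cohort")
  expect_error(run_structural_arm(sc_small, run_config(n_null = 0L,
                                                       n_perm = 50L)),
               "below 2 subjects")
})
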