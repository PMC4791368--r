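test_that("cohort_spec validates its invariants", {
  expect_s3_class(cohort_spec(), "cohort_spec")
  expect_error(cohort_spec(rho_within = 0.1, rho_between = 0.3),
               "rho_between < rho_within")
  expect_error(cohort_spec(n_rois = 91L), "divisible")
  expect_error(cohort_spec(group_sizes = c(1L, 5L, 5L)), ">= 2")
  expect_error(cohort_spec(fn_mean_within = -1), "non-negative")
  expect_error(cohort_spec(fn_dispersion = 0), "positive")
  expect_error(cohort_spec(spike_rate = 1), "spike_rate")
  # equal zero correlations are a valid degenerate request
  expect_s3_class(cohort_spec(rho_within = 0, rho_between = 0,
                              rho_homotopic = 0.5), "cohort_spec")
})

test_that("functional cohort is reproducible and respects group structure", {
  spec <- tiny_spec(seed = 42L)
  c1 <- generate_functional_cohort(spec)
  c2 <- generate_functional_cohort(spec)
  expect_identical(c1, c2)
  expect_length(c1, 12L)
  expect_identical(vapply(c1, `[[`, "", "group"),
                   rep(c("AVH", "nAVH", "HC"), each = 4L))
  # AHRS present iff AVH
  has_ahrs <- vapply(c1, function(r) !is.null(r$ahrs_total), logical(1))
  expect_identical(has_ahrs, rep(c(TRUE, FALSE, FALSE), each = 4L))
  expect_true(all(vapply(c1[1:4], `[[`, 0, "ahrs_total") >= 0))
  # dimensions
  expect_identical(dim(c1[[1]]$timeseries$values), c(90L, 180L))
  expect_identical(c1[[1]]$timeseries$tr, 2)
})

test_that("zero-correlation cohorts produce null-level empirical correlations", {
  # rho_within = rho_between = 0: mean absolute off-diagonal correlation
  # should sit at the white-noise level ~ sqrt(2/pi)/sqrt(n)
  spec <- cohort_spec(group_sizes = c(AVH = 17L, nAVH = 17L, HC = 18L),
                      n_rois = 30L, n_modules = 6L, n_volumes = 200L,
                      rho_within = 0, rho_between = 0, rho_homotopic = 0,
                      rho_subject_sd = 0, seed = 9L)
  cohort <- generate_functional_cohort(spec)
  offdiag <- unlist(lapply(cohort, function(rec) {
    r <- cor(t(rec$timeseries$values))
    abs(r[upper.tri(r)])
  }))
  n <- spec$n_volumes
  expected <- sqrt(2 / pi) / sqrt(n - 1)       # E|r| under the null
  se <- sqrt((1 - 2 / pi) / (n - 1)) / sqrt(length(offdiag))
  expect_lt(abs(mean(offdiag) - expected), 3 * se + 0.002)
})

test_that("large-sample correlations recover the requested block structure", {
  spec <- cohort_spec(group_sizes = c(AVH = 2L, nAVH = 2L, HC = 4L),
                      n_volumes = 2000L, rho_within = 0.5, rho_between = 0.1,
                      rho_homotopic = 0.9, rho_subject_sd = 0, seed = 5L)
  cohort <- generate_functional_cohort(spec)
  mod <- rep(1:6, each = 15L)
  hp <- cbind(seq(1L, 89L, 2L), seq(2L, 90L, 2L))
  within <- outer(mod, mod, "==")
  diag(within) <- FALSE
  within[hp] <- FALSE
  within[hp[, 2:1]] <- FALSE
  r_within <- sapply(cohort[5:8], function(rec) {
    r <- cor(t(rec$timeseries$values))
    mean(r[within])
  })
  expect_lt(max(abs(r_within - 0.5)), 0.05)
})

test_that("structural cohorts are symmetric integer matrices with planted rates", {
  spec <- tiny_spec(seed = 3L)
  sc <- generate_structural_cohort(spec)
  for (rec in sc[c(1, 7, 12)]) {
    fn <- rec$fiber_counts
    expect_identical(fn, t(fn))
    expect_true(all(fn >= 0))
    expect_true(all(fn == round(fn)))
    expect_true(all(diag(fn) == 0))
  }
  # degenerate rates: no between-module mass at all
  spec0 <- tiny_spec(fn_mean_between = 0,
                     shortcut_density = c(0, 0, 0), seed = 4L)
  sc0 <- generate_structural_cohort(spec0)
  mod <- rep(1:6, each = 15L)
  between <- outer(mod, mod, "!=")
  expect_true(all(vapply(sc0, function(r) all(r$fiber_counts[between] == 0),
                         logical(1))))
  # Monte-Carlo mean recovery of the within-module rate
  spec1 <- cohort_spec(group_sizes = c(AVH = 33L, nAVH = 33L, HC = 34L),
                       seed = 11L)
  sc1 <- generate_structural_cohort(spec1)
  within <- outer(mod, mod, "==")
  diag(within) <- FALSE
  m_within <- mean(vapply(sc1, function(r) mean(r$fiber_counts[within]),
                          numeric(1)))
  expect_lt(abs(m_within - spec1$fn_mean_within), 0.1 * spec1$fn_mean_within)
})

test_that("motion traces are seeded, smooth, and spike where requested", {
  m1 <- generate_motion_trace(180L, 0.1, seed = 8L)
  m2 <- generate_motion_trace(180L, 0.1, seed = 8L)
  expect_identical(m1, m2)
  expect_error(generate_motion_trace(1L, 0), "n_volumes")
  expect_error(generate_motion_trace(100L, 1.2), "spike_rate")
  # no spikes -> FD never crosses the threshold
  fd0 <- framewise_displacement(generate_motion_trace(500L, 0, seed = 2L))
  expect_true(all(fd0 < 0.5))
  # spike count over seeds within the binomial 99% interval
  counts <- vapply(1:30, function(s) {
    fd <- framewise_displacement(generate_motion_trace(180L, 0.1, seed = s))
    sum(fd > 0.5)
  }, numeric(1))
  n_bern <- 30 * 179
  band <- qbinom(c(0.005, 0.995), n_bern, 0.1)
  expect_gte(sum(counts), band[1])
  expect_lte(sum(counts), band[2])
})

test_that("symptom scores match the published summary distribution", {
  s <- generate_symptom_scores(1000L, seed = 13L)
  expect_length(s, 1000L)
  expect_true(all(s >= 0))
  expect_lt(abs(mean(s) - 23.9), 1.0)
  expect_lt(abs(sd(s) - 8.4), 1.0)
  expect_identical(generate_symptom_scores(1L, seed = 5L),
                   generate_symptom_scores(1L, seed = 5L))
  expect_false(identical(generate_symptom_scores(5L, seed = 1L),
                         generate_symptom_scores(5L, seed = 2L)))
})
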