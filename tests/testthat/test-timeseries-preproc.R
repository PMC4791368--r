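make_ts <- function(values, tr = 2) subject_timeseries(values, tr)

test_that("initial-volume discard trims exactly and rejects emptying", {
  ts <- make_ts(matrix(rnorm(4 * 180), 4))
  expect_identical(ncol(discard_initial_volumes(ts, 10L)$values), 170L)
  expect_identical(discard_initial_volumes(ts, 0L), ts)
  expect_error(discard_initial_volumes(ts, 180L), "discard")
  expect_error(discard_initial_volumes(ts, 200L), "discard")
})

test_that("framewise displacement follows the scalar convention", {
  n <- 20L
  tr0 <- matrix(0, n, 3)
  rot0 <- matrix(0, n, 3)
  # constant motion -> all-zero FD
  fd <- framewise_displacement(motion_trace(tr0 + 1.5, rot0 + 0.2))
  expect_identical(as.numeric(fd), rep(0, n))
  # single 0.3 mm translation step
  tr1 <- tr0
  tr1[10:n, 2] <- 0.3
  fd <- framewise_displacement(motion_trace(tr1, rot0))
  expect_equal(as.numeric(fd)[10], 0.3)
  expect_identical(sum(as.numeric(fd) != 0), 1L)
  # single 0.01 rad rotation step at 50 mm radius -> exactly 0.5 mm
  rot1 <- rot0
  rot1[5:n, 3] <- 0.01
  fd <- framewise_displacement(motion_trace(tr0, rot1))
  expect_identical(as.numeric(fd)[5], 0.5)
  expect_error(framewise_displacement(motion_trace(tr0 * NA, rot0)),
               "non-finite")
})

test_that("spike detection uses a strict threshold", {
  expect_identical(detect_spike_volumes(c(0, 0.6, 0.2)), 2L)
  expect_identical(detect_spike_volumes(c(0, 0.5, 0.49)), integer(0))
  expect_identical(detect_spike_volumes(rep(0.2, 10)), integer(0))
})

test_that("nuisance matrix has the canonical 15 + spikes layout", {
  n <- 30L
  mt <- motion_trace(matrix(rnorm(n * 3), n), matrix(rnorm(n * 3), n))
  g <- rnorm(n); w <- rnorm(n); c <- rnorm(n)
  x0 <- build_nuisance_matrix(mt, g, w, c)
  expect_identical(ncol(x0), 15L)
  x3 <- build_nuisance_matrix(mt, g, w, c, spikes = c(4L, 9L, 20L))
  expect_identical(ncol(x3), 18L)
  expect_true(all(colSums(x3[, 16:18]) == 1))
  expect_equal(x3[4, "spike_004"], 1, ignore_attr = TRUE)
  # constant motion -> zero difference columns, and all start with 0
  mt_const <- motion_trace(matrix(1, n, 3), matrix(0.5, n, 3))
  xc <- build_nuisance_matrix(mt_const, g, w, c)
  expect_true(all(xc[, 7:12] == 0))
  expect_true(all(x0[1, 7:12] == 0))
  expect_error(build_nuisance_matrix(mt, g[-1], w, c), "lengths")
})

test_that("nuisance regression removes regressor content exactly", {
  set.seed(31)
  n <- 100L
  x <- cbind(a = rnorm(n), b = rnorm(n))
  # ROI equal to a regressor -> residual identically zero
  ts <- make_ts(rbind(x[, "a"], rnorm(n)))
  out <- regress_nuisance(ts, x)
  expect_lt(max(abs(out$values[1, ])), 1e-10)
  # residuals orthogonal to every regressor
  g <- out$values %*% x
  expect_lt(max(abs(g)) / max(colSums(x^2)), 1e-10)
  # mean-zero series orthogonal to regressors passes through
  v <- rnorm(n)
  v <- qr.resid(qr(cbind(1, x)), v)
  out2 <- regress_nuisance(make_ts(rbind(v, v)), x)
  expect_equal(out2$values[1, ], v, tolerance = 1e-10,
               ignore_attr = TRUE)
  # collinear columns are pruned with names
  expect_warning(regress_nuisance(ts, cbind(x, a2 = x[, "a"])),
                 "a2")
})

test_that("residual variance matches the noise variance in simulation", {
  set.seed(77)
  n <- 120L
  ratio <- replicate(100, {
    x <- cbind(rnorm(n), rnorm(n))
    noise <- rnorm(n)
    y <- 2 * x[, 1] - 3 * x[, 2] + noise
    out <- regress_nuisance(make_ts(rbind(y, rnorm(n))), x)
    var(out$values[1, ]) / var(qr.resid(qr(cbind(1, x)), noise))
  })
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("ideal band-pass passes in-band and rejects out-of-band tones", {
  tr <- 2
  n <- 200L  # 400 s: 0.04 Hz and 0.2 Hz fall on exact DFT bins
  t <- (seq_len(n) - 1) * tr
  tone <- function(f) sin(2 * pi * f * t)
  ts_in <- make_ts(rbind(tone(0.04), tone(0.04)), tr)
  out_in <- bandpass_filter(ts_in)
  expect_lt(abs(sd(out_in$values[1, ]) / sd(ts_in$values[1, ]) - 1), 0.01)
  ts_out <- make_ts(rbind(tone(0.2), tone(0.2)), tr)
  out_out <- bandpass_filter(ts_out)
  expect_lt(sd(out_out$values[1, ]) / sd(ts_out$values[1, ]), 0.01)
  # constant series -> identically zero (mean always removed)
  out_const <- bandpass_filter(make_ts(matrix(5, 2, n), tr))
  expect_lt(max(abs(out_const$values)), 1e-10)
  expect_error(bandpass_filter(ts_in, 0.08, 0.01), "exceed")
  expect_error(bandpass_filter(ts_in, 0.01, 0.3), "Nyquist")
})

test_that("full-band refiltering of pipeline output is the identity", {
  set.seed(5)
  ts <- make_ts(matrix(rnorm(3 * 170), 3), 2)
  once <- bandpass_filter(ts, 0.01, 0.08)
  again <- bandpass_filter(once, 1e-6, 0.2499999)
  expect_equal(again$values, once$values, tolerance = 1e-8)
})

test_that("preprocess_subject runs the fixed pipeline order end to end", {
  spec <- tiny_spec(seed = 19L, spike_rate = 0.05)
  rec <- generate_functional_cohort(spec)[[1]]
  out <- preprocess_subject(rec$timeseries, rec$motion, rec$nuisance)
  expect_identical(ncol(out$timeseries$values), 170L)
  expect_length(as.numeric(out$fd), 170L)
  expect_true(all(out$spikes %in% seq_len(170L)))
  expect_named(out$qc, c("mean_fd", "n_spikes"))
  # spike volumes were regressed out: residuals at spike volumes are the
  # pre-filter zero of the one-hot regressor fit
  expect_true(out$qc[["mean_fd"]] > 0)
})
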