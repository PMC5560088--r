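make_panel <- function(data, tr = 1.5, ...) time_series_panel(data, tr = tr, ...)

test_that("tSNR is mean over sd, gates subjects, and flags degenerate ROIs", {
  set.seed(1)
  p <- make_panel(matrix(100 + rnorm(500 * 4), 500, 4))
  q <- tsnr(p)
  expect_equal(unname(q$values), rep(100, 4), tolerance = 5)
  expect_true(q$pass)
  # zero-mean series
  p0 <- make_panel(matrix(rnorm(500 * 3), 500, 3))
  expect_lt(tsnr(p0)$mean_tsnr, 1)
  # all ROIs just under the threshold excludes the subject
  p44 <- make_panel(matrix(44 + rnorm(2000 * 3, sd = 1), 2000, 3))
  q44 <- tsnr(p44, threshold = 45)
  expect_true(all(q44$values < 45))
  expect_false(q44$pass)
  expect_null(suppressMessages(panel_connectivity(p44, tsnr_threshold = 45)))
  # constant ROI reports Inf and logs
  pc <- make_panel(cbind(rep(5, 10), rnorm(10)))
  expect_message(qc <- tsnr(pc), "zero-variance")
  expect_true(is.infinite(qc$values[1]))
})

test_that("confound regression is exact OLS residualization", {
  set.seed(2)
  x <- matrix(rnorm(200 * 3) + 7, 200, 3)
  # no confounds: demeaning only
  out <- regress_confounds(make_panel(x))
  expect_equal(unname(out$data), unname(scale(x, scale = FALSE)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # ROI equal to a confound column: perfect fit
  conf <- cbind(g = rnorm(200))
  x2 <- cbind(conf[, 1], rnorm(200))
  out2 <- regress_confounds(make_panel(x2, confounds = conf))
  expect_lt(max(abs(out2$data[, 1])), 1e-10)
  # orthogonality to an injected global signal
  g <- rnorm(200)
  x3 <- matrix(rnorm(200 * 5), 200, 5) + 0.8 * g
  out3 <- regress_confounds(make_panel(x3, confounds = cbind(global = g)))
  expect_true(all(abs(cor(out3$data, g)) < 1e-6))
  # collinear confounds dropped with a warning
  expect_warning(regress_confounds(make_panel(x3, confounds = cbind(g, 2 * g))),
                 "collinear")
})

test_that("detrend and ideal band-pass behave on known signals", {
  tp <- 301; tr <- 1.5
  tt <- (seq_len(tp) - 1) * tr
  # a pure ramp vanishes
  ramp <- make_panel(matrix(5 + 0.3 * tt, ncol = 1), tr = tr)
  expect_lt(max(abs(detrend_bandpass(ramp, 0.009, 0.3)$data)), 1e-8)
  # an in-band 0.1 Hz sinusoid survives: RMS amplitude within 1% and shape
  # essentially unchanged (pointwise deviations concentrate at the window
  # edges, the unavoidable leakage of a finite-window rectangular mask)
  sig <- sin(2 * pi * 0.1 * tt)
  keep <- detrend_bandpass(make_panel(matrix(sig, ncol = 1), tr = tr),
                           0.009, 0.3)
  expect_lt(abs(sd(keep$data[, 1]) / sd(sig) - 1), 0.01)
  expect_gt(cor(keep$data[, 1], sig), 0.995)
  # a slow drift-band sinusoid is removed: the component coherent with the
  # input drops below 1% and the residual energy below 5%
  f_out <- 0.004
  slow <- sin(2 * pi * f_out * tt)
  kill <- detrend_bandpass(make_panel(matrix(slow, ncol = 1), tr = tr),
                           0.009, 0.3)
  expect_lt(abs(sum(kill$data[, 1] * slow)) / sum(slow^2), 0.01)
  expect_lt(sd(kill$data[, 1]) / sd(slow), 0.05)
  # no residual linear trend
  set.seed(3)
  out <- detrend_bandpass(make_panel(matrix(rnorm(tp * 2), tp, 2), tr = tr))
  slope <- abs(coef(lm(out$data[, 1] ~ seq_len(tp)))[2])
  expect_lt(slope, 1e-8)
  # upper edge above Nyquist is clamped with a message; bad edges rejected
  expect_message(detrend_bandpass(make_panel(matrix(rnorm(60), 30, 2), tr = tr)),
                 "Nyquist")
  expect_error(detrend_bandpass(make_panel(matrix(rnorm(60), 30, 2)), 0.2, 0.1),
               "high_hz")
})

test_that("correlation matrix is Fisher-z with clamping and zero diagonal", {
  set.seed(4)
  x <- matrix(rnorm(100 * 4), 100, 4)
  cm <- correlation_matrix(make_panel(x))
  expect_equal(diag(cm$z), rep(0, 4), ignore_attr = TRUE)
  expect_equal(cm$z[1, 2], atanh(cor(x[, 1], x[, 2])), tolerance = 1e-12)
  expect_equal(cm$z, t(cm$z))
  # duplicated ROI hits the clamp ceiling
  dup <- cbind(x, x[, 1])
  cm2 <- suppressMessages(correlation_matrix(make_panel(dup)))
  expect_equal(cm2$z[1, 5], atanh(1 - 1e-7))
  # a zero-variance ROI is an error naming the ROI
  bad <- cbind(x, const = rep(1, 100))
  expect_error(correlation_matrix(make_panel(bad)), "const")
})

test_that("upper-triangle vectorization is a row-major bijection", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- 11; m[1, 3] <- 22; m[2, 3] <- 33
  m <- m + t(m)
  fv <- vectorize_upper_triangle(m)
  expect_equal(fv$values, c(11, 22, 33))
  expect_equal(fv$index_map$i, c(1, 1, 2))
  expect_equal(fv$index_map$j, c(2, 3, 3))
  # 45 ROIs give 990 features and a perfect round trip
  set.seed(5)
  w <- matrix(rnorm(45 * 45), 45)
  w <- w + t(w); diag(w) <- 0
  fv45 <- vectorize_upper_triangle(w)
  expect_length(fv45$values, 990)
  expect_equal(unname(matrix_from_features(fv45)), w, tolerance = 1e-12)
  # asymmetric input rejected
  wa <- w; wa[2, 1] <- wa[2, 1] + 1
  expect_error(vectorize_upper_triangle(wa), "symmetric")
})

test_that("the denoising chain commutes with ROI relabelling", {
  set.seed(6)
  cfg <- cohort_config(n_per_group = 1, n_rois = 9, module_sizes = c(3, 3, 3),
                       n_timepoints = 60,
                       confound_spec = list(global_amp = 1))
  s <- simulate_subject(cfg, "groupA", rng_seed = 4)
  cm <- suppressMessages(panel_connectivity(s$panel))
  perm <- sample(9)
  pp <- time_series_panel(s$panel$data[, perm], tr = s$panel$tr,
                          roi_names = s$panel$roi_names[perm],
                          confounds = s$panel$confounds,
                          subject_id = s$panel$subject_id)
  cmp <- suppressMessages(panel_connectivity(pp))
  expect_equal(cmp$z, cm$z[perm, perm], tolerance = 1e-10)
})

test_that("off-diagonal z magnitude shrinks with scan length for white signal", {
  cfg100 <- cohort_config(n_per_group = 1, n_rois = 20, module_sizes = 20,
                          intra_r = c(0, 0), inter_r = c(0, 0),
                          n_timepoints = 100, seed = 1)
  cfg1000 <- cohort_config(n_per_group = 1, n_rois = 20, module_sizes = 20,
                           intra_r = c(0, 0), inter_r = c(0, 0),
                           n_timepoints = 1000, seed = 1)
  z100 <- suppressMessages(panel_connectivity(
    simulate_subject(cfg100, "groupA", 2)$panel))$z
  z1000 <- suppressMessages(panel_connectivity(
    simulate_subject(cfg1000, "groupA", 2)$panel))$z
  expect_lt(mean(abs(z1000[upper.tri(z1000)])),
            mean(abs(z100[upper.tri(z100)])))
})

test_that("parcel averaging collapses labelled columns", {
  x <- cbind(rep(1, 5), rep(3, 5), rep(10, 5), rnorm(5))
  m <- average_parcels(x, c(1, 1, 2, 0))
  expect_equal(ncol(m), 2)
  expect_equal(m[, 1], rep(2, 5), ignore_attr = TRUE)
  expect_equal(m[, 2], rep(10, 5), ignore_attr = TRUE)
})

test_that("connectivity matrices round-trip through CSV", {
  set.seed(7)
  x <- matrix(rnorm(60 * 5), 60, 5)
  cm <- correlation_matrix(make_panel(x))
  path <- withr::local_tempfile(fileext = ".csv")
  write_connectivity_csv(cm, path)
  back <- read_connectivity_csv(path)
  expect_equal(back$z, cm$z, tolerance = 1e-12)
})
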