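test_that("background subtraction removes the series elementwise", {
  tr <- toy_trace(rbind(c(5, 6, 7)), stage = "raw")
  out <- subtract_background(tr, c(1, 1, 1))
  expect_equal(unname(out$values[1, ]), c(4, 5, 6))
  expect_equal(out$stage, "background_subtracted")

  out0 <- subtract_background(tr, c(0, 0, 0))
  expect_equal(out0$values, tr$values)

  expect_error(subtract_background(tr, c(1, 1, 1, 1)),
               "background length \\(4\\).*frame count \\(3\\)")
})

test_that("exponential detrending flattens a pure exponential and keeps constants", {
  tt <- (0:199) / 10
  y <- 80 * exp(-tt / 5) + 40
  tr <- toy_trace(rbind(y, y), stage = "raw")
  out <- detrend_exponential(tr)
  # an exact-model trace becomes constant at its own mean
  expect_equal(unname(out$values[1, ]), rep(mean(y), 200), tolerance = 1e-6)
  rep <- attr(out, "detrend_report")
  expect_equal(rep$tau[1], 5, tolerance = 0.01)

  const <- toy_trace(rbind(rep(7, 50)), stage = "raw")
  out2 <- detrend_exponential(const)
  expect_equal(unname(out2$values[1, ]), rep(7, 50))

  expect_error(detrend_exponential(toy_trace(rbind(1:5), stage = "raw")),
               "at least 10 frames")
})

test_that("detrending recovers a planted photobleaching time constant", {
  cfg <- synth_config(
    n_animals = 1, n_neurons = 5, n_artifact_rois = 0, seed = 3,
    calibration = list(event_amplitude = 30, bleach_amplitude = 800),
    regime_V = regime_hub_centric(noise_sd = 0, bleach_tau = 300),
    regime_VT = regime_distributed(noise_sd = 0, bleach_tau = 300)
  )
  ds <- generate_dataset(cfg)
  for (cond in c("V", "VT")) {
    rep <- attr(detrend_exponential(ds$traces$animal_01[[cond]]),
                "detrend_report")
    expect_true(all(rep$method == "exponential"))
    expect_true(all(abs(rep$tau - 300) / 300 < 0.20))
  }
})

test_that("scaling multiplies values and validates its factor", {
  tr <- toy_trace(rbind(c(4000, 2000, 1000)), stage = "raw")
  out <- scale_traces(tr, 0.001)
  expect_equal(unname(out$values[1, ]), c(4, 2, 1))
  expect_equal(out$stage, "scaled")
  expect_equal(scale_traces(tr, 1)$values, tr$values)
  expect_error(scale_traces(tr, -0.001), "positive")
})

test_that("QC retains only ROIs passing both thresholds in both conditions", {
  mk <- function(v1, v2, v3, cond) {
    # rows engineered to given variance/max: rescale a fixed shape
    base <- c(-1, 0, 1, 0, -1, 1, 0, -1, 0, 1)
    shape <- function(target_var, target_max) {
      x <- base * sqrt(target_var / var(base))
      x + (target_max - max(x))
    }
    toy_trace(rbind(shape(v1[1], v1[2]), shape(v2[1], v2[2]),
                    shape(v3[1], v3[2])),
              stage = "scaled", condition = cond,
              roi_ids = c("a", "b", "c"))
  }
  # a: passes everywhere; b: variance fails in V only; c: max fails in VT
  tv <- mk(c(1.5, 5.0), c(0.5, 5.0), c(1.5, 5.0), "V")
  tvt <- mk(c(1.5, 5.0), c(1.5, 5.0), c(1.5, 3.0), "VT")
  qc <- qc_filter(tv, tvt)
  expect_equal(qc$retained, "a")
  expect_equal(qc$report$pass_variance, c(TRUE, FALSE, TRUE))
  expect_equal(qc$report$pass_max, c(TRUE, TRUE, FALSE))

  # symmetric in conditions
  tvt2 <- tvt
  tvt2$condition <- "V"
  tv2 <- tv
  tv2$condition <- "VT"
  qc_swapped <- qc_filter(tvt2, tv2)
  expect_equal(qc_swapped$retained, qc$retained)

  tv_bad <- tv
  tv_bad$roi_ids <- c("a", "b", "z")
  rownames(tv_bad$values) <- tv_bad$roi_ids
  expect_error(qc_filter(tv_bad, tvt), "roi_ids differ")
})

test_that("Savitzky-Golay smoothing reproduces polynomials and matches windowed fits", {
  tt <- 1:100
  cubic <- 2 + 0.5 * tt - 0.02 * tt^2 + 1e-4 * tt^3
  tr <- toy_trace(rbind(cubic), stage = "scaled")
  out <- smooth_savgol(tr, window = 21, order = 3)
  expect_equal(unname(out$values[1, ]), cubic, tolerance = 1e-9)
  expect_equal(out$stage, "smoothed")

  const <- toy_trace(rbind(rep(3, 50)), stage = "scaled")
  expect_equal(unname(smooth_savgol(const, 21, 3)$values[1, ]), rep(3, 50))

  # step input: interior points equal the direct per-window polynomial fit
  step <- c(rep(0, 50), rep(1, 50))
  sm <- smooth_savgol(toy_trace(rbind(step), stage = "scaled"), 21, 3)
  half <- 10
  for (i in c(45, 50, 51, 56)) {
    win <- (i - half):(i + half)
    fit <- lm(y ~ poly(x, 3, raw = TRUE),
              data = data.frame(x = win - i, y = step[win]))
    expect_equal(unname(sm$values[1, i]), unname(coef(fit)[1]),
                 tolerance = 1e-9)
  }

  expect_error(smooth_savgol(tr, window = 20, order = 3), "odd")
  expect_error(smooth_savgol(tr, window = 3, order = 3), "exceed")
  expect_error(smooth_savgol(toy_trace(rbind(1:10), stage = "scaled"), 21, 3),
               "fewer than the window")
})

test_that("min-max normalization spans [0, 1] exactly and flags constants", {
  tr <- toy_trace(rbind(c(2, 4, 6)), stage = "smoothed")
  out <- normalize_minmax(tr)
  expect_equal(unname(out$values[1, ]), c(0, 0.5, 1))
  expect_equal(out$stage, "normalized")

  spanning <- toy_trace(rbind(c(0, 0.25, 1, 0.5)), stage = "smoothed")
  expect_equal(normalize_minmax(spanning)$values, spanning$values)

  expect_warning(
    out2 <- normalize_minmax(toy_trace(rbind(c(1, 1, 1), c(1, 2, 3)),
                                       stage = "smoothed")),
    "constant"
  )
  expect_equal(unname(out2$values[1, ]), c(0, 0, 0))
  expect_equal(attr(out2, "degenerate_rois"), "roi_001")

  # property: every non-degenerate row spans exactly [0, 1]
  set.seed(42)
  for (i in 1:20) {
    vals <- matrix(rnorm(5 * 30, sd = runif(1, 0.1, 50)), 5, 30)
    norm <- normalize_minmax(toy_trace(vals, stage = "smoothed"))
    expect_equal(unname(apply(norm$values, 1, min)), rep(0, 5))
    expect_equal(unname(apply(norm$values, 1, max)), rep(1, 5))
  }
})

test_that("processing stages cannot be reordered or revisited", {
  tr <- toy_trace(rbind(rnorm(30)), stage = "raw")
  sc <- scale_traces(tr, 0.001)
  expect_error(subtract_background(sc, rep(0, 30)), "expects a trace at stage")
  expect_error(detrend_exponential(sc), "expects a trace at stage")
  sm <- smooth_savgol(toy_trace(rbind(rnorm(30)), stage = "scaled"), 5, 2)
  expect_error(scale_traces(sm, 0.001), "expects a trace at stage")
  expect_error(qc_filter(sm, sm), "expects a trace at stage")
  nm <- normalize_minmax(sm)
  expect_error(smooth_savgol(nm, 5, 2), "expects a trace at stage")
})

test_that("the paired preprocessing wrapper applies the documented order and logs counts", {
  cfg <- small_synth_config(seed = 4, n_neurons = 20, n_repeats = 2)
  ds <- generate_dataset(cfg)
  pre <- preprocess_traces(ds$traces$animal_01$V, ds$traces$animal_01$VT)
  expect_equal(pre$V$stage, "normalized")
  expect_equal(pre$smoothed_V$stage, "smoothed")
  expect_equal(sort(pre$V$roi_ids), sort(pre$qc$retained))
  expect_true(any(grepl("QC: 30 ROIs in", pre$log)))
  # artifacts are exactly the exclusions
  planted <- ds$ground_truth$animal_01$V$artifact_ids
  expect_setequal(setdiff(ds$traces$animal_01$V$roi_ids, pre$qc$retained),
                  planted)
})
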