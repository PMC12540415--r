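test_that("identical seeds produce identical datasets", {
  cfg <- small_synth_config(seed = 0, n_neurons = 15, n_repeats = 1)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$traces, ds2$traces)
  expect_identical(ds1$ground_truth, ds2$ground_truth)
  ds3 <- generate_dataset(small_synth_config(seed = 1, n_neurons = 15,
                                             n_repeats = 1))
  expect_false(identical(ds1$traces, ds3$traces))
})

test_that("hub coupling row sums strictly exceed every non-hub row sum", {
  cfg <- small_synth_config(seed = 2, n_neurons = 50)
  ds <- generate_dataset(cfg)
  truth <- ds$ground_truth$animal_01$V
  rs <- rowSums(truth$coupling)
  expect_length(truth$hub_indices, 5)
  expect_true(min(rs[truth$hub_indices]) > max(rs[-truth$hub_indices]))
  # hub and artifact index sets are disjoint, artifacts sit outside coupling
  expect_length(intersect(truth$hub_indices, truth$artifact_indices), 0)
  # coupling matrix is symmetric with zero diagonal
  expect_equal(truth$coupling, t(truth$coupling))
  expect_true(all(diag(truth$coupling) == 0))
})

test_that("zero background coupling yields an empty latent matrix and uncorrelated traces", {
  cfg <- synth_config(
    n_animals = 1, n_neurons = 20, n_repeats = 3, n_artifact_rois = 0,
    seed = 3,
    regime_VT = regime_distributed(background_coupling = 0,
                                   coupling_jitter = 0),
    # flat drive: without stimulus-rate modulation no shared signal remains
    calibration = list(rate_stim = 0.3, rate_isi = 0.3)
  )
  ds <- generate_dataset(cfg)
  truth <- ds$ground_truth$animal_01$VT
  expect_true(all(truth$coupling == 0))
  tr <- normalize_minmax(smooth_savgol(scale_traces(ds$traces$animal_01$VT)))
  r <- cor(t(tr$values))
  expect_lt(mean(abs(r[upper.tri(r)])), 0.08)
})

test_that("non-integer frame counts are rejected naming the parameters", {
  expect_error(synth_config(n_directions = 1, n_repeats = 1,
                            frame_rate = 0.3),
               "not an integer.*frame_rate", ignore.case = TRUE)
})

test_that("hub pairs correlate more strongly than non-hub pairs in the hub-centric regime", {
  for (seed in 1:5) {
    cfg <- small_synth_config(seed = seed)
    ds <- generate_dataset(cfg)
    truth <- ds$ground_truth$animal_01$V
    tr <- normalize_minmax(smooth_savgol(scale_traces(
      detrend_exponential(ds$traces$animal_01$V))))
    genuine <- tr$roi_ids[seq_len(cfg$n_neurons)]
    r <- cor(t(tr$values[genuine, ]))
    hubs <- truth$hub_indices
    hub_pairs <- r[hubs, hubs][upper.tri(r[hubs, hubs])]
    non <- setdiff(seq_len(cfg$n_neurons), hubs)
    non_pairs <- r[non, non][upper.tri(r[non, non])]
    expect_gt(mean(hub_pairs), mean(non_pairs))
  }
})

test_that("artifact ROIs violate a QC threshold by construction, per class", {
  for (seed in 1:3) {
    cfg <- small_synth_config(seed = seed, n_neurons = 10)
    ds <- generate_dataset(cfg)
    tr <- scale_traces(detrend_exponential(ds$traces$animal_01$V))
    truth <- ds$ground_truth$animal_01$V
    vars <- apply(tr$values, 1, var)
    maxs <- apply(tr$values, 1, max)
    spikes <- truth$artifact_indices[truth$artifact_class == "spike_like"]
    noise <- truth$artifact_indices[truth$artifact_class == "white_noise"]
    # spike-like: rare large transients leave variance low but the max high
    expect_true(all(vars[spikes] < 1.0))
    expect_true(all(maxs[spikes] >= 4.0))
    # white-noise: variance high but the (clipped) maximum stays small
    expect_true(all(vars[noise] >= 1.0))
    expect_true(all(maxs[noise] < 4.0))
  }
})

test_that("trial onsets follow the 2 s stimulus / 4 s ISI grid", {
  cfg <- synth_config(n_animals = 1)
  on <- trial_onsets(cfg)
  expect_length(on, 12 * 10)
  expect_equal(on[1:3], c(0, 6, 12))
  expect_equal(cfg$total_frames, 12 * 10 * 6 * 10)
})

test_that("calcium kernel peaks within about a second and is unit-normalized", {
  k <- calcium_kernel(frame_rate = 10)
  expect_equal(max(k), 1)
  expect_lt(which.max(k) / 10, 1.0)
  expect_gt(which.max(k) / 10, 0.1)
})
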