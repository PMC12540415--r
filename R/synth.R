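#' Latent coupling regime parameters
#'
#' Describes the latent functional-coupling architecture used by the
#' synthetic generator for one stimulation condition. Two canonical regimes
#' are provided: a hub-centric regime ([regime_hub_centric()]) in which a few
#' hub neurons couple strongly to the whole population and the remaining
#' neurons form modules, and a distributed regime ([regime_distributed()]) in
#' which all pairs share an elevated, roughly uniform coupling.
#'
#' @param n_hubs number of hub neurons (0 for a distributed regime).
#' @param hub_coupling coupling in `[0, 1]` between a hub and every other
#'   neuron.
#' @param background_coupling baseline coupling in `[0, 1]` between neurons
#'   in different modules (hub-centric) or between all pairs (distributed).
#' @param n_modules number of modules the non-hub neurons are partitioned
#'   into.
#' @param within_module_coupling coupling in `[0, 1]` between non-hub neurons
#'   of the same module.
#' @param hub_amplitude_gain multiplicative gain (>= 1) applied to the event
#'   amplitude of hub neurons, planting a response hierarchy at the hubs.
#' @param noise_sd standard deviation of additive Gaussian detector noise, in
#'   raw fluorescence units.
#' @param bleach_tau time constant (seconds) of the slow exponential
#'   photobleaching trend.
#' @param coupling_jitter relative jitter applied to pairwise couplings in the
#'   distributed regime: each coupling is multiplied by a value drawn
#'   uniformly from `[1 - coupling_jitter, 1 + coupling_jitter]`.
#' @param tuning_strength direction-tuning depth in `[0, 1]` of non-hub
#'   neurons: 0 means an untuned response to every stimulus direction, 1 a
#'   fully tuned response `((1 + cos(d - theta)) / 2)^2` around the neuron's
#'   preferred direction `theta`. In the hub-centric regime neurons of the
#'   same module share a preferred direction (like-to-like functional
#'   coupling) and hubs are untuned integrators; in the distributed regime
#'   preferred directions are drawn uniformly.
#' @return An object of class `regime_params`.
#' @export
regime_params <- function(n_hubs = 0L, hub_coupling = 0,
                          background_coupling = 0.1, n_modules = 1L,
                          within_module_coupling = background_coupling,
                          hub_amplitude_gain = 1, noise_sd = 150,
                          bleach_tau = 600, coupling_jitter = 0.1,
                          tuning_strength = 0.5) {
  couplings <- c(hub_coupling = hub_coupling,
                 background_coupling = background_coupling,
                 within_module_coupling = within_module_coupling)
  bad <- couplings < 0 | couplings > 1
  if (any(bad)) {
    stop("couplings must lie in [0, 1]; offending: ",
         paste(names(couplings)[bad], collapse = ", "))
  }
  if (n_hubs < 0 || n_modules < 1) stop("n_hubs >= 0 and n_modules >= 1 required")
  if (n_hubs > 0 && hub_coupling <= background_coupling) {
    stop("a hub-centric regime requires hub_coupling > background_coupling")
  }
  if (hub_amplitude_gain < 1) stop("hub_amplitude_gain must be >= 1")
  if (noise_sd < 0 || bleach_tau <= 0) stop("noise_sd >= 0 and bleach_tau > 0 required")
  if (coupling_jitter < 0 || coupling_jitter >= 1) stop("coupling_jitter must lie in [0, 1)")
  if (tuning_strength < 0 || tuning_strength > 1) stop("tuning_strength must lie in [0, 1]")
  structure(
    list(n_hubs = as.integer(n_hubs), hub_coupling = hub_coupling,
         background_coupling = background_coupling,
         n_modules = as.integer(n_modules),
         within_module_coupling = within_module_coupling,
         hub_amplitude_gain = hub_amplitude_gain, noise_sd = noise_sd,
         bleach_tau = bleach_tau, coupling_jitter = coupling_jitter,
         tuning_strength = tuning_strength),
    class = "regime_params"
  )
}

#' @rdname regime_params
#' @export
regime_hub_centric <- function(n_hubs = 5L, hub_coupling = 0.55,
                               background_coupling = 0.05, n_modules = 5L,
                               within_module_coupling = 0.30,
                               hub_amplitude_gain = 2, noise_sd = 150,
                               bleach_tau = 600, coupling_jitter = 0,
                               tuning_strength = 1) {
  regime_params(n_hubs = n_hubs, hub_coupling = hub_coupling,
                background_coupling = background_coupling,
                n_modules = n_modules,
                within_module_coupling = within_module_coupling,
                hub_amplitude_gain = hub_amplitude_gain, noise_sd = noise_sd,
                bleach_tau = bleach_tau, coupling_jitter = coupling_jitter,
                tuning_strength = tuning_strength)
}

#' @rdname regime_params
#' @export
regime_distributed <- function(background_coupling = 0.45, noise_sd = 150,
                               bleach_tau = 600, coupling_jitter = 0.1,
                               tuning_strength = 0.3) {
  regime_params(n_hubs = 0L, hub_coupling = 0,
                background_coupling = background_coupling, n_modules = 1L,
                within_module_coupling = background_coupling,
                hub_amplitude_gain = 1, noise_sd = noise_sd,
                bleach_tau = bleach_tau, coupling_jitter = coupling_jitter,
                tuning_strength = tuning_strength)
}

#' Synthetic study configuration
#'
#' Parameters of the synthetic paired-condition calcium-imaging study. The
#' defaults emulate an 11-animal experiment with 150 neurons per field of
#' view, drifting-grating trials of 2 s stimulus followed by a 4 s
#' inter-stimulus interval, 12 directions, 10 repeats, sampled at 10 Hz, with
#' a hub-centric latent architecture under unimodal visual stimulation (`V`)
#' and a distributed architecture under bimodal visuotactile stimulation
#' (`VT`). Contaminant ROIs (spike-like and white-noise artifacts) are
#' appended to exercise the downstream quality-control filter.
#'
#' The `calibration` list holds the raw-fluorescence scale of the generator:
#' `baseline` (constant offset), `bleach_amplitude` (initial amplitude of the
#' exponential bleaching trend), `event_amplitude` (peak fluorescence of a
#' single calcium event), `rate_stim` / `rate_isi` (event rates in events/s
#' during stimulus and inter-stimulus windows), and the calcium kernel time
#' constants `kernel_rise` / `kernel_decay` (seconds). These values are
#' calibrated so that, after the standard 0.001 scaling, genuine ROIs satisfy
#' variance >= 1 and maximum response >= 4 with a comfortable margin.
#'
#' @param n_animals number of animals (paired recordings per animal).
#' @param n_neurons genuine neurons per animal.
#' @param frame_rate imaging rate, Hz.
#' @param n_directions number of stimulus directions per repeat.
#' @param stim_duration stimulus duration per trial, seconds.
#' @param isi_duration inter-stimulus interval per trial, seconds.
#' @param n_repeats number of repeats of the direction sequence.
#' @param regime_V,regime_VT [regime_params()] for each condition.
#' @param n_artifact_rois number of contaminant ROIs appended per animal
#'   (alternating spike-like and white-noise classes).
#' @param seed integer seed; all randomness in [generate_dataset()] flows
#'   from it.
#' @param calibration named list of raw-fluorescence calibration constants
#'   (see Details).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_animals = 11L, n_neurons = 150L, frame_rate = 10,
                         n_directions = 12L, stim_duration = 2,
                         isi_duration = 4, n_repeats = 10L,
                         regime_V = regime_hub_centric(),
                         regime_VT = regime_distributed(),
                         n_artifact_rois = 10L, seed = 1L,
                         calibration = list()) {
  counts <- c(n_animals = n_animals, n_neurons = n_neurons,
              n_directions = n_directions, n_repeats = n_repeats)
  if (any(counts < 1)) {
    stop("all counts must be >= 1; offending: ",
         paste(names(counts)[counts < 1], collapse = ", "))
  }
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  if (n_artifact_rois < 0) stop("n_artifact_rois must be >= 0")
  total_frames <- n_directions * n_repeats * (stim_duration + isi_duration) *
    frame_rate
  if (abs(total_frames - round(total_frames)) > 1e-9) {
    stop("total frame count n_directions * n_repeats * (stim_duration + ",
         "isi_duration) * frame_rate = ", total_frames,
         " is not an integer; adjust stim_duration (", stim_duration,
         "), isi_duration (", isi_duration, ") or frame_rate (", frame_rate,
         ")")
  }
  stopifnot(inherits(regime_V, "regime_params"),
            inherits(regime_VT, "regime_params"))
  calib <- utils::modifyList(
    list(baseline = 1000, bleach_amplitude = 500, event_amplitude = 6000,
         rate_stim = 0.8, rate_isi = 0.1, kernel_rise = 0.1,
         kernel_decay = 1.0, share_scale = 1.5, tuning_exponent = 4,
         expression_sd = 0.25),
    calibration
  )
  structure(
    list(n_animals = as.integer(n_animals), n_neurons = as.integer(n_neurons),
         frame_rate = frame_rate, n_directions = as.integer(n_directions),
         stim_duration = stim_duration, isi_duration = isi_duration,
         n_repeats = as.integer(n_repeats), regime_V = regime_V,
         regime_VT = regime_VT, n_artifact_rois = as.integer(n_artifact_rois),
         seed = as.integer(seed), calibration = calib,
         total_frames = as.integer(round(total_frames))),
    class = "synth_config"
  )
}

#' Trial onset times of the stimulation protocol
#'
#' @param config a [synth_config()].
#' @return Numeric vector of stimulus onset times in seconds, one per trial
#'   (`n_directions * n_repeats` trials; each trial is `stim_duration`
#'   seconds of stimulus followed by `isi_duration` seconds of ISI).
#' @export
trial_onsets <- function(config) {
  trial_len <- config$stim_duration + config$isi_duration
  (seq_len(config$n_directions * config$n_repeats) - 1) * trial_len
}

#' Difference-of-exponentials calcium impulse response
#'
#' @param frame_rate sampling rate, Hz.
#' @param rise,decay rise and decay time constants, seconds.
#' @return Numeric vector of kernel samples, normalized to unit peak, covering
#'   five decay time constants.
#' @export
calcium_kernel <- function(frame_rate, rise = 0.1, decay = 1.0) {
  tt <- seq(0, 5 * decay, by = 1 / frame_rate)
  k <- exp(-tt / decay) - exp(-tt / rise)
  k / max(k)
}

# Build the latent coupling matrix, hub indices, module assignment and
# direction tuning for one regime. Hub indices refer to genuine neurons only.
# In the hub-centric regime, neurons of the same module share a preferred
# direction (like-to-like coupling) and hubs are untuned; in the distributed
# regime preferred directions are uniform random.
.latent_coupling <- function(regime, n_neurons) {
  C <- matrix(regime$background_coupling, n_neurons, n_neurons)
  theta <- stats::runif(n_neurons, 0, 2 * pi)
  tuning <- rep(regime$tuning_strength, n_neurons)
  if (regime$n_hubs > 0) {
    if (regime$n_hubs > n_neurons) {
      stop("n_hubs (", regime$n_hubs, ") cannot exceed n_neurons (",
           n_neurons, ")")
    }
    hubs <- sort(sample.int(n_neurons, regime$n_hubs))
    non_hubs <- setdiff(seq_len(n_neurons), hubs)
    modules <- integer(n_neurons)
    modules[non_hubs] <- rep_len(seq_len(regime$n_modules), length(non_hubs))
    module_theta <- 2 * pi * (seq_len(regime$n_modules) - 1) / regime$n_modules
    for (m in seq_len(regime$n_modules)) {
      idx <- which(modules == m)
      C[idx, idx] <- regime$within_module_coupling
      theta[idx] <- module_theta[m]
    }
    C[hubs, ] <- regime$hub_coupling
    C[, hubs] <- regime$hub_coupling
    tuning[hubs] <- 0  # hubs integrate across directions
  } else {
    hubs <- integer(0)
    modules <- rep(1L, n_neurons)
    if (regime$coupling_jitter > 0 && n_neurons > 1) {
      jit <- matrix(1, n_neurons, n_neurons)
      jit[upper.tri(jit)] <- stats::runif(sum(upper.tri(jit)),
                                          1 - regime$coupling_jitter,
                                          1 + regime$coupling_jitter)
      jit[lower.tri(jit)] <- t(jit)[lower.tri(jit)]
      C <- C * jit
    }
  }
  diag(C) <- 0
  list(coupling = C, hub_indices = hubs, module_assignment = modules,
       preferred_direction = theta, tuning_strength = tuning)
}

# Simulate one trace matrix (genuine neurons + artifacts) for one
# animal/condition under a regime. Returns the trace and its ground truth.
.simulate_condition <- function(config, regime, condition, animal_id,
                                expr_gain) {
  n <- config$n_neurons
  nf <- config$total_frames
  fr <- config$frame_rate
  calib <- config$calibration
  lat <- .latent_coupling(regime, n)

  # stimulus-locked per-neuron, per-frame event rate (events/frame): during
  # the stimulus window of a trial with direction d, neuron i fires at
  # rate_isi + (rate_stim - rate_isi) * g_i(d), where the direction gain is
  # g_i(d) = (1 - ts_i) + ts_i * ((1 + cos(d - theta_i)) / 2)^2
  tt <- (seq_len(nf) - 1) / fr
  trial_len <- config$stim_duration + config$isi_duration
  in_stim <- (tt %% trial_len) < config$stim_duration
  trial_of_frame <- pmin(floor(tt / trial_len) + 1L,
                         config$n_directions * config$n_repeats)
  dir_of_trial <- rep_len(2 * pi * (seq_len(config$n_directions) - 1) /
                            config$n_directions,
                          config$n_directions * config$n_repeats)
  dir_of_frame <- dir_of_trial[trial_of_frame]
  ts <- lat$tuning_strength
  texp <- calib$tuning_exponent
  gain <- (1 - ts) +
    ts * outer(lat$preferred_direction, dir_of_frame,
               function(th, d) ((1 + cos(d - th)) / 2)^texp)
  rate <- matrix(calib$rate_isi / fr, n, nf)
  stim_cols <- which(in_stim)
  rate[, stim_cols] <- (calib$rate_isi +
    (calib$rate_stim - calib$rate_isi) * gain[, stim_cols]) / fr

  # own events, then event sharing: each event of neuron i is copied into
  # neuron j with probability proportional to the latent coupling C[i, j].
  # The single proportionality constant keeps the total copied event mass a
  # neuron receives at most `share_scale` times its own, so traces retain
  # private variance instead of collapsing onto the population average.
  E <- matrix(stats::rpois(n * nf, as.vector(rate)), n, nf)
  max_row <- max(rowSums(lat$coupling))
  share_p <- if (max_row > 0) {
    pmin(lat$coupling * (calib$share_scale / max_row), 1)
  } else {
    lat$coupling * 0
  }
  Ftot <- E
  for (i in seq_len(n)) {
    active <- which(E[i, ] > 0L)
    if (!length(active)) next
    sizes <- E[i, active]
    copied <- matrix(
      stats::rbinom(n * length(active), size = rep(sizes, each = n),
                    prob = rep(share_p[, i], times = length(active))),
      n, length(active)
    )
    Ftot[, active] <- Ftot[, active] + copied
  }

  # convolve with the calcium kernel
  k <- calcium_kernel(fr, calib$kernel_rise, calib$kernel_decay)
  sig <- t(apply(Ftot, 1L, function(x) {
    stats::convolve(x, rev(k), type = "open")[seq_len(nf)]
  }))

  amp <- calib$event_amplitude * expr_gain
  if (length(lat$hub_indices)) {
    amp[lat$hub_indices] <- amp[lat$hub_indices] * regime$hub_amplitude_gain
  }
  bleach <- calib$bleach_amplitude * exp(-tt / regime$bleach_tau)
  values <- sig * amp +
    matrix(bleach, n, nf, byrow = TRUE) + calib$baseline
  if (regime$noise_sd > 0) {
    values <- values + matrix(stats::rnorm(n * nf, sd = regime$noise_sd), n, nf)
  }

  roi_ids <- sprintf("roi_%03d", seq_len(n))

  # contaminant ROIs: spike-like (near-constant with rare large transients,
  # low variance) and white-noise (high variance, clipped low maximum)
  n_art <- config$n_artifact_rois
  artifact_class <- character(0)
  if (n_art > 0) {
    artifact_class <- rep_len(c("spike_like", "white_noise"), n_art)
    art <- matrix(0, n_art, nf)
    for (a in seq_len(n_art)) {
      if (artifact_class[a] == "spike_like") {
        row <- 500 + stats::rnorm(nf, sd = 20)
        spikes <- sample.int(nf, 3L)
        row[spikes] <- stats::runif(3L, 7000, 9000)
      } else {
        row <- pmin(500 + stats::rnorm(nf, sd = 2000), 3200)
      }
      art[a, ] <- row
    }
    art_ids <- sprintf("art_%s_%02d",
                       ifelse(artifact_class == "spike_like", "spk", "wns"),
                       seq_len(n_art))
    values <- rbind(values, art)
    roi_ids <- c(roi_ids, art_ids)
  }

  trace <- trace_matrix(values, roi_ids = roi_ids, frame_rate = fr,
                        condition = condition, animal_id = animal_id,
                        stage = "raw")
  truth <- list(
    coupling = lat$coupling,
    hub_indices = lat$hub_indices,
    module_assignment = lat$module_assignment,
    preferred_direction = lat$preferred_direction,
    tuning_strength = lat$tuning_strength,
    artifact_indices = if (n_art > 0) n + seq_len(n_art) else integer(0),
    artifact_class = artifact_class,
    hub_ids = roi_ids[lat$hub_indices],
    artifact_ids = if (n_art > 0) roi_ids[n + seq_len(n_art)] else character(0)
  )
  list(trace = trace, truth = truth)
}

#' Generate a synthetic paired-condition calcium-imaging dataset
#'
#' Simulates, for each animal, a pair of raw fluorescence trace matrices over
#' the same ROI set: condition `V` under `config$regime_V` and condition `VT`
#' under `config$regime_VT`. Events are drawn from a stimulus-locked,
#' direction-tuned Poisson process per neuron (see [regime_params()]) and
#' shared between coupled pairs with probability equal to the latent
#' coupling, so that the pairwise correlation structure of the traces
#' reflects the latent architecture (a common-input model; no spiking
#' dynamics are simulated). Event trains are convolved with a
#' difference-of-exponentials calcium kernel, hub amplitudes are multiplied
#' by the regime's `hub_amplitude_gain`, and a slow exponential bleaching
#' trend plus Gaussian noise are added. Contaminant ROIs are appended last.
#'
#' All randomness flows from `config$seed`: identical configurations produce
#' identical datasets.
#'
#' @param config a [synth_config()].
#' @return An object of class `synth_dataset`: a list with elements `traces`
#'   (per animal, a list with `V` and `VT` [trace_matrix()] objects),
#'   `ground_truth` (per animal, per condition: latent coupling matrix, hub
#'   indices/ids, module assignment, artifact indices/ids and classes) and
#'   `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)
  animal_ids <- sprintf("animal_%02d", seq_len(config$n_animals))
  traces <- vector("list", config$n_animals)
  truth <- vector("list", config$n_animals)
  names(traces) <- names(truth) <- animal_ids
  for (a in seq_len(config$n_animals)) {
    # indicator expression level is a property of the neuron, shared across
    # the paired conditions
    expr_gain <- exp(stats::rnorm(config$n_neurons,
                                  sd = config$calibration$expression_sd))
    v <- .simulate_condition(config, config$regime_V, "V", animal_ids[a],
                             expr_gain)
    vt <- .simulate_condition(config, config$regime_VT, "VT", animal_ids[a],
                              expr_gain)
    traces[[a]] <- list(V = v$trace, VT = vt$trace)
    truth[[a]] <- list(V = v$truth, VT = vt$truth)
  }
  structure(list(traces = traces, ground_truth = truth, config = config),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cfg <- x$config
  cat("<synth_dataset> ", cfg$n_animals, " animals x 2 conditions, ",
      cfg$n_neurons, " neurons + ", cfg$n_artifact_rois, " artifact ROIs, ",
      cfg$total_frames, " frames @ ", cfg$frame_rate, " Hz (seed ",
      cfg$seed, ")\n", sep = "")
  invisible(x)
}
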