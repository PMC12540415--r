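#' Preprocessing configuration
#'
#' Settings for the trace preprocessing and ROI quality-control pipeline.
#'
#' @param scale_factor multiplicative scaling applied to raw response values
#'   before quality control (default 0.001).
#' @param var_threshold minimum variance of the scaled trace for an ROI to be
#'   considered genuine (default 1.0; targets spike-like artifacts, whose
#'   rare large transients leave the overall variance low).
#' @param max_threshold minimum maximum response of the scaled trace (default
#'   4.0; targets white-noise ROIs, whose variance is high but whose maximum
#'   stays small).
#' @param savgol_window Savitzky-Golay window length in frames. Must be odd
#'   and larger than `savgol_order`; the default 21 is the closest valid
#'   width to a nominal 20-frame window.
#' @param savgol_order Savitzky-Golay polynomial order (default 3).
#' @param detrend `"exponential"` (default) or `"none"`.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(scale_factor = 0.001, var_threshold = 1.0,
                              max_threshold = 4.0, savgol_window = 21L,
                              savgol_order = 3L,
                              detrend = c("exponential", "none")) {
  detrend <- match.arg(detrend)
  if (scale_factor <= 0) stop("scale_factor must be > 0")
  if (var_threshold < 0 || max_threshold < 0) stop("thresholds must be >= 0")
  if (savgol_window %% 2 == 0) {
    stop("savgol_window must be odd, got ", savgol_window)
  }
  if (savgol_window <= savgol_order) {
    stop("savgol_window (", savgol_window, ") must exceed savgol_order (",
         savgol_order, ")")
  }
  structure(
    list(scale_factor = scale_factor, var_threshold = var_threshold,
         max_threshold = max_threshold,
         savgol_window = as.integer(savgol_window),
         savgol_order = as.integer(savgol_order), detrend = detrend),
    class = "preprocess_config"
  )
}

#' Subtract a background fluorescence series
#'
#' Subtracts, frame by frame, the mean fluorescence of an adjacent cell-free
#' region from every ROI trace, correcting for ambient background.
#'
#' @param trace a raw [trace_matrix()].
#' @param background numeric vector of per-frame background fluorescence; must
#'   have exactly one value per frame.
#' @return The trace with the background removed, at stage
#'   `background_subtracted`.
#' @export
subtract_background <- function(trace, background) {
  stopifnot(inherits(trace, "trace_matrix"))
  .require_stage(trace, "raw", "subtract_background")
  if (length(background) != ncol(trace$values)) {
    stop("background length (", length(background),
         ") does not match frame count (", ncol(trace$values), ")")
  }
  trace$values <- sweep(trace$values, 2L, as.numeric(background), `-`)
  .advance_stage(trace, "background_subtracted")
}

# Profile least-squares fit of a * exp(-t / tau) + c to a single trace:
# for a candidate tau the optimal (a, c) are linear, so only tau is searched.
# The RSS profile over tau can be nearly flat or multimodal when the trend is
# small relative to the signal, so a log-spaced grid brackets the global
# minimum before local refinement.
.fit_exponential <- function(y, tt) {
  dur <- max(tt) - min(tt)
  rss_for <- function(tau) {
    b <- exp(-tt / tau)
    fit <- stats::.lm.fit(cbind(b, 1), y)
    sum(fit$residuals^2)
  }
  grid <- exp(seq(log(dur / 100), log(dur * 20), length.out = 40))
  rss <- vapply(grid, rss_for, numeric(1))
  best <- which.min(rss)
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  opt <- stats::optimize(rss_for, interval = c(lo, hi), tol = dur * 1e-5)
  tau <- if (opt$objective <= rss[best]) opt$minimum else grid[best]
  b <- exp(-tt / tau)
  fit <- stats::.lm.fit(cbind(b, 1), y)
  coefs <- fit$coefficients
  if (any(!is.finite(coefs))) stop("exponential fit produced non-finite coefficients")
  trend <- coefs[1] * b + coefs[2]
  list(trend = trend, a = coefs[1], tau = tau, c = coefs[2])
}

#' Remove a slow exponential trend from each ROI trace
#'
#' Fits `f(t) = a * exp(-t / tau) + c` to each ROI trace by least squares
#' (profiling over `tau` with the linear coefficients solved exactly) and
#' returns the trace minus the fitted trend plus the trend's temporal mean, so
#' the mean fluorescence level of each ROI is preserved. ROIs whose
#' exponential fit fails fall back to a linear detrend and are recorded in the
#' attached report.
#'
#' @param trace a [trace_matrix()] at stage `raw` or `background_subtracted`,
#'   with at least 10 frames.
#' @return The detrended trace (stage `detrended`). The attribute
#'   `detrend_report` is a data frame with the fitted `a`, `tau`, `c` and the
#'   method used (`"exponential"` or `"linear"`) per ROI.
#' @export
detrend_exponential <- function(trace) {
  stopifnot(inherits(trace, "trace_matrix"))
  .require_stage(trace, c("raw", "background_subtracted"),
                 "detrend_exponential")
  if (ncol(trace$values) < 10) {
    stop("exponential detrending needs at least 10 frames, got ",
         ncol(trace$values))
  }
  tt <- frame_times(trace)
  n <- nrow(trace$values)
  report <- data.frame(roi_id = trace$roi_ids, a = NA_real_, tau = NA_real_,
                       c = NA_real_, method = "exponential",
                       stringsAsFactors = FALSE)
  out <- trace$values
  n_fallback <- 0L
  for (i in seq_len(n)) {
    y <- trace$values[i, ]
    fit <- tryCatch(.fit_exponential(y, tt), error = function(e) NULL)
    if (is.null(fit)) {
      lf <- stats::.lm.fit(cbind(1, tt), y)
      trend <- lf$coefficients[1] + lf$coefficients[2] * tt
      report$method[i] <- "linear"
      n_fallback <- n_fallback + 1L
      fit <- list(trend = trend, a = NA_real_, tau = NA_real_, c = NA_real_)
    }
    out[i, ] <- y - fit$trend + mean(fit$trend)
    report$a[i] <- fit$a
    report$tau[i] <- fit$tau
    report$c[i] <- fit$c
  }
  if (n_fallback > 0L) {
    warning(n_fallback,
            " ROI(s) fell back to linear detrending (exponential fit failed)")
  }
  trace$values <- out
  trace <- .advance_stage(trace, "detrended")
  attr(trace, "detrend_report") <- report
  trace
}

#' Scale trace values
#'
#' Multiplies all fluorescence values by a fixed factor (0.001 by default)
#' before the quality-control thresholds are evaluated.
#'
#' @param trace a [trace_matrix()] at a stage before `smoothed`.
#' @param scale_factor positive multiplicative factor.
#' @return The scaled trace (stage `scaled`).
#' @export
scale_traces <- function(trace, scale_factor = 0.001) {
  stopifnot(inherits(trace, "trace_matrix"))
  .require_stage(trace, c("raw", "background_subtracted", "detrended"),
                 "scale_traces")
  if (!is.numeric(scale_factor) || length(scale_factor) != 1L ||
      scale_factor <= 0) {
    stop("scale_factor must be a single positive number")
  }
  trace$values <- trace$values * scale_factor
  .advance_stage(trace, "scaled")
}

#' Two-stage ROI quality-control filter
#'
#' Evaluates, on the scaled traces of both stimulation conditions, the two
#' quality criteria per ROI: variance >= `var_threshold` and maximum response
#' >= `max_threshold`. An ROI is retained only if it meets both criteria
#' under both conditions.
#'
#' @param trace_V,trace_VT [trace_matrix()] objects at stage `scaled`, with
#'   identical ROI identifiers in identical order.
#' @param config a [preprocess_config()].
#' @return An object of class `qc_report`: a list with `retained` (character
#'   vector of retained ROI ids) and `report`, a data frame with the four
#'   per-ROI statistics (`variance_V`, `variance_VT`, `max_V`, `max_VT`) and
#'   the flags `pass_variance`, `pass_max` and `retained`.
#' @export
qc_filter <- function(trace_V, trace_VT, config = preprocess_config()) {
  stopifnot(inherits(trace_V, "trace_matrix"),
            inherits(trace_VT, "trace_matrix"))
  .require_stage(trace_V, "scaled", "qc_filter")
  .require_stage(trace_VT, "scaled", "qc_filter")
  if (!identical(trace_V$roi_ids, trace_VT$roi_ids)) {
    stop("roi_ids differ between conditions; qc_filter requires identical ",
         "ROI sets in identical order")
  }
  row_var <- function(m) apply(m, 1L, stats::var)
  report <- data.frame(
    roi_id = trace_V$roi_ids,
    variance_V = row_var(trace_V$values),
    variance_VT = row_var(trace_VT$values),
    max_V = apply(trace_V$values, 1L, max),
    max_VT = apply(trace_VT$values, 1L, max),
    stringsAsFactors = FALSE
  )
  report$pass_variance <- report$variance_V >= config$var_threshold &
    report$variance_VT >= config$var_threshold
  report$pass_max <- report$max_V >= config$max_threshold &
    report$max_VT >= config$max_threshold
  report$retained <- report$pass_variance & report$pass_max
  rownames(report) <- NULL
  structure(list(retained = report$roi_id[report$retained], report = report),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", nrow(x$report), " ROIs, ", length(x$retained),
      " retained (", nrow(x$report) - length(x$retained), " excluded)\n",
      sep = "")
  invisible(x)
}

#' Savitzky-Golay smoothing of each ROI trace
#'
#' Replaces each ROI trace by its Savitzky-Golay filtered version: a
#' least-squares polynomial of order `order` fitted over a sliding window of
#' `window` frames, evaluated at the window center (edges are handled by
#' off-center polynomial fits).
#'
#' @param trace a [trace_matrix()] at a stage before `smoothed`.
#' @param window window length in frames; must be odd and greater than
#'   `order`, and no longer than the trace.
#' @param order polynomial order.
#' @return The smoothed trace (stage `smoothed`).
#' @export
smooth_savgol <- function(trace, window = 21L, order = 3L) {
  stopifnot(inherits(trace, "trace_matrix"))
  .require_stage(trace, c("raw", "background_subtracted", "detrended",
                          "scaled"), "smooth_savgol")
  if (window %% 2 == 0) stop("savgol window must be odd, got ", window)
  if (window <= order) {
    stop("savgol window (", window, ") must exceed the polynomial order (",
         order, ")")
  }
  if (ncol(trace$values) < window) {
    stop("trace has ", ncol(trace$values), " frames, fewer than the window (",
         window, ")")
  }
  trace$values <- t(apply(trace$values, 1L, function(x) {
    signal::sgolayfilt(x, p = order, n = window)
  }))
  rownames(trace$values) <- trace$roi_ids
  .advance_stage(trace, "smoothed")
}

#' Min-max normalization of each ROI trace
#'
#' Maps each ROI trace to `(F - F_min) / (F_max - F_min)` so that every
#' non-degenerate ROI spans exactly `[0, 1]`. Constant ROIs (for which
#' `F_max == F_min`) cannot be normalized; they are set to all zeros and
#' reported with a warning rather than aborting the run.
#'
#' @param trace a [trace_matrix()] at a stage before `normalized`.
#' @return The normalized trace (stage `normalized`). The attribute
#'   `degenerate_rois` lists ROIs that were constant.
#' @export
normalize_minmax <- function(trace) {
  stopifnot(inherits(trace, "trace_matrix"))
  .require_stage(trace, setdiff(.trace_stages, "normalized"),
                 "normalize_minmax")
  lo <- apply(trace$values, 1L, min)
  hi <- apply(trace$values, 1L, max)
  span <- hi - lo
  degenerate <- span == 0
  span[degenerate] <- 1  # avoid 0/0; degenerate rows are zeroed below
  trace$values <- (trace$values - lo) / span
  if (any(degenerate)) {
    trace$values[degenerate, ] <- 0
    warning("constant trace(s) set to zero during min-max normalization: ",
            paste(trace$roi_ids[degenerate], collapse = ", "))
  }
  trace <- .advance_stage(trace, "normalized")
  attr(trace, "degenerate_rois") <- trace$roi_ids[degenerate]
  trace
}

#' Preprocess a paired-condition recording end to end
#'
#' Convenience wrapper applying the standard preprocessing order to a pair of
#' raw trace matrices from the same animal: optional background subtraction,
#' exponential detrending, scaling, joint two-condition quality control,
#' Savitzky-Golay smoothing of the retained ROIs and min-max normalization.
#' Quality-control statistics are computed on the scaled, pre-smoothing
#' traces, because the variance and maximum-response thresholds target raw
#' artifact signatures that smoothing would mask and that normalization
#' (which bounds every trace by 1) would erase.
#'
#' @param trace_V,trace_VT raw [trace_matrix()] objects for the two
#'   conditions.
#' @param config a [preprocess_config()].
#' @param background_V,background_VT optional per-frame background series.
#' @return A list with `V` and `VT` (normalized traces over retained ROIs),
#'   `smoothed_V` / `smoothed_VT` (scaled, smoothed, pre-normalization traces
#'   used for response-amplitude measurements), `qc` (the [qc_filter()]
#'   result) and `log` (character vector describing the applied stages and
#'   ROI counts).
#' @export
preprocess_traces <- function(trace_V, trace_VT,
                              config = preprocess_config(),
                              background_V = NULL, background_VT = NULL) {
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  n_in <- nrow(trace_V$values)
  if (!is.null(background_V)) {
    trace_V <- subtract_background(trace_V, background_V)
    trace_VT <- subtract_background(trace_VT, background_VT)
    note("background subtraction applied")
  }
  if (config$detrend == "exponential") {
    trace_V <- detrend_exponential(trace_V)
    trace_VT <- detrend_exponential(trace_VT)
    note("exponential detrending applied")
  }
  trace_V <- scale_traces(trace_V, config$scale_factor)
  trace_VT <- scale_traces(trace_VT, config$scale_factor)
  note("scaled by ", config$scale_factor)
  qc <- qc_filter(trace_V, trace_VT, config)
  note("QC: ", n_in, " ROIs in, ", length(qc$retained), " retained ",
       "(variance >= ", config$var_threshold, " and max >= ",
       config$max_threshold, " in both conditions)")
  if (length(qc$retained) < 2) {
    stop("fewer than 2 ROIs retained by QC for animal ", trace_V$animal_id)
  }
  trace_V <- subset_trace(trace_V, qc$retained)
  trace_VT <- subset_trace(trace_VT, qc$retained)
  sm_V <- smooth_savgol(trace_V, config$savgol_window, config$savgol_order)
  sm_VT <- smooth_savgol(trace_VT, config$savgol_window, config$savgol_order)
  note("Savitzky-Golay smoothing (window ", config$savgol_window,
       ", order ", config$savgol_order, ")")
  norm_V <- normalize_minmax(sm_V)
  norm_VT <- normalize_minmax(sm_VT)
  note("min-max normalization to [0, 1]")
  list(V = norm_V, VT = norm_VT, smoothed_V = sm_V, smoothed_VT = sm_VT,
       qc = qc, log = log)
}
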