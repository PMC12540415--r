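# Ordered processing stages a trace matrix moves through. Stages may be
# skipped but never revisited or reordered.
.trace_stages <- c("raw", "background_subtracted", "detrended", "scaled",
                   "smoothed", "normalized")

#' Fluorescence trace matrix
#'
#' Container for a per-animal, per-condition block of fluorescence time
#' series: one row per ROI (neuron soma), one column per imaging frame.
#' The `stage` field tracks which preprocessing steps have been applied;
#' stage transitions are only permitted in the order
#' raw -> background_subtracted -> detrended -> scaled -> smoothed ->
#' normalized (skipping allowed, reordering not).
#'
#' @param values numeric matrix, ROIs x frames; no missing values.
#' @param roi_ids character vector of unique ROI identifiers; defaults to the
#'   rownames of `values` or `roi_001`, `roi_002`, ...
#' @param frame_rate imaging frame rate in Hz (> 0).
#' @param condition stimulation condition label, `"V"` (unimodal visual) or
#'   `"VT"` (bimodal visuotactile).
#' @param animal_id identifier of the animal the traces were recorded from.
#' @param stage processing stage of `values` (see above).
#' @return An object of class `trace_matrix`.
#' @export
trace_matrix <- function(values, roi_ids = NULL, frame_rate,
                         condition = c("V", "VT"), animal_id = "animal_1",
                         stage = "raw") {
  condition <- match.arg(condition)
  stage <- match.arg(stage, .trace_stages)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("trace matrix contains missing values")
  if (is.null(roi_ids)) {
    roi_ids <- rownames(values)
    if (is.null(roi_ids)) roi_ids <- sprintf("roi_%03d", seq_len(nrow(values)))
  }
  roi_ids <- as.character(roi_ids)
  if (length(roi_ids) != nrow(values)) {
    stop("roi_ids length (", length(roi_ids), ") does not match number of ROI rows (",
         nrow(values), ")")
  }
  if (anyDuplicated(roi_ids)) stop("roi_ids must be unique")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    stop("frame_rate must be a single positive number (Hz)")
  }
  rownames(values) <- roi_ids
  structure(
    list(values = values, roi_ids = roi_ids, frame_rate = frame_rate,
         condition = condition, animal_id = as.character(animal_id),
         stage = stage),
    class = "trace_matrix"
  )
}

.stage_index <- function(stage) match(stage, .trace_stages)

# Advance the stage of a trace, enforcing the forward-only ordering.
.advance_stage <- function(trace, to) {
  from <- .stage_index(trace$stage)
  dest <- .stage_index(to)
  if (is.na(dest)) stop("unknown stage: ", to)
  if (dest <= from) {
    stop("invalid stage transition: '", trace$stage, "' -> '", to,
         "' (stages advance only in the order ",
         paste(.trace_stages, collapse = " -> "), ")")
  }
  trace$stage <- to
  trace
}

# Require that the current stage is one of `allowed` before an operation.
.require_stage <- function(trace, allowed, op) {
  if (!trace$stage %in% allowed) {
    stop(op, " expects a trace at stage ",
         paste(sQuote(allowed), collapse = " or "),
         ", got ", sQuote(trace$stage))
  }
  invisible(trace)
}

#' Subset a trace matrix to a set of ROIs
#'
#' @param trace a [trace_matrix()].
#' @param roi_ids character vector of ROI identifiers to keep (order is
#'   preserved as given).
#' @return A `trace_matrix` restricted to the requested ROIs.
#' @export
subset_trace <- function(trace, roi_ids) {
  stopifnot(inherits(trace, "trace_matrix"))
  missing_ids <- setdiff(roi_ids, trace$roi_ids)
  if (length(missing_ids)) {
    stop("unknown roi_ids: ", paste(missing_ids, collapse = ", "))
  }
  trace$values <- trace$values[roi_ids, , drop = FALSE]
  trace$roi_ids <- roi_ids
  trace
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat("<trace_matrix> ", nrow(x$values), " ROIs x ", ncol(x$values),
      " frames @ ", x$frame_rate, " Hz\n", sep = "")
  cat("  animal: ", x$animal_id, " | condition: ", x$condition,
      " | stage: ", x$stage, "\n", sep = "")
  invisible(x)
}

#' Frame times of a trace matrix
#'
#' @param trace a [trace_matrix()].
#' @return Numeric vector of frame times in seconds (first frame at 0).
#' @export
frame_times <- function(trace) {
  (seq_len(ncol(trace$values)) - 1) / trace$frame_rate
}
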