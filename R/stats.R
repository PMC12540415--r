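#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Paired two-sided Wilcoxon signed-rank test. Differences `d = x - y` equal
#' to zero are dropped; the absolute differences are ranked with midranks for
#' ties; the statistic `W` is the sum of ranks of positive differences. For
#' `n <= 25` retained pairs the p-value is exact: the full null distribution
#' of `W` over all `2^n` equally likely sign assignments is enumerated (via
#' the generating-function recursion over the rank multiset, which yields the
#' identical distribution), and the two-sided p-value is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`. Above 25 pairs a normal
#' approximation with tie correction and continuity correction is used
#' (`E[W] = sum(r)/2`, `Var[W] = sum(r^2)/4` over the midranks `r`, which
#' reduces to the classical moments without ties).
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_limit largest `n` for which the exact distribution is used.
#' @return A list with `statistic` (W), `p_value`, `n` (pairs retained after
#'   zero-difference removal), `n_dropped` and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 25L) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length (paired samples); got ",
         length(x), " and ", length(y))
  }
  d <- x - y
  d <- d[!is.na(d)]
  n_dropped <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n < 2) {
    stop("no nonzero pairs (", n,
         " nonzero difference(s); at least 2 required)")
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    # null distribution of 2W (doubled ranks are integers even with midranks)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1L)  # counts[v + 1] = #assignments with 2W = v
    counts[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(total + 1L - ri)])
      counts <- counts + shifted
    }
    w2 <- as.integer(round(2 * w))
    p_le <- sum(counts[seq_len(w2 + 1L)]) / 2^n
    p_ge <- sum(counts[(w2 + 1L):(total + 1L)]) / 2^n
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    # Edgeworth-corrected normal approximation: W = sum r_i B_i with
    # B_i ~ Bernoulli(1/2), so E[W] = sum(r)/2, Var[W] = sum(r^2)/4 (exact
    # with midranks), skewness 0 and excess kurtosis -sum(r^4)/8 / Var^2.
    mu <- sum(r) / 2
    v <- sum(r^2) / 4
    sd0 <- sqrt(v)
    g2 <- (-sum(r^4) / 8) / v^2
    cdf <- function(z) {
      stats::pnorm(z) - stats::dnorm(z) * (g2 / 24) * (z^3 - 3 * z)
    }
    z_lo <- (w - mu + 0.5) / sd0  # P(W <= w) with continuity correction
    z_hi <- (w - mu - 0.5) / sd0  # 1 - P(W >= w)
    p_le <- min(1, max(0, cdf(z_lo)))
    p_ge <- min(1, max(0, 1 - cdf(z_hi)))
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "normal_approximation"
  }
  list(statistic = w, p_value = p, n = n, n_dropped = n_dropped,
       method = method)
}

#' Paired across-animal comparison of network metrics
#'
#' Compares, metric by metric, the per-animal network measures between the
#' two stimulation conditions with the exact Wilcoxon signed-rank test
#' ([wilcoxon_signed_rank()]). The direction of each effect is the sign of
#' the median paired difference. A paired t-test p-value is included as a
#' secondary column. No multiple-testing correction is applied across
#' metrics; the `flag` column notes this and any degenerate comparisons
#' (all differences zero), which are reported as non-significant rather than
#' aborting.
#'
#' @param metrics_V,metrics_VT data frames of per-animal metric values, one
#'   row per animal in matching order, one column per metric (any shared
#'   numeric columns are compared; a column named `animal_id` is ignored).
#' @param alpha significance level (default 0.05).
#' @return A data frame of class `group_comparison` with one row per metric:
#'   `metric`, `n`, `median_V`, `median_VT`, `W`, `p_value`, `p_t_test`,
#'   `direction` (`V_greater`, `VT_greater` or `none`), `significant`,
#'   `flag`.
#' @export
compare_conditions <- function(metrics_V, metrics_VT, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  shared <- intersect(names(metrics_V), names(metrics_VT))
  shared <- shared[shared != "animal_id"]
  shared <- shared[vapply(metrics_V[shared], is.numeric, logical(1))]
  if (!length(shared)) stop("no shared numeric metric columns to compare")
  if (nrow(metrics_V) != nrow(metrics_VT)) {
    stop("metrics_V and metrics_VT must have one row per animal in matching order")
  }
  rows <- lapply(shared, function(metric) {
    v <- metrics_V[[metric]]
    vt <- metrics_VT[[metric]]
    med_diff <- stats::median(v - vt)
    direction <- if (med_diff > 0) "V_greater" else if (med_diff < 0) {
      "VT_greater"
    } else "none"
    res <- tryCatch(wilcoxon_signed_rank(v, vt), error = function(e) NULL)
    if (is.null(res)) {
      data.frame(metric = metric, n = length(v), median_V = stats::median(v),
                 median_VT = stats::median(vt), W = NA_real_,
                 p_value = NA_real_, p_t_test = NA_real_, direction = "none",
                 significant = FALSE, flag = "all_differences_zero",
                 stringsAsFactors = FALSE)
    } else {
      p_t <- tryCatch(stats::t.test(v, vt, paired = TRUE)$p.value,
                      error = function(e) NA_real_)
      data.frame(metric = metric, n = res$n, median_V = stats::median(v),
                 median_VT = stats::median(vt), W = res$statistic,
                 p_value = res$p_value, p_t_test = p_t,
                 direction = direction,
                 significant = res$p_value < alpha,
                 flag = "uncorrected_for_multiple_comparisons",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Stimulus-evoked response amplitude per ROI
#'
#' Measures, for each ROI, the mean stimulus-evoked response over trials:
#' within each trial the peak value inside the stimulus window (extended by
#' one second to cover the calcium indicator lag) is taken, and the mean of
#' these per-trial peaks, minus a baseline (the mean over the final 2 s of
#' every inter-stimulus interval), is returned. If no trial structure is
#' supplied the trace-wide mean is used instead. Amplitudes should be
#' measured on a scale-preserving stage (e.g. smoothed, pre-normalization
#' traces): min-max normalization bounds every ROI by 1 and erases amplitude
#' differences.
#'
#' @param trace a [trace_matrix()].
#' @param onsets stimulus onset times in seconds (e.g. [trial_onsets()]), or
#'   `NULL` for no trial structure.
#' @param stim_duration stimulus duration in seconds.
#' @param isi_duration inter-stimulus interval in seconds (used for the
#'   baseline window).
#' @return Named numeric vector of response amplitudes, one per ROI.
#' @export
response_amplitudes <- function(trace, onsets = NULL, stim_duration = 2,
                                isi_duration = 4) {
  stopifnot(inherits(trace, "trace_matrix"))
  if (is.null(onsets)) {
    amps <- rowMeans(trace$values)
    names(amps) <- trace$roi_ids
    return(amps)
  }
  fr <- trace$frame_rate
  n_frames <- ncol(trace$values)
  lag <- 1  # seconds added after stimulus offset for the indicator lag
  peak_cols <- lapply(onsets, function(on) {
    idx <- seq(floor(on * fr) + 1L,
               min(n_frames, ceiling((on + stim_duration + lag) * fr)))
    idx[idx >= 1L]
  })
  base_start <- stim_duration + max(isi_duration - 2, 0)
  base_cols <- unlist(lapply(onsets, function(on) {
    idx <- seq(floor((on + base_start) * fr) + 1L,
               min(n_frames, floor((on + stim_duration + isi_duration) * fr)))
    idx[idx >= 1L & idx <= n_frames]
  }))
  base_cols <- unique(base_cols)
  baseline <- rowMeans(trace$values[, base_cols, drop = FALSE])
  peaks <- vapply(peak_cols, function(idx) {
    apply(trace$values[, idx, drop = FALSE], 1L, max)
  }, numeric(nrow(trace$values)))
  amps <- rowMeans(peaks) - baseline
  names(amps) <- trace$roi_ids
  amps
}

#' Compare responses of top-k centrality nodes with the rest
#'
#' For each centrality measure in the table, ranks nodes by that measure
#' (ties broken deterministically toward the lower node id), takes the top
#' `k`, and compares their response amplitudes with those of the remaining
#' nodes using a two-sided Wilcoxon rank-sum (Mann-Whitney) test.
#'
#' @param centralities a [centrality_table()].
#' @param amplitudes named numeric vector of response amplitudes covering
#'   exactly the table's nodes (see [response_amplitudes()]).
#' @param k number of top nodes (default 5); must be smaller than the number
#'   of nodes.
#' @param alpha significance level.
#' @param measures which centrality columns to analyze.
#' @return A data frame with one row per measure: `centrality`, `top_ids`
#'   (comma-separated), `mean_top`, `mean_rest`, `statistic` (rank-sum U),
#'   `p_value`, `significant`.
#' @export
top_k_response_analysis <- function(centralities, amplitudes, k = 5L,
                                    alpha = 0.05,
                                    measures = c("betweenness", "closeness",
                                                 "degree")) {
  stopifnot(inherits(centralities, "centrality_table"))
  n <- nrow(centralities)
  if (n <= k) {
    stop("top-", k, " analysis needs more than ", k, " nodes, got ", n)
  }
  if (!setequal(names(amplitudes), centralities$node_id)) {
    stop("amplitudes must cover exactly the nodes of the centrality table")
  }
  amplitudes <- amplitudes[centralities$node_id]
  rows <- lapply(measures, function(ms) {
    vals <- centralities[[ms]]
    ord <- order(-vals, centralities$node_id)  # deterministic tie-break
    top <- ord[seq_len(k)]
    rest <- ord[-seq_len(k)]
    if (length(unique(amplitudes)) == 1L) {
      # fully tied amplitudes carry no evidence of a hierarchy
      stat <- k * (n - k) / 2
      p <- 1
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(amplitudes[top], amplitudes[rest])
      )
      stat <- unname(wt$statistic)
      p <- wt$p.value
    }
    data.frame(centrality = ms,
               top_ids = paste(centralities$node_id[top], collapse = ","),
               mean_top = mean(amplitudes[top]),
               mean_rest = mean(amplitudes[rest]),
               statistic = stat, p_value = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlation between centrality and response amplitude
#'
#' Pearson correlation (with its two-sided p-value) between each centrality
#' measure and the per-node response amplitudes. A constant centrality or
#' amplitude vector leaves the correlation undefined; such rows are flagged
#' rather than raising an error.
#'
#' @inheritParams top_k_response_analysis
#' @return A data frame with one row per measure: `centrality`, `r`,
#'   `p_value`, `defined`.
#' @export
centrality_response_correlation <- function(centralities, amplitudes,
                                            measures = c("betweenness",
                                                         "closeness",
                                                         "degree")) {
  stopifnot(inherits(centralities, "centrality_table"))
  if (!setequal(names(amplitudes), centralities$node_id)) {
    stop("amplitudes must cover exactly the nodes of the centrality table")
  }
  amplitudes <- amplitudes[centralities$node_id]
  rows <- lapply(measures, function(ms) {
    vals <- centralities[[ms]]
    if (stats::sd(vals) == 0 || stats::sd(amplitudes) == 0) {
      data.frame(centrality = ms, r = NA_real_, p_value = NA_real_,
                 defined = FALSE, stringsAsFactors = FALSE)
    } else {
      ct <- stats::cor.test(vals, amplitudes, method = "pearson")
      data.frame(centrality = ms, r = unname(ct$estimate),
                 p_value = ct$p.value, defined = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
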