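#' End-to-end run configuration
#'
#' Configuration of a full study analysis. Input traces come either from
#' files on disk (`inputs`) or from the synthetic generator (`synth`);
#' exactly one of the two must be supplied.
#'
#' @param synth a [synth_config()], or `NULL`.
#' @param inputs a list of per-animal entries, each a list with `animal_id`,
#'   `V` and `VT` (paths to raw trace files as written by
#'   [write_trace_matrix()]), or `NULL`.
#' @param preprocess a [preprocess_config()].
#' @param threshold network edge threshold (see [build_network()]).
#' @param distance_rule weight-to-distance convention (see
#'   [functional_network()]).
#' @param cor_method correlation type for network construction.
#' @param gamma Louvain resolution parameter.
#' @param k number of top-centrality nodes in the response-hierarchy
#'   analysis.
#' @param alpha significance level.
#' @param seed integer seed for community detection (and, when `synth` is
#'   used without its own seed, data generation).
#' @param out_dir output directory for the result bundle.
#' @param stim_onsets,stim_duration,isi_duration trial structure used for
#'   response amplitudes when inputs come from files; derived from `synth`
#'   otherwise.
#' @return An object of class `run_config`.
#' @export
run_config <- function(synth = NULL, inputs = NULL,
                       preprocess = preprocess_config(), threshold = 0,
                       distance_rule = "inverse_weight",
                       cor_method = "pearson", gamma = 1, k = 5L,
                       alpha = 0.05, seed = 1L, out_dir = "calnet_results",
                       stim_onsets = NULL, stim_duration = 2,
                       isi_duration = 4) {
  if (is.null(synth) && is.null(inputs)) {
    stop("configuration error: either a synth block or input trace paths ",
         "must be provided (got neither)")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!is.null(synth)) stopifnot(inherits(synth, "synth_config"))
  structure(
    list(synth = synth, inputs = inputs, preprocess = preprocess,
         threshold = threshold, distance_rule = distance_rule,
         cor_method = cor_method, gamma = gamma, k = as.integer(k),
         alpha = alpha, seed = as.integer(seed), out_dir = out_dir,
         stim_onsets = stim_onsets, stim_duration = stim_duration,
         isi_duration = isi_duration),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' The file may contain the top-level keys `synth` (fields of
#' [synth_config()], with `regime_V` / `regime_VT` sub-maps holding
#' [regime_params()] fields), `inputs` (list of `animal_id` / `V` / `VT`
#' path entries), `preprocess` (fields of [preprocess_config()]), `network`
#' (`threshold`, `distance_rule`, `cor_method`), `metrics` (`gamma`),
#' `stats` (`alpha`, `k`), `seed` and `out_dir`.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  synth <- NULL
  if (!is.null(y$synth)) {
    sy <- y$synth
    for (reg in c("regime_V", "regime_VT")) {
      if (!is.null(sy[[reg]])) sy[[reg]] <- do.call(regime_params, sy[[reg]])
    }
    synth <- do.call(synth_config, sy)
  }
  pp <- if (!is.null(y$preprocess)) {
    do.call(preprocess_config, y$preprocess)
  } else {
    preprocess_config()
  }
  net <- if (!is.null(y$network)) y$network else list()
  met <- if (!is.null(y$metrics)) y$metrics else list()
  st <- if (!is.null(y$stats)) y$stats else list()
  run_config(
    synth = synth, inputs = y$inputs, preprocess = pp,
    threshold = if (!is.null(net$threshold)) net$threshold else 0,
    distance_rule = if (!is.null(net$distance_rule)) net$distance_rule else "inverse_weight",
    cor_method = if (!is.null(net$cor_method)) net$cor_method else "pearson",
    gamma = if (!is.null(met$gamma)) met$gamma else 1,
    k = if (!is.null(st$k)) st$k else 5L,
    alpha = if (!is.null(st$alpha)) st$alpha else 0.05,
    seed = if (!is.null(y$seed)) y$seed else 1L,
    out_dir = if (!is.null(y$out_dir)) y$out_dir else "calnet_results",
    stim_duration = if (!is.null(y$stim_duration)) y$stim_duration else 2,
    isi_duration = if (!is.null(y$isi_duration)) y$isi_duration else 4
  )
}

# Load or generate the raw paired traces for every animal.
.load_study_traces <- function(config) {
  if (!is.null(config$synth)) {
    dataset <- generate_dataset(config$synth)
    onsets <- trial_onsets(config$synth)
    list(traces = dataset$traces, onsets = onsets,
         stim_duration = config$synth$stim_duration,
         isi_duration = config$synth$isi_duration)
  } else {
    traces <- lapply(config$inputs, function(inp) {
      list(V = read_trace_matrix(inp$V), VT = read_trace_matrix(inp$VT))
    })
    names(traces) <- vapply(config$inputs, `[[`, character(1), "animal_id")
    list(traces = traces, onsets = config$stim_onsets,
         stim_duration = config$stim_duration,
         isi_duration = config$isi_duration)
  }
}

# Analyze one animal/condition: network, centralities, communities.
.analyze_condition <- function(norm_trace, config) {
  net <- build_network(norm_trace, threshold = config$threshold,
                       distance_rule = config$distance_rule,
                       method = config$cor_method)
  ct <- centrality_table(net)
  part <- louvain(net, gamma = config$gamma, seed = config$seed)
  summ <- attr(ct, "summary")
  metrics <- data.frame(
    mean_betweenness = summ$mean[summ$measure == "betweenness"],
    max_betweenness = summ$max[summ$measure == "betweenness"],
    mean_closeness = summ$mean[summ$measure == "closeness"],
    mean_degree = summ$mean[summ$measure == "degree"],
    modularity = part$Q,
    global_efficiency = attr(ct, "global_efficiency")
  )
  list(network = net, centrality = ct, partition = part, metrics = metrics)
}

#' Run the full network-topology analysis pipeline
#'
#' For every animal: preprocesses the paired raw traces (exponential
#' detrending, 0.001 scaling, two-condition quality control, Savitzky-Golay
#' smoothing, min-max normalization), builds one weighted functional network
#' per condition, computes per-node centralities, global efficiency and
#' Louvain modularity, and measures stimulus-evoked response amplitudes.
#' Across animals it then compares every network metric between conditions
#' with the exact Wilcoxon signed-rank test and runs the top-k
#' centrality-node response-hierarchy analysis. All results are written to
#' `config$out_dir` and also returned.
#'
#' @param config a [run_config()].
#' @param write logical; write the result bundle to disk (default `TRUE`).
#' @return Invisibly, a list with `animal_metrics` (per animal x condition
#'   summary metrics), `comparison` (the [compare_conditions()] table),
#'   `hub_response` (per animal x condition x centrality top-k analysis),
#'   `hub_response_study` (across-animal signed-rank test on the per-animal
#'   top-k minus rest amplitude differences, per centrality x condition),
#'   `correlations` (centrality vs amplitude), `qc` (per animal), `networks`,
#'   `centralities`, `partitions` and `log`.
#' @export
run_pipeline <- function(config, write = TRUE) {
  stopifnot(inherits(config, "run_config"))
  study <- .load_study_traces(config)
  animals <- names(study$traces)
  if (is.null(animals) || !length(animals)) stop("no animals in input")
  log <- c(paste0("calnet pipeline, package version ",
                  as.character(utils::packageVersion("calnet"))),
           paste0("seed: ", config$seed),
           paste0("animals: ", length(animals)),
           paste0("network: ", config$cor_method, " correlation, threshold ",
                  config$threshold, ", distance rule ", config$distance_rule),
           paste0("gamma: ", config$gamma, "; alpha: ", config$alpha,
                  "; top-k: ", config$k),
           "negative correlations are clipped to zero (counts per network below)",
           "QC statistics computed on detrended, scaled, pre-smoothing traces",
           "response amplitudes measured on smoothed pre-normalization traces",
           "no multiple-testing correction across metric comparisons")

  per_animal <- list()
  hub_rows <- list()
  corr_rows <- list()
  qc_list <- list()
  networks <- list()
  centralities <- list()
  partitions <- list()

  for (animal in animals) {
    pair <- study$traces[[animal]]
    pre <- tryCatch(
      preprocess_traces(pair$V, pair$VT, config$preprocess),
      error = function(e) stop("preprocess failed for ", animal, ": ",
                               conditionMessage(e))
    )
    qc_list[[animal]] <- pre$qc
    log <- c(log, paste0(animal, ": ", pre$log[length(pre$log) - 2]))
    for (cond in c("V", "VT")) {
      norm_trace <- pre[[cond]]
      sm_trace <- pre[[paste0("smoothed_", cond)]]
      res <- tryCatch(
        .analyze_condition(norm_trace, config),
        error = function(e) stop("network/metrics failed for ", animal, "/",
                                 cond, ": ", conditionMessage(e))
      )
      key <- paste0(animal, "_", cond)
      networks[[key]] <- res$network
      centralities[[key]] <- res$centrality
      partitions[[key]] <- res$partition
      amps <- response_amplitudes(sm_trace, onsets = study$onsets,
                                  stim_duration = study$stim_duration,
                                  isi_duration = study$isi_duration)
      hub <- top_k_response_analysis(res$centrality, amps, k = config$k,
                                     alpha = config$alpha)
      hub$animal_id <- animal
      hub$condition <- cond
      hub_rows[[key]] <- hub
      cr <- centrality_response_correlation(res$centrality, amps)
      cr$animal_id <- animal
      cr$condition <- cond
      corr_rows[[key]] <- cr
      per_animal[[key]] <- cbind(
        data.frame(animal_id = animal, condition = cond,
                   n_nodes = length(res$network$node_ids),
                   n_clipped = res$network$n_clipped,
                   n_communities = res$partition$n_communities),
        res$metrics
      )
      log <- c(log, paste0(key, ": ", length(res$network$node_ids),
                           " nodes, ", res$network$n_clipped,
                           " clipped edges, ", res$partition$n_communities,
                           " communities"))
    }
  }

  animal_metrics <- do.call(rbind, per_animal)
  rownames(animal_metrics) <- NULL
  metric_cols <- c("mean_betweenness", "max_betweenness", "mean_closeness",
                   "mean_degree", "modularity", "global_efficiency")
  mv <- animal_metrics[animal_metrics$condition == "V",
                       c("animal_id", metric_cols)]
  mvt <- animal_metrics[animal_metrics$condition == "VT",
                        c("animal_id", metric_cols)]
  mv <- mv[order(mv$animal_id), ]
  mvt <- mvt[order(mvt$animal_id), ]
  comparison <- compare_conditions(mv, mvt, alpha = config$alpha)

  hub_response <- do.call(rbind, hub_rows)
  rownames(hub_response) <- NULL
  correlations <- do.call(rbind, corr_rows)
  rownames(correlations) <- NULL

  # study-level response-hierarchy test: per centrality x condition, paired
  # signed-rank across animals of (mean top-k amplitude - mean rest)
  hub_study <- list()
  for (ms in unique(hub_response$centrality)) {
    for (cond in c("V", "VT")) {
      sel <- hub_response[hub_response$centrality == ms &
                            hub_response$condition == cond, ]
      sel <- sel[order(sel$animal_id), ]
      row <- data.frame(centrality = ms, condition = cond,
                        n = nrow(sel),
                        mean_top = mean(sel$mean_top),
                        mean_rest = mean(sel$mean_rest),
                        W = NA_real_, p_value = NA_real_,
                        significant = NA, stringsAsFactors = FALSE)
      if (nrow(sel) >= 2) {
        ws <- tryCatch(wilcoxon_signed_rank(sel$mean_top, sel$mean_rest),
                       error = function(e) NULL)
        if (!is.null(ws)) {
          row$W <- ws$statistic
          row$p_value <- ws$p_value
          row$significant <- ws$p_value < config$alpha
        }
      }
      hub_study[[paste0(ms, "_", cond)]] <- row
    }
  }
  hub_response_study <- do.call(rbind, hub_study)
  rownames(hub_response_study) <- NULL

  result <- list(animal_metrics = animal_metrics, comparison = comparison,
                 hub_response = hub_response,
                 hub_response_study = hub_response_study,
                 correlations = correlations, qc = qc_list,
                 networks = networks, centralities = centralities,
                 partitions = partitions, log = log)
  if (write) .write_bundle(result, config)
  invisible(result)
}

# Write the full result bundle under config$out_dir.
.write_bundle <- function(result, config) {
  out <- config$out_dir
  for (d in c("", "qc", "networks", "metrics", "summary")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  for (animal in names(result$qc)) {
    write_table_tsv(result$qc[[animal]]$report,
                    file.path(out, "qc", paste0(animal, "_qc.tsv")))
  }
  for (key in names(result$networks)) {
    write_network(result$networks[[key]], file.path(out, "networks", key))
    ct <- result$centralities[[key]]
    write_table_tsv(as.data.frame(ct),
                    file.path(out, "metrics", paste0(key, "_centrality.tsv")))
    part <- result$partitions[[key]]
    write_table_tsv(
      data.frame(node_id = names(part$membership),
                 community = unname(part$membership)),
      file.path(out, "metrics", paste0(key, "_partition.tsv"))
    )
  }
  write_table_tsv(result$animal_metrics,
                  file.path(out, "summary", "metrics_by_animal.tsv"))
  write_table_tsv(as.data.frame(result$comparison),
                  file.path(out, "summary", "group_comparison.tsv"))
  write_table_tsv(result$hub_response,
                  file.path(out, "summary", "hub_response.tsv"))
  write_table_tsv(result$hub_response_study,
                  file.path(out, "summary", "hub_response_study.tsv"))
  write_table_tsv(result$correlations,
                  file.path(out, "summary", "centrality_response_correlation.tsv"))
  writeLines(result$log, file.path(out, "run_log.txt"))
  invisible(out)
}
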