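# Numbers are written with 17 significant digits so that write -> read round
# trips are bitwise exact for doubles.
.fmt <- function(x) sprintf("%.17g", x)

.parse_numeric <- function(fields, line_no, path) {
  suppressWarnings(vals <- as.numeric(fields))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop("non-numeric cell ", sQuote(fields[bad]), " at line ", line_no,
         " of ", path)
  }
  vals
}

#' Write a trace matrix as delimited text
#'
#' Tab-separated format: comment header lines (`# key: value`) carrying the
#' frame rate, condition, animal id and stage, then a header row (`roi_id`
#' followed by the frame times in seconds), then one row per ROI. Values are
#' written with enough digits for an exact round trip.
#'
#' @param trace a [trace_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_matrix <- function(trace, path) {
  stopifnot(inherits(trace, "trace_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# frame_rate: ", .fmt(trace$frame_rate)),
    paste0("# condition: ", trace$condition),
    paste0("# animal_id: ", trace$animal_id),
    paste0("# stage: ", trace$stage),
    paste(c("roi_id", .fmt(frame_times(trace))), collapse = "\t")
  ), con)
  body <- vapply(seq_len(nrow(trace$values)), function(i) {
    paste(c(trace$roi_ids[i], .fmt(trace$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a trace matrix written by [write_trace_matrix()]
#'
#' @param path input file path.
#' @return A [trace_matrix()]. Malformed input (ragged rows, non-numeric
#'   cells, missing header) raises a parse error naming the offending line.
#' @export
read_trace_matrix <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty trace file: ", path)
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(lines[ln], regexec("^#\\s*([^:]+):\\s*(.*)$", lines[ln]))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- setdiff(seq_along(lines), meta_lines)
  if (length(body) < 2) stop("trace file has no data rows: ", path)
  header_ln <- body[1]
  header <- strsplit(lines[header_ln], "\t", fixed = TRUE)[[1]]
  if (header[1] != "roi_id") {
    stop("malformed header at line ", header_ln, " of ", path,
         ": first field must be 'roi_id'")
  }
  n_fields <- length(header)
  rows <- lapply(body[-1], function(ln) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) != n_fields) {
      stop("ragged row at line ", ln, " of ", path, ": expected ", n_fields,
           " fields, found ", length(fields))
    }
    list(id = fields[1], values = .parse_numeric(fields[-1], ln, path))
  })
  values <- do.call(rbind, lapply(rows, `[[`, "values"))
  roi_ids <- vapply(rows, `[[`, character(1), "id")
  frame_rate <- if (!is.null(meta$frame_rate)) as.numeric(meta$frame_rate) else {
    tt <- .parse_numeric(header[-1], header_ln, path)
    if (length(tt) > 1) 1 / (tt[2] - tt[1]) else 1
  }
  trace_matrix(values, roi_ids = roi_ids, frame_rate = frame_rate,
               condition = if (!is.null(meta$condition)) meta$condition else "V",
               animal_id = if (!is.null(meta$animal_id)) meta$animal_id else "animal_1",
               stage = if (!is.null(meta$stage)) meta$stage else "raw")
}

#' Write a functional network to disk
#'
#' Writes three representations: the full weight matrix (`<stem>_weights.tsv`,
#' tab-separated with node ids as row and column labels), an edge list
#' (`<stem>_edges.tsv` with columns `node_i`, `node_j`, `weight`, upper
#' triangle, positive weights only) and a GraphML file (`<stem>.graphml`,
#' undirected, with a `weight` edge attribute) readable by standard graph
#' libraries.
#'
#' @param net a [functional_network()].
#' @param stem output path stem (directory + file prefix).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_network <- function(net, stem) {
  stopifnot(inherits(net, "functional_network"))
  w <- net$weights
  ids <- net$node_ids
  paths <- c(weights = paste0(stem, "_weights.tsv"),
             edges = paste0(stem, "_edges.tsv"),
             graphml = paste0(stem, ".graphml"))

  mat_lines <- c(paste(c("node_id", ids), collapse = "\t"),
                 vapply(seq_along(ids), function(i) {
                   paste(c(ids[i], .fmt(w[i, ])), collapse = "\t")
                 }, character(1)))
  writeLines(mat_lines, paths[["weights"]])

  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  edge_lines <- c("node_i\tnode_j\tweight",
                  vapply(seq_len(nrow(ut)), function(e) {
                    paste(ids[ut[e, 1]], ids[ut[e, 2]],
                          .fmt(w[ut[e, 1], ut[e, 2]]), sep = "\t")
                  }, character(1)))
  writeLines(edge_lines, paths[["edges"]])

  gml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="w" for="edge" attr.name="weight" attr.type="double"/>',
    '  <graph id="G" edgedefault="undirected">',
    sprintf('    <node id="%s"/>', ids),
    vapply(seq_len(nrow(ut)), function(e) {
      sprintf('    <edge source="%s" target="%s"><data key="w">%s</data></edge>',
              ids[ut[e, 1]], ids[ut[e, 2]], .fmt(w[ut[e, 1], ut[e, 2]]))
    }, character(1)),
    "  </graph>",
    "</graphml>"
  )
  writeLines(gml, paths[["graphml"]])
  invisible(paths)
}

#' Read a weight matrix written by [write_network()]
#'
#' @param path the `<stem>_weights.tsv` file.
#' @param distance_rule,animal_id,condition passed to
#'   [functional_network()].
#' @return A [functional_network()].
#' @export
read_network_weights <- function(path, distance_rule = "inverse_weight",
                                 animal_id = "animal_1", condition = "V") {
  lines <- readLines(path)
  if (length(lines) < 3) stop("weight matrix file too short: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  ids <- header[-1]
  n <- length(ids)
  w <- matrix(0, n, n)
  row_ids <- character(n)
  for (i in seq_len(n)) {
    fields <- strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]]
    if (length(fields) != n + 1) {
      stop("ragged row at line ", i + 1, " of ", path, ": expected ", n + 1,
           " fields, found ", length(fields))
    }
    row_ids[i] <- fields[1]
    w[i, ] <- .parse_numeric(fields[-1], i + 1, path)
  }
  if (!identical(row_ids, ids)) {
    stop("row and column node ids disagree in ", path)
  }
  functional_network(w, node_ids = ids, distance_rule = distance_rule,
                     animal_id = animal_id, condition = condition)
}

#' Write a data frame as a tab-separated table with header
#'
#' @param df a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to disk
#'
#' Writes, per animal, the two raw trace matrices (delimited text, see
#' [write_trace_matrix()]) and the per-condition ground truth: the latent
#' coupling matrix as an edge list (`node_i`, `node_j`, `weight`) and a node
#' attribute table (node id, hub flag, module, artifact class).
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (animal in names(dataset$traces)) {
    for (cond in c("V", "VT")) {
      trace <- dataset$traces[[animal]][[cond]]
      truth <- dataset$ground_truth[[animal]][[cond]]
      stem <- file.path(dir, paste0(animal, "_", cond))
      write_trace_matrix(trace, paste0(stem, "_traces.tsv"))

      C <- truth$coupling
      ids <- trace$roi_ids[seq_len(nrow(C))]
      ut <- which(upper.tri(C) & C > 0, arr.ind = TRUE)
      ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
      edge_lines <- c("node_i\tnode_j\tweight",
                      vapply(seq_len(nrow(ut)), function(e) {
                        paste(ids[ut[e, 1]], ids[ut[e, 2]],
                              .fmt(C[ut[e, 1], ut[e, 2]]), sep = "\t")
                      }, character(1)))
      writeLines(edge_lines, paste0(stem, "_truth_edges.tsv"))

      all_ids <- trace$roi_ids
      nodes <- data.frame(
        node_id = all_ids,
        is_hub = all_ids %in% truth$hub_ids,
        module = c(truth$module_assignment,
                   rep(NA_integer_, length(all_ids) - length(ids))),
        artifact_class = ifelse(
          all_ids %in% truth$artifact_ids,
          truth$artifact_class[match(all_ids, truth$artifact_ids)],
          "none"),
        stringsAsFactors = FALSE
      )
      write_table_tsv(nodes, paste0(stem, "_truth_nodes.tsv"))
    }
  }
  invisible(dir)
}
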