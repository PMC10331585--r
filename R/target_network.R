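#' @title Drug-target recurrence network filter
#' @name target_network
#' @description
#' The in-silico refinement filter. Hit drugs are linked to their annotated
#' protein targets (a bipartite table) and targets are linked to each other
#' by confidence-scored interactions. After discarding low-confidence
#' interactions, targets hit by several drugs ("recurrent" targets) define
#' the favorite hits; hits with no annotation at all are kept separately as
#' unknown hits for the downstream imaging filter.
NULL

#' Build a drug-target graph
#'
#' Restricts the drug-to-target pairs to the supplied hit set, deduplicates
#' them, and keeps undirected target-target edges whose confidence reaches
#' `confidence_cutoff` (inclusive, matching the usual "high confidence
#' 0.700" database convention). Duplicate undirected edges are collapsed
#' keeping the maximum confidence; self-edges are dropped.
#'
#' @param pairs data.frame with columns `drug_id`, `target_id`.
#' @param edges data.frame with columns `target_a`, `target_b`,
#'   `confidence` (in `[0, 1]`).
#' @param hits character vector of hit drug ids.
#' @param confidence_cutoff minimum retained confidence (default 0.7).
#' @return a `drug_target_graph` list with elements `pairs`, `target_edges`,
#'   `hit_ids`, `confidence_cutoff`.
#' @export
build_drug_target_graph <- function(pairs, edges, hits,
                                    confidence_cutoff = 0.7) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("drug_id", "target_id") %in% names(pairs)),
            all(c("target_a", "target_b", "confidence") %in% names(edges)))
  if (nrow(edges) > 0 &&
      (any(edges$confidence < 0) || any(edges$confidence > 1))) {
    stage_error("target_network", "confidence scores must lie in [0, 1]")
  }
  pairs <- unique(pairs[pairs$drug_id %in% hits,
                        c("drug_id", "target_id"), drop = FALSE])
  rownames(pairs) <- NULL

  edges <- edges[edges$confidence >= confidence_cutoff, , drop = FALSE]
  edges <- edges[edges$target_a != edges$target_b, , drop = FALSE]
  if (nrow(edges) > 0) {
    a <- pmin(edges$target_a, edges$target_b)
    b <- pmax(edges$target_a, edges$target_b)
    key <- paste(a, b, sep = "\r")
    conf <- vapply(split(edges$confidence, key), max, numeric(1))
    uk <- unique(key)
    parts <- strsplit(uk, "\r", fixed = TRUE)
    edges <- data.frame(
      target_a = vapply(parts, `[[`, character(1), 1),
      target_b = vapply(parts, `[[`, character(1), 2),
      confidence = as.numeric(conf[uk]),
      stringsAsFactors = FALSE)
    rownames(edges) <- NULL
  }
  structure(list(pairs = pairs, target_edges = edges,
                 hit_ids = unique(as.character(hits)),
                 confidence_cutoff = confidence_cutoff),
            class = "drug_target_graph")
}

#' @export
print.drug_target_graph <- function(x, ...) {
  cat(sprintf(
    "drug_target_graph: %d hits, %d drug-target pairs, %d target edges (confidence >= %.2f)\n",
    length(x$hit_ids), nrow(x$pairs), nrow(x$target_edges),
    x$confidence_cutoff))
  invisible(x)
}

#' Target recurrence counts
#'
#' Number of distinct hit drugs annotated to each target (duplicated pairs
#' count once).
#'
#' @param graph a [build_drug_target_graph()] result.
#' @return named integer vector, target id -> recurrence.
#' @export
target_recurrence <- function(graph) {
  stopifnot(inherits(graph, "drug_target_graph"))
  if (nrow(graph$pairs) == 0) return(setNames(integer(0), character(0)))
  tab <- table(unique(graph$pairs)$target_id)
  setNames(as.integer(tab), names(tab))
}

#' Select favorite and unknown hits by target recurrence
#'
#' Targets with recurrence at or above `recurrence_cutoff` are recurrent;
#' favorite hits are hits annotated to at least one recurrent target;
#' unknown hits are hits with no annotation at all (kept for downstream
#' filtering). Components are the connected components of the
#' confidence-filtered target graph (isolated annotated targets are
#' singleton components).
#'
#' @param graph a [build_drug_target_graph()] result.
#' @param recurrence recurrence counts from [target_recurrence()]; computed
#'   from `graph` when omitted.
#' @param recurrence_cutoff minimum recurrence (inclusive, default 3).
#' @return a `recurrence_report` list: `recurrence`, `recurrent_targets`,
#'   `favorite_hits`, `unknown_hits`, `components` (named integer vector
#'   target -> component id) and `recurrence_cutoff`.
#' @export
select_hits <- function(graph, recurrence = NULL, recurrence_cutoff = 3) {
  stopifnot(inherits(graph, "drug_target_graph"))
  if (is.null(recurrence)) recurrence <- target_recurrence(graph)
  recurrent <- names(recurrence)[recurrence >= recurrence_cutoff]
  annotated <- unique(graph$pairs$drug_id)
  favorite <- sort(unique(
    graph$pairs$drug_id[graph$pairs$target_id %in% recurrent]))
  unknown <- sort(setdiff(graph$hit_ids, annotated))

  nodes <- sort(unique(c(graph$pairs$target_id, graph$target_edges$target_a,
                         graph$target_edges$target_b)))
  components <- if (length(nodes) > 0) {
    g <- igraph::graph_from_data_frame(
      graph$target_edges[, c("target_a", "target_b"), drop = FALSE],
      directed = FALSE, vertices = nodes)
    comp <- igraph::components(g)$membership
    setNames(as.integer(comp), names(comp))
  } else {
    setNames(integer(0), character(0))
  }
  structure(
    list(recurrence = recurrence, recurrent_targets = sort(recurrent),
         favorite_hits = favorite, unknown_hits = unknown,
         components = components, recurrence_cutoff = recurrence_cutoff),
    class = "recurrence_report")
}

#' @export
print.recurrence_report <- function(x, ...) {
  cat(sprintf(
    "recurrence_report: %d recurrent target(s) (cutoff %d), %d favorite hit(s), %d unknown hit(s)\n",
    length(x$recurrent_targets), x$recurrence_cutoff,
    length(x$favorite_hits), length(x$unknown_hits)))
  invisible(x)
}

#' Export a drug-target network for graph viewers
#'
#' Writes `nodes.tsv` (id, type, recurrence, component, favorite) and
#' `edges.tsv` (from, to, kind, confidence) under `dir`, plus a JSON copy of
#' the recurrence report. Drug-target pairs get `kind = "drug_target"` and
#' confidence `NA`; target-target edges `kind = "target_target"`.
#'
#' @param graph a [build_drug_target_graph()] result.
#' @param report a [select_hits()] report.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
export_network <- function(graph, report, dir) {
  stopifnot(inherits(graph, "drug_target_graph"),
            inherits(report, "recurrence_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  drugs <- unique(graph$pairs$drug_id)
  targets <- sort(unique(c(graph$pairs$target_id,
                           graph$target_edges$target_a,
                           graph$target_edges$target_b)))
  nodes <- rbind(
    data.frame(id = drugs, type = rep("drug", length(drugs)),
               recurrence = rep(NA_integer_, length(drugs)),
               component = rep(NA_integer_, length(drugs)),
               favorite = drugs %in% report$favorite_hits,
               stringsAsFactors = FALSE),
    data.frame(id = targets, type = rep("target", length(targets)),
               recurrence = as.integer(report$recurrence[targets]),
               component = as.integer(report$components[targets]),
               favorite = rep(NA, length(targets)),
               stringsAsFactors = FALSE))
  edges <- rbind(
    if (nrow(graph$pairs) > 0) {
      data.frame(from = graph$pairs$drug_id, to = graph$pairs$target_id,
                 kind = "drug_target", confidence = NA_real_,
                 stringsAsFactors = FALSE)
    },
    if (nrow(graph$target_edges) > 0) {
      data.frame(from = graph$target_edges$target_a,
                 to = graph$target_edges$target_b,
                 kind = "target_target",
                 confidence = graph$target_edges$confidence,
                 stringsAsFactors = FALSE)
    })
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        kind = character(0), confidence = numeric(0))
  }
  nodes_path <- file.path(dir, "nodes.tsv")
  edges_path <- file.path(dir, "edges.tsv")
  json_path <- file.path(dir, "recurrence_report.json")
  write.table(nodes, nodes_path, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(edges, edges_path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(recurrence = as.list(report$recurrence),
         recurrent_targets = report$recurrent_targets,
         favorite_hits = report$favorite_hits,
         unknown_hits = report$unknown_hits,
         components = as.list(report$components),
         recurrence_cutoff = report$recurrence_cutoff),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(nodes = nodes_path, edges = edges_path, report = json_path))
}
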