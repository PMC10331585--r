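#' Parameters of a synthetic drug-target table pair
#'
#' Describes a small bipartite drug-to-target annotation table plus a
#' confidence-scored target-target interaction table, emulating exports from
#' curated drug-target and protein-interaction databases. The default
#' unknown fraction (0.25) matches the typical share of screened compounds
#' with no annotated target.
#'
#' @param n_hit_drugs number of hit drugs annotated.
#' @param n_targets number of background targets available.
#' @param recurrent_target_spec named integer vector `c(T1 = 3, ...)`: each
#'   listed target is mapped to exactly that many distinct drugs.
#' @param unknown_fraction fraction of drugs with zero annotated targets.
#' @param edge_density probability that any target pair is connected.
#' @param max_extra_targets background targets drawn per remaining drug
#'   (uniform 1..max).
#' @param seed integer seed.
#' @return a `network_params` list.
#' @export
network_params <- function(n_hit_drugs, n_targets = 20,
                           recurrent_target_spec = integer(0),
                           unknown_fraction = 0.25,
                           edge_density = 0.1,
                           max_extra_targets = 2,
                           seed = 1) {
  spec <- recurrent_target_spec
  stopifnot(n_hit_drugs >= 1, n_targets >= 0,
            unknown_fraction >= 0, unknown_fraction <= 1,
            edge_density >= 0, edge_density <= 1,
            all(spec >= 1), max_extra_targets >= 1)
  if (length(spec) > 0 && is.null(names(spec))) {
    stage_error("synthetic_data",
                "recurrent_target_spec must be a named vector")
  }
  structure(
    list(n_hit_drugs = as.integer(n_hit_drugs),
         n_targets = as.integer(n_targets),
         recurrent_target_spec = spec,
         unknown_fraction = unknown_fraction,
         edge_density = edge_density,
         max_extra_targets = as.integer(max_extra_targets),
         seed = as.integer(seed)),
    class = "network_params")
}

#' Simulate drug-to-target and target-target tables
#'
#' Constructs the two input tables of the network filter. Each entry
#' `(T, m)` of `recurrent_target_spec` maps exactly `m` distinct annotated
#' drugs to target `T` (so `T` has recurrence `m` by construction). A
#' `unknown_fraction` share of drugs receives zero targets. Remaining
#' annotated drugs get 1 to `max_extra_targets` background targets.
#' Undirected target-target edges are drawn independently with
#' `edge_density` and uniform confidences on `[0, 1]`. Deterministic given
#' the seed.
#'
#' @param params a [network_params()] list.
#' @param drug_ids optional drug id vector (default `H0001..`).
#' @return list with `pairs` (data.frame drug_id, target_id), `edges`
#'   (data.frame target_a, target_b, confidence), `hit_ids`, and
#'   `unknown_ids` (drugs designed with no annotation).
#' @export
simulate_drug_target_tables <- function(params, drug_ids = NULL) {
  stopifnot(inherits(params, "network_params"))
  n <- params$n_hit_drugs
  if (is.null(drug_ids)) drug_ids <- sprintf("H%04d", seq_len(n))
  stopifnot(length(drug_ids) == n)
  n_unknown <- floor(params$unknown_fraction * n)
  spec <- params$recurrent_target_spec
  n_known <- n - n_unknown
  if (length(spec) > 0 && max(spec) > n_known) {
    stage_error("synthetic_data",
                "recurrent-target multiplicity exceeds the annotated drugs")
  }
  targets <- sprintf("T%03d", seq_len(params$n_targets))
  targets <- union(names(spec), targets)

  with_stream(params$seed, "network-tables", {
    unknown_ids <- if (n_unknown > 0) sample(drug_ids, n_unknown)
                   else character(0)
    known_ids <- setdiff(drug_ids, unknown_ids)
    pairs <- list()
    for (t in names(spec)) {
      chosen <- sample(known_ids, spec[[t]])
      pairs[[t]] <- data.frame(drug_id = chosen, target_id = t,
                               stringsAsFactors = FALSE)
    }
    background <- setdiff(targets, names(spec))
    covered <- unique(unlist(lapply(pairs, `[[`, "drug_id")))
    rest <- setdiff(known_ids, covered)
    if (length(rest) > 0 && length(background) > 0) {
      extra <- do.call(rbind, lapply(rest, function(d) {
        k <- sample(params$max_extra_targets, 1)
        data.frame(drug_id = d,
                   target_id = sample(background,
                                      min(k, length(background))),
                   stringsAsFactors = FALSE)
      }))
      pairs <- c(pairs, list(extra))
    }
    pairs <- if (length(pairs)) do.call(rbind, pairs) else
      data.frame(drug_id = character(0), target_id = character(0))
    rownames(pairs) <- NULL

    used <- sort(unique(c(pairs$target_id, names(spec))))
    if (length(used) >= 2) {
      combos <- t(utils::combn(used, 2))
      keep <- runif(nrow(combos)) < params$edge_density
      edges <- data.frame(target_a = combos[keep, 1],
                          target_b = combos[keep, 2],
                          confidence = runif(sum(keep)),
                          stringsAsFactors = FALSE)
    } else {
      edges <- data.frame(target_a = character(0), target_b = character(0),
                          confidence = numeric(0))
    }
    list(pairs = pairs, edges = edges, hit_ids = drug_ids,
         unknown_ids = sort(unknown_ids))
  })
}

#' Write / read the network tables as TSV
#'
#' `pairs` is written as a two-column TSV (drug_id, target_id) and `edges`
#' as a three-column TSV (target_a, target_b, confidence).
#'
#' @param tables list as returned by [simulate_drug_target_tables()].
#' @param pairs_path,edges_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_network_tables <- function(tables, pairs_path, edges_path) {
  write.table(tables$pairs, pairs_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(tables$edges, edges_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(c(pairs = pairs_path, edges = edges_path))
}

#' @rdname write_network_tables
#' @export
read_network_tables <- function(pairs_path, edges_path) {
  pairs <- read.delim(pairs_path, stringsAsFactors = FALSE)
  edges <- read.delim(edges_path, stringsAsFactors = FALSE)
  list(pairs = pairs, edges = edges)
}
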