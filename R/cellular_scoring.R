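#' @title Cellular hit refinement
#' @name cellular_scoring
#' @description
#' Final refinement of hits on the three imaging parameters: (1) number of
#' AChR clusters, (2) NMJ structure overlap, (3) mean axonal length. Each
#' drug's quadruplicate of embryo metrics is averaged and z-scored against
#' the distribution of individual WT embryos (median/MAD, the same robust
#' convention as the behavioral screen). A parameter counts as rescued when
#' its z exceeds the threshold; the final-hit call requires rescue of the
#' two NMJ parameters common to all validated hits (clusters and overlap),
#' with axon length reported but not required.
NULL

CELLULAR_PARAMS <- c("n_achr_clusters", "overlap_percent",
                     "mean_axon_length_um")

#' Three-parameter cellular z-score of a drug
#'
#' For each parameter: `z = (mean over the drug's embryos - median(WT)) /
#' mad(WT)` with the raw MAD and the same zero-spread guard as the
#' behavioral scoring.
#'
#' @param drug_metrics `cellular_metrics` rows of the drug's (typically
#'   quadruplicate) embryos.
#' @param wt_metrics `cellular_metrics` rows of individual WT embryos
#'   (at least 3).
#' @param params metric columns to score (default the three standard
#'   parameters).
#' @param mad_constant MAD consistency constant (default 1).
#' @return named numeric z-vector (z_clusters, z_overlap, z_axon_length for
#'   the defaults).
#' @export
cellular_z <- function(drug_metrics, wt_metrics,
                       params = CELLULAR_PARAMS, mad_constant = 1) {
  if (nrow(wt_metrics) < 3) {
    stage_error("cellular_scoring", "need at least 3 WT embryos")
  }
  vapply(params, function(p) {
    wt <- wt_metrics[[p]]
    wt <- wt[!is.na(wt)]
    m <- median(wt)
    s <- raw_mad(wt, mad_constant)
    if (s == 0) {
      s <- .Machine$double.eps * max(abs(m), 1)
      warning(sprintf("WT MAD is zero for %s; using a guarded divisor", p),
              call. = FALSE)
    }
    (mean(drug_metrics[[p]], na.rm = TRUE) - m) / s
  }, numeric(1))
}

#' Rescue flags and final-hit call from a cellular z-vector
#'
#' A parameter is rescued when its z-score strictly exceeds `z_threshold`
#' (default -1, adopted from the behavioral per-fish criterion). The final
#' hit call requires parameters 1 (#AChR clusters) and 2 (overlap); the
#' third (axon length) is reported but not required.
#'
#' @param z3 numeric z-vector of length 3 (clusters, overlap, axon length).
#' @param z_threshold rescue threshold (default -1).
#' @return list with `rescue_flags` (logical, named like `z3`), `final_hit`
#'   and `n_rescued`.
#' @export
#' @examples
#' rescue_call(c(0.2, -0.5, -3))  # final hit; axon length not rescued
rescue_call <- function(z3, z_threshold = -1) {
  stopifnot(length(z3) == 3, all(is.finite(z3)))
  flags <- z3 > z_threshold
  list(rescue_flags = flags, final_hit = unname(flags[1] && flags[2]),
       n_rescued = sum(flags))
}

#' Score a panel of drugs against WT embryo metrics
#'
#' @param metrics `cellular_metrics` data.frame of all embryos, with `group`
#'   and `drug_id` columns.
#' @param wt_group group label of the WT embryos (default `"WT_CONTROL"`).
#' @param z_threshold rescue threshold, see [rescue_call()].
#' @param mad_constant MAD consistency constant.
#' @return a `cellular_scores` data.frame: drug_id, z_clusters, z_overlap,
#'   z_axon_length, rescued_clusters, rescued_overlap, rescued_axon_length,
#'   n_rescued, final_hit.
#' @export
cellular_scores <- function(metrics, wt_group = "WT_CONTROL",
                            z_threshold = -1, mad_constant = 1) {
  wt <- metrics[!is.na(metrics$group) & metrics$group == wt_group, ,
                drop = FALSE]
  drugs <- unique(metrics$drug_id[!is.na(metrics$drug_id)])
  out <- do.call(rbind, lapply(drugs, function(d) {
    dm <- metrics[!is.na(metrics$drug_id) & metrics$drug_id == d, ,
                  drop = FALSE]
    z3 <- cellular_z(dm, wt, mad_constant = mad_constant)
    call <- rescue_call(z3, z_threshold)
    data.frame(drug_id = d,
               z_clusters = z3[[1]], z_overlap = z3[[2]],
               z_axon_length = z3[[3]],
               rescued_clusters = call$rescue_flags[[1]],
               rescued_overlap = call$rescue_flags[[2]],
               rescued_axon_length = call$rescue_flags[[3]],
               n_rescued = call$n_rescued,
               final_hit = call$final_hit,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(drug_id = character(0), z_clusters = numeric(0),
                      z_overlap = numeric(0), z_axon_length = numeric(0),
                      rescued_clusters = logical(0),
                      rescued_overlap = logical(0),
                      rescued_axon_length = logical(0),
                      n_rescued = integer(0), final_hit = logical(0))
  }
  rownames(out) <- NULL
  class(out) <- c("cellular_scores", class(out))
  out
}

#' Holm step-down adjustment
#'
#' Explicit implementation: sort the raw p-values ascending; the i-th
#' adjusted value is `max_{j <= i} min(1, (m - j + 1) * p_(j))`, reported in
#' the original order.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values, same order as `p`.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
holm_adjust <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Nonparametric group comparison with Holm-corrected post hoc tests
#'
#' Kruskal-Wallis omnibus test across the groups; when the omnibus p-value
#' is at or below `posthoc_alpha`, all pairwise rank-sum (Mann-Whitney)
#' tests are run and adjusted with [holm_adjust()]. Rank-sum tests use the
#' exact distribution when the combined sample size is at most
#' `exact_max_n` and there are no ties, and the tie-corrected normal
#' approximation otherwise.
#'
#' @param groups named list mapping group name to a numeric vector of
#'   per-embryo values (>= 2 groups of >= 2 values each).
#' @param posthoc_alpha omnibus gate for running post hoc tests
#'   (default 0.05).
#' @param exact_max_n maximum combined n for exact rank-sum p-values
#'   (default 12).
#' @return a `group_comparison` list: `omnibus_stat`, `omnibus_p`,
#'   `pairwise` (data.frame group_a, group_b, statistic, raw_p,
#'   holm_adjusted_p; empty when the omnibus gate fails).
#' @export
group_compare <- function(groups, posthoc_alpha = 0.05, exact_max_n = 12) {
  if (length(groups) < 2) {
    stage_error("cellular_scoring", "need at least two groups")
  }
  small <- vapply(groups, length, integer(1)) < 2
  if (any(small)) {
    stage_error("cellular_scoring", paste0(
      "group(s) with fewer than 2 values: ",
      paste(names(groups)[small], collapse = ", ")))
  }
  kw <- kruskal.test(groups)
  pairwise <- data.frame(group_a = character(0), group_b = character(0),
                         statistic = numeric(0), raw_p = numeric(0),
                         holm_adjusted_p = numeric(0))
  if (kw$p.value <= posthoc_alpha) {
    combos <- utils::combn(names(groups), 2)
    rows <- apply(combos, 2, function(pair) {
      a <- groups[[pair[1]]]; b <- groups[[pair[2]]]
      exact <- (length(a) + length(b)) <= exact_max_n &&
        !any(duplicated(c(a, b)))
      wt <- suppressWarnings(wilcox.test(a, b, exact = exact,
                                         correct = TRUE))
      data.frame(group_a = pair[1], group_b = pair[2],
                 statistic = unname(wt$statistic), raw_p = wt$p.value,
                 stringsAsFactors = FALSE)
    })
    pairwise <- do.call(rbind, rows)
    pairwise$holm_adjusted_p <- holm_adjust(pairwise$raw_p)
    rownames(pairwise) <- NULL
  }
  structure(list(omnibus_stat = unname(kw$statistic),
                 omnibus_p = kw$p.value, pairwise = pairwise),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison: Kruskal-Wallis chi-squared = %.3f, p = %.4g; %d pairwise test(s)\n",
              x$omnibus_stat, x$omnibus_p, nrow(x$pairwise)))
  invisible(x)
}

#' Hit map: ranked summary of cellular scores
#'
#' Orders drugs by the number of rescued parameters, then by mean z, and
#' counts how many drugs rescue all three parameters, the two NMJ parameters
#' (final hits), or fewer.
#'
#' @param scores a [cellular_scores()] data.frame.
#' @return list with `table` (ordered scores with `mean_z`) and `counts`
#'   (`all_three`, `nmj_pair`, `fewer`).
#' @export
hitmap <- function(scores) {
  stopifnot(inherits(scores, "cellular_scores"))
  tab <- as.data.frame(scores)
  if (nrow(tab) > 0) {
    tab$mean_z <- rowMeans(tab[, c("z_clusters", "z_overlap",
                                   "z_axon_length")])
    tab <- tab[order(-tab$n_rescued, -tab$mean_z), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab$mean_z <- numeric(0)
  }
  counts <- c(all_three = sum(tab$n_rescued == 3),
              nmj_pair = sum(tab$final_hit & tab$n_rescued < 3),
              fewer = sum(!tab$final_hit))
  list(table = tab, counts = counts)
}
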