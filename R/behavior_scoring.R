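#' @title Behavioral screen statistics
#' @name behavior_scoring
#' @description
#' The primary screen statistics. Distances on each plate are rescaled by the
#' median of the plate's live wild-type (WT) controls (fold-of-control
#' median normalization), each treated larva is scored with a robust z-score
#' against the plate's normalized WT controls,
#' \deqn{z = \frac{x' - \mathrm{median}(c')}{\mathrm{mad}(c')},}
#' and every drug's quadruplicate is classified as toxic, non-hit, or an
#' A/B hit. Assay quality is the Z'-factor
#' \deqn{Z' = 1 - \frac{3(\sigma_p + \sigma_n)}{|\mu_p - \mu_n|},}
#' where \eqn{\mu} and \eqn{\sigma} are the median and raw median absolute
#' deviation of the positive (WT) and negative (morphant) controls. The
#' rescreen statistic is Normalized Percent(age) Activation (NPA), a 0-100%
#' rescale of a raw readout between the negative- and positive-control
#' medians.
NULL

#' Summarize a control group
#'
#' @param values numeric readouts of one control group (live fish only).
#' @param mad_constant consistency constant passed to [raw_mad()].
#' @return list with `mu` (median), `sigma` (raw MAD) and `n`.
#' @export
control_summary <- function(values, mad_constant = 1) {
  values <- values[!is.na(values)]
  if (length(values) < 1) {
    stage_error("behavior_scoring", "control group is empty")
  }
  list(mu = median(values), sigma = raw_mad(values, mad_constant),
       n = length(values))
}

#' Z'-factor assay quality
#'
#' `1 - 3 * (sigma_p + sigma_n) / abs(mu_p - mu_n)`, computed from the
#' median/MAD summaries of the positive and negative controls. Always <= 1,
#' equal to 1 only when both spreads vanish; the absolute separation makes
#' the statistic symmetric in which control is labeled positive.
#'
#' @param pos,neg [control_summary()] lists for the positive (WT) and
#'   negative (morphant) controls.
#' @return the Z'-factor (a dimensionless number <= 1).
#' @export
#' @examples
#' z_prime(control_summary(c(90, 100, 110)), control_summary(c(-5, 0, 5)))
z_prime <- function(pos, neg) {
  sep <- abs(pos$mu - neg$mu)
  if (sep == 0) {
    stage_error("behavior_scoring",
                "Z'-factor undefined: control medians coincide")
  }
  1 - 3 * (pos$sigma + neg$sigma) / sep
}

#' Median-based plate normalization
#'
#' Divides raw distances by the median of the plate's WT control distances,
#' so the WT median maps to 1 and multiplicative plate effects cancel.
#'
#' @param distances numeric readouts to normalize.
#' @param wt_controls numeric WT control readouts from the same plate.
#' @return normalized values `x / median(wt_controls)`.
#' @export
median_normalize <- function(distances, wt_controls) {
  wt_controls <- wt_controls[!is.na(wt_controls)]
  if (length(wt_controls) == 0) {
    stage_error("behavior_scoring", "no WT controls to normalize against")
  }
  m <- median(wt_controls)
  if (m == 0) {
    stage_error("behavior_scoring",
                "WT control median is zero; cannot normalize")
  }
  distances / m
}

#' Robust z-score against normalized WT controls
#'
#' `z = (x' - median(c')) / mad(c')` with the raw (unscaled) MAD. When the
#' WT spread is exactly zero, the divisor is replaced by the smallest
#' positive representable spread relative to the median (with a warning) so
#' classification can proceed on degenerate fixtures.
#'
#' @param x_prime normalized value(s) to score.
#' @param wt_prime normalized WT control values.
#' @param mad_constant consistency constant for the MAD (default 1).
#' @return z-score(s), same length as `x_prime`.
#' @export
#' @examples
#' robust_z(0.7, c(0.8, 1.0, 1.2, 1.0))  # -3
robust_z <- function(x_prime, wt_prime, mad_constant = 1) {
  wt_prime <- wt_prime[!is.na(wt_prime)]
  if (length(wt_prime) == 0) {
    stage_error("behavior_scoring", "no WT controls for z-scoring")
  }
  m <- median(wt_prime)
  s <- raw_mad(wt_prime, mad_constant)
  if (s == 0) {
    s <- .Machine$double.eps * max(abs(m), 1)
    warning("WT control MAD is zero; using a guarded divisor",
            call. = FALSE)
  }
  (x_prime - m) / s
}

#' Classify a drug's quadruplicate of fish z-scores
#'
#' Four-way call from the per-fish z-scores of one drug:
#' * `TOXIC` when `>= toxic_dead_min` of the fish died;
#' * otherwise a hit when at least `hit_fish_min` live fish have
#'   `z > fish_z_threshold`, split into `HIT_A` (mean z over live fish
#'   strictly above `mean_z_threshold`) and `HIT_B` (mean at or below it);
#' * `NON_HIT` otherwise.
#' Dead fish never satisfy the per-fish criterion and are excluded from the
#' mean.
#'
#' @param z numeric z-scores, length `replicate_count`; entries for dead fish
#'   are ignored (may be `NA`).
#' @param alive logical vector, same length.
#' @param mean_z_threshold mean-z boundary between A and B hits (default 0).
#' @param fish_z_threshold per-fish rescue threshold (default -1).
#' @param toxic_dead_min deaths required for a toxicity call (default 3).
#' @param hit_fish_min live fish above threshold required for a hit
#'   (default 2).
#' @param replicate_count expected arity (default 4).
#' @return one of `"TOXIC"`, `"NON_HIT"`, `"HIT_A"`, `"HIT_B"`.
#' @export
#' @examples
#' classify_drug(c(0.3, 0.2, -0.1, 0.1), rep(TRUE, 4))            # HIT_A
#' classify_drug(c(0.5, 0.4, -2.5, -2.8), rep(TRUE, 4))           # HIT_B
#' classify_drug(c(NA, NA, NA, 0.5), c(FALSE, FALSE, FALSE, TRUE)) # TOXIC
classify_drug <- function(z, alive, mean_z_threshold = 0,
                          fish_z_threshold = -1, toxic_dead_min = 3,
                          hit_fish_min = 2, replicate_count = 4) {
  if (length(z) != replicate_count || length(alive) != replicate_count) {
    stage_error("behavior_scoring", sprintf(
      "expected %d fish per drug, got %d z-scores and %d alive flags",
      replicate_count, length(z), length(alive)))
  }
  n_dead <- sum(!alive)
  if (n_dead >= toxic_dead_min) return("TOXIC")
  z_alive <- z[alive]
  n_above <- sum(z_alive > fish_z_threshold, na.rm = TRUE)
  if (n_above >= hit_fish_min) {
    if (mean(z_alive, na.rm = TRUE) > mean_z_threshold) "HIT_A" else "HIT_B"
  } else {
    "NON_HIT"
  }
}

# internal: split a screen table into analysis pieces, excluding flagged and
# (for control summaries) dead fish
plate_pieces <- function(table) {
  obs <- table$observations
  obs <- obs[!obs$excluded, , drop = FALSE]
  split(obs, obs$plate)
}

#' Score a full primary screen
#'
#' Per plate: summarize live controls, normalize every distance by the WT
#' median, z-score each treated fish against the plate's normalized live WT
#' controls, then classify every drug's replicate set with
#' [classify_drug()]. Each fish is scored against the controls of its own
#' plate, so a drug's replicates may sit on different reading plates.
#'
#' @param table a [screen_table()].
#' @param ... classification parameters forwarded to [classify_drug()].
#' @param mad_constant consistency constant for all MADs.
#' @return a `screen_result` list:
#'   * `per_fish`: data.frame (drug_id, fish_index, plate, alive, z);
#'   * `per_drug`: data.frame (drug_id, n_dead, n_above, mean_z, category);
#'   * `plate_quality`: data.frame (plate, zprime, n_wt, n_mo);
#'   * `counts`: named category counts partitioning the drug list.
#' @export
screen_scores <- function(table, ..., mad_constant = 1) {
  stopifnot(inherits(table, "screen_table"))
  pieces <- plate_pieces(table)
  per_fish <- list()
  quality <- list()
  for (p in names(pieces)) {
    obs <- pieces[[p]]
    wt <- obs[obs$group == "WT_CONTROL" & obs$alive, , drop = FALSE]
    mo <- obs[obs$group == "MO_CONTROL" & obs$alive, , drop = FALSE]
    if (nrow(wt) == 0) {
      stage_error("behavior_scoring",
                  sprintf("plate %s has no live WT controls", p))
    }
    if (nrow(mo) == 0) {
      stage_error("behavior_scoring",
                  sprintf("plate %s has no live MO controls", p))
    }
    wt_prime <- median_normalize(wt$distance_m, wt$distance_m)
    mo_prime <- median_normalize(mo$distance_m, wt$distance_m)
    zp <- z_prime(control_summary(wt_prime, mad_constant),
                  control_summary(mo_prime, mad_constant))
    quality[[p]] <- data.frame(plate = as.integer(p), zprime = zp,
                               n_wt = nrow(wt), n_mo = nrow(mo))
    treated <- obs[obs$group == "TREATED", , drop = FALSE]
    if (nrow(treated) > 0) {
      x_prime <- median_normalize(treated$distance_m, wt$distance_m)
      z <- robust_z(x_prime, wt_prime, mad_constant)
      per_fish[[p]] <- data.frame(
        drug_id = treated$drug_id, fish_index = treated$fish_index,
        plate = treated$plate, alive = treated$alive,
        z = ifelse(treated$alive, z, NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  per_fish <- if (length(per_fish)) do.call(rbind, per_fish) else
    data.frame(drug_id = character(0), fish_index = integer(0),
               plate = integer(0), alive = logical(0), z = numeric(0))
  rownames(per_fish) <- NULL

  drug_ids <- table$drugs$drug_id
  per_drug <- do.call(rbind, lapply(drug_ids, function(d) {
    rows <- per_fish[per_fish$drug_id == d, , drop = FALSE]
    cat <- classify_drug(rows$z, rows$alive,
                         replicate_count = nrow(rows), ...)
    data.frame(
      drug_id = d, n_dead = sum(!rows$alive),
      n_above = sum(rows$z[rows$alive] > -1, na.rm = TRUE),
      mean_z = if (any(rows$alive)) mean(rows$z[rows$alive]) else NA_real_,
      category = cat, stringsAsFactors = FALSE)
  }))
  if (is.null(per_drug)) {
    per_drug <- data.frame(drug_id = character(0), n_dead = integer(0),
                           n_above = integer(0), mean_z = numeric(0),
                           category = character(0))
  }
  counts <- table(factor(per_drug$category,
                         levels = c("TOXIC", "NON_HIT", "HIT_A", "HIT_B")))
  structure(
    list(per_fish = per_fish, per_drug = per_drug,
         plate_quality = do.call(rbind, quality),
         counts = setNames(as.integer(counts), names(counts))),
    class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "screen_result: %d drugs | TOXIC %d, NON_HIT %d, HIT_A %d, HIT_B %d | median plate Z' = %.3f\n",
    nrow(x$per_drug), x$counts[["TOXIC"]], x$counts[["NON_HIT"]],
    x$counts[["HIT_A"]], x$counts[["HIT_B"]],
    median(x$plate_quality$zprime)))
  invisible(x)
}

#' Hit drug ids of a screen result
#'
#' @param result a `screen_result` from [screen_scores()].
#' @return character vector of drug ids classified `HIT_A` or `HIT_B`.
#' @export
screen_hits <- function(result) {
  stopifnot(inherits(result, "screen_result"))
  result$per_drug$drug_id[result$per_drug$category %in% c("HIT_A", "HIT_B")]
}

#' Normalized Percent Activation
#'
#' Rescales a raw readout onto a 0-100% effect scale between the control
#' medians. The default `"standard"` orientation,
#' `(X - mu_n) / (mu_p - mu_n) * 100`, maps the negative-control median to
#' 0% (no effect) and the positive-control median to 100% (full WT-like
#' activity). The `"as_printed"` variant is the sign-flipped form
#' `(mu_n - X) / (mu_p - mu_n) * 100` found in some protocol write-ups; it
#' returns negative values for rescued animals and is kept only for
#' comparability.
#'
#' @param x raw readout value(s).
#' @param mu_neg median of the negative (disease) control.
#' @param mu_pos median of the positive (WT) control.
#' @param variant `"standard"` (default) or `"as_printed"`.
#' @return NPA value(s) in percent.
#' @export
#' @examples
#' npa(6, mu_neg = 2, mu_pos = 10)  # 50
npa <- function(x, mu_neg, mu_pos, variant = c("standard", "as_printed")) {
  variant <- match.arg(variant)
  if (mu_pos == mu_neg) {
    stage_error("behavior_scoring",
                "NPA undefined: control medians coincide")
  }
  v <- (x - mu_neg) / (mu_pos - mu_neg) * 100
  if (variant == "as_printed") -v else v
}

#' Rescreen scoring by Normalized Percent Activation
#'
#' Per plate, takes the medians of the live WT (positive) and MO (negative)
#' control raw distances, converts every live treated fish to NPA, and
#' averages per drug. A drug passes when its mean NPA reaches `cutoff`
#' (inclusive). Dead fish are excluded from the mean but reported.
#'
#' @param table a [screen_table()] of the rescreen.
#' @param cutoff mean-NPA pass threshold in percent (default 50).
#' @param variant NPA orientation, see [npa()].
#' @return data.frame (drug_id, n_alive, n_dead, mean_npa, pass) plus a
#'   `per_fish` attribute with fish-level NPA values.
#' @export
rescreen_npa <- function(table, cutoff = 50,
                         variant = c("standard", "as_printed")) {
  stopifnot(inherits(table, "screen_table"))
  variant <- match.arg(variant)
  pieces <- plate_pieces(table)
  per_fish <- list()
  for (p in names(pieces)) {
    obs <- pieces[[p]]
    wt <- obs[obs$group == "WT_CONTROL" & obs$alive, , drop = FALSE]
    mo <- obs[obs$group == "MO_CONTROL" & obs$alive, , drop = FALSE]
    if (nrow(wt) == 0 || nrow(mo) == 0) {
      stage_error("behavior_scoring",
                  sprintf("plate %s lacks live controls for NPA", p))
    }
    treated <- obs[obs$group == "TREATED", , drop = FALSE]
    if (nrow(treated) == 0) next
    per_fish[[p]] <- data.frame(
      drug_id = treated$drug_id, fish_index = treated$fish_index,
      plate = treated$plate, alive = treated$alive,
      npa = ifelse(treated$alive,
                   npa(treated$distance_m, median(mo$distance_m),
                       median(wt$distance_m), variant),
                   NA_real_),
      stringsAsFactors = FALSE)
  }
  per_fish <- if (length(per_fish)) do.call(rbind, per_fish) else
    data.frame(drug_id = character(0), fish_index = integer(0),
               plate = integer(0), alive = logical(0), npa = numeric(0))
  rownames(per_fish) <- NULL
  ids <- unique(table$observations$drug_id[
    table$observations$group == "TREATED"])
  out <- do.call(rbind, lapply(ids, function(d) {
    rows <- per_fish[per_fish$drug_id == d, , drop = FALSE]
    m <- if (any(rows$alive)) mean(rows$npa[rows$alive]) else NA_real_
    data.frame(drug_id = d, n_alive = sum(rows$alive),
               n_dead = sum(!rows$alive), mean_npa = m,
               pass = !is.na(m) && m >= cutoff, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(drug_id = character(0), n_alive = integer(0),
                      n_dead = integer(0), mean_npa = numeric(0),
                      pass = logical(0))
  }
  attr(out, "per_fish") <- per_fish
  out
}

#' Dose-response summary with toxicity gating
#'
#' Summarizes treated distances per dose and flags doses whose dead fraction
#' reaches `toxic_dead_min / replicate_count`; flagged doses are excluded
#' from the response curve (column `included`). The standard error is absent
#' when fewer than two fish survive a dose.
#'
#' @param tables named list mapping dose label (coercible to numeric) to a
#'   [screen_table()] of that dose.
#' @param toxic_dead_min deaths per replicate set that define toxicity
#'   (default 3).
#' @param replicate_count designed larvae per drug (default taken from the
#'   first table).
#' @return data.frame (dose, n, n_dead, frac_dead, mean_distance_m, sem,
#'   toxic, included), ordered by dose.
#' @export
dose_response_summary <- function(tables, toxic_dead_min = 3,
                                  replicate_count = NULL) {
  if (length(tables) < 2) {
    stage_error("behavior_scoring",
                "dose-response needs at least two doses")
  }
  if (is.null(replicate_count)) {
    replicate_count <- tables[[1]]$replicate_count
  }
  doses <- as.numeric(names(tables))
  out <- do.call(rbind, lapply(seq_along(tables), function(i) {
    obs <- tables[[i]]$observations
    tr <- obs[obs$group == "TREATED" & !obs$excluded, , drop = FALSE]
    alive <- tr[tr$alive, , drop = FALSE]
    n_alive <- nrow(alive)
    frac_dead <- if (nrow(tr) > 0) sum(!tr$alive) / nrow(tr) else 0
    data.frame(
      dose = doses[i], n = nrow(tr), n_dead = sum(!tr$alive),
      frac_dead = frac_dead,
      mean_distance_m = if (n_alive > 0) mean(alive$distance_m) else NA_real_,
      sem = if (n_alive >= 2) sd(alive$distance_m) / sqrt(n_alive)
            else NA_real_,
      toxic = frac_dead >= toxic_dead_min / replicate_count)
  }))
  out$included <- !out$toxic
  out[order(out$dose), , drop = FALSE]
}

#' Write screen scores and a JSON screen report
#'
#' @param result a `screen_result` from [screen_scores()].
#' @param csv_path per-drug scores CSV path.
#' @param json_path JSON report path (per-plate Z', category counts).
#' @return invisibly, a list of the two paths.
#' @export
write_screen_report <- function(result, csv_path, json_path) {
  stopifnot(inherits(result, "screen_result"))
  write.csv(result$per_drug, csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(plate_quality = result$plate_quality,
         counts = as.list(result$counts)),
    json_path, auto_unbox = TRUE, dataframe = "rows", digits = NA)
  invisible(list(csv = csv_path, json = json_path))
}
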