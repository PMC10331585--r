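#' Parameters of a synthetic behavioral cohort
#'
#' Defaults encode the disease model's stated phenotype: morphants show a
#' complete loss of locomotion in 79.2% of animals, and the remaining movers
#' travel 85% less than wild type. Wild-type distances are log-normal
#' (positive support, right-skewed) around a 1 m median with 25% dispersion;
#' the absolute scale is a free parameter of the assay.
#'
#' @param n_drugs number of treated compounds.
#' @param wt_distance_median_m median WT distance traveled in 1 h (meters).
#' @param wt_distance_cv coefficient of variation of the WT log-normal.
#' @param mo_zero_fraction probability that a morphant is a complete
#'   non-mover (distance 0).
#' @param mo_mover_reduction fractional distance reduction of moving
#'   morphants relative to WT.
#' @param rescue_strength per-drug rescue effect e in `[0, 1]`; scalar is
#'   recycled. A treated fish's distance interpolates between a morphant
#'   draw (e = 0) and a WT draw (e = 1).
#' @param toxicity_prob per-drug probability that a treated fish dies;
#'   scalar is recycled.
#' @param replicate_count larvae per drug (default 4).
#' @param n_controls_per_plate WT and MO control fish per reading plate
#'   (default 8, one column of a 96-well plate each).
#' @param n_plates number of library plates (each is read as
#'   `replicate_count` reading plates); defaults to the minimum needed for
#'   80 drugs per plate (columns 2-11), at least 1.
#' @param seed integer master seed.
#' @return a `cohort_params` list.
#' @export
cohort_params <- function(n_drugs = 0,
                          wt_distance_median_m = 1.0,
                          wt_distance_cv = 0.25,
                          mo_zero_fraction = 0.792,
                          mo_mover_reduction = 0.85,
                          rescue_strength = 0,
                          toxicity_prob = 0,
                          replicate_count = 4,
                          n_controls_per_plate = 8,
                          n_plates = NULL,
                          seed = 1) {
  stopifnot(
    n_drugs >= 0, wt_distance_median_m > 0, wt_distance_cv > 0,
    mo_zero_fraction >= 0, mo_zero_fraction <= 1,
    mo_mover_reduction >= 0, mo_mover_reduction <= 1,
    all(rescue_strength >= 0), all(rescue_strength <= 1),
    all(toxicity_prob >= 0), all(toxicity_prob <= 1),
    replicate_count >= 1, n_controls_per_plate >= 1)
  rescue_strength <- rep_len(rescue_strength, n_drugs)
  toxicity_prob <- rep_len(toxicity_prob, n_drugs)
  if (is.null(n_plates)) n_plates <- max(1L, ceiling(n_drugs / 80))
  if (n_drugs > n_plates * 80) {
    stage_error("synthetic_data",
                "more than 80 drugs per plate do not fit columns 2-11")
  }
  structure(
    list(n_drugs = as.integer(n_drugs),
         wt_distance_median_m = wt_distance_median_m,
         wt_distance_cv = wt_distance_cv,
         mo_zero_fraction = mo_zero_fraction,
         mo_mover_reduction = mo_mover_reduction,
         rescue_strength = rescue_strength,
         toxicity_prob = toxicity_prob,
         replicate_count = as.integer(replicate_count),
         n_controls_per_plate = as.integer(n_controls_per_plate),
         n_plates = as.integer(n_plates),
         seed = as.integer(seed)),
    class = "cohort_params")
}

# log-normal with a given median and coefficient of variation
rlnorm_median_cv <- function(n, median, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

# one morphant-behavior draw per fish: non-mover with probability p0, else a
# WT draw scaled down by the mover reduction
draw_mo <- function(n, params) {
  zero <- rbinom(n, 1, params$mo_zero_fraction) == 1
  base <- rlnorm_median_cv(n, params$wt_distance_median_m,
                           params$wt_distance_cv)
  ifelse(zero, 0, base * (1 - params$mo_mover_reduction))
}

# well addresses for n_drugs treated wells: columns 2-11, rows A-H per plate
drug_addresses <- function(n_drugs, n_plates) {
  slots <- expand.grid(row = LETTERS[1:8], column = 2:11,
                       plate = seq_len(n_plates),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  slots <- slots[order(slots$plate, slots$column, slots$row), ]
  slots[seq_len(n_drugs), c("plate", "row", "column")]
}

#' Simulate a primary behavioral screen
#'
#' Generates a full [screen_table()] under the stated cohort model. Each
#' library plate is read as `replicate_count` reading plates (one larva per
#' well, same plate design), so a drug's replicates sit at the same well
#' position on consecutive reading plates, each carrying its own control
#' columns: WT controls in column 1 and MO controls in column 12. Each
#' treated fish dies with its drug's `toxicity_prob` (distance 0), otherwise
#' travels `(1 - e) * MO_draw + e * WT_draw` for rescue strength `e`. All
#' draws come from RNG streams keyed off `(seed, stage)`, so the output is a
#' pure function of the parameters and adding drugs does not perturb the
#' control draws.
#'
#' @param params a [cohort_params()] list.
#' @param stage_prefix internal stream label prefix (the rescreen uses an
#'   independent prefix).
#' @return a validated [screen_table()].
#' @export
#' @examples
#' tab <- simulate_screen(cohort_params(n_drugs = 4, seed = 7))
#' tab
simulate_screen <- function(params, stage_prefix = "screen") {
  stopifnot(inherits(params, "cohort_params"))
  k <- params$replicate_count
  n_reading <- params$n_plates * k
  nc <- params$n_controls_per_plate
  seed <- params$seed

  control_rows <- function(group, column, distances) {
    data.frame(
      plate = rep(seq_len(n_reading), each = nc),
      row = rep(LETTERS[seq_len(nc)], times = n_reading),
      column = column,
      fish_index = 1L,
      group = group, drug_id = NA_character_,
      alive = TRUE, distance_m = distances,
      stringsAsFactors = FALSE)
  }
  wt_dist <- with_stream(seed, paste0(stage_prefix, "-wt-controls"),
    rlnorm_median_cv(n_reading * nc, params$wt_distance_median_m,
                     params$wt_distance_cv))
  mo_dist <- with_stream(seed, paste0(stage_prefix, "-mo-controls"),
    draw_mo(n_reading * nc, params))
  obs <- rbind(control_rows("WT_CONTROL", 1L, wt_dist),
               control_rows("MO_CONTROL", 12L, mo_dist))

  if (params$n_drugs > 0) {
    addr <- drug_addresses(params$n_drugs, params$n_plates)
    ids <- sprintf("D%04d", seq_len(params$n_drugs))
    n_fish <- params$n_drugs * k
    e <- rep(params$rescue_strength, each = k)
    ptox <- rep(params$toxicity_prob, each = k)
    dead <- with_stream(seed, paste0(stage_prefix, "-toxicity"),
                        rbinom(n_fish, 1, ptox) == 1)
    wt_draw <- with_stream(seed, paste0(stage_prefix, "-treated-wt"),
      rlnorm_median_cv(n_fish, params$wt_distance_median_m,
                       params$wt_distance_cv))
    mo_draw <- with_stream(seed, paste0(stage_prefix, "-treated-mo"),
                           draw_mo(n_fish, params))
    dist <- (1 - e) * mo_draw + e * wt_draw
    dist[dead] <- 0
    treated <- data.frame(
      # replicate r of a library-plate-L drug sits on reading plate
      # (L - 1) * k + r
      plate = rep((addr$plate - 1L) * k, each = k) + seq_len(k),
      row = rep(addr$row, each = k),
      column = rep(addr$column, each = k),
      fish_index = rep(seq_len(k), times = params$n_drugs),
      group = "TREATED",
      drug_id = rep(ids, each = k),
      alive = !dead, distance_m = dist,
      stringsAsFactors = FALSE)
    obs <- rbind(obs, treated)
    drugs <- data.frame(drug_id = ids,
                        rescue_strength = params$rescue_strength,
                        toxicity_prob = params$toxicity_prob,
                        stringsAsFactors = FALSE)
  } else {
    drugs <- data.frame(drug_id = character(0),
                        rescue_strength = numeric(0),
                        toxicity_prob = numeric(0))
  }
  screen_table(obs, drugs, replicate_count = params$replicate_count)
}

#' Simulate a rescreen of selected hits
#'
#' Same generative model as [simulate_screen()] but restricted to `hit_ids`
#' and drawn from an independent seed stream, emulating retesting the
#' primary hits on a second disease model.
#'
#' @param params the [cohort_params()] of the original cohort.
#' @param hit_ids drug ids to retest; must be a subset of the cohort's ids.
#' @return a [screen_table()] containing only the hit drugs (plus controls).
#' @export
simulate_rescreen <- function(params, hit_ids) {
  stopifnot(inherits(params, "cohort_params"))
  ids <- sprintf("D%04d", seq_len(params$n_drugs))
  unknown <- setdiff(hit_ids, ids)
  if (length(unknown) > 0) {
    stage_error("synthetic_data", paste0(
      "unknown hit id(s): ", paste(unknown, collapse = ", ")))
  }
  keep <- match(hit_ids, ids)
  sub <- cohort_params(
    n_drugs = length(hit_ids),
    wt_distance_median_m = params$wt_distance_median_m,
    wt_distance_cv = params$wt_distance_cv,
    mo_zero_fraction = params$mo_zero_fraction,
    mo_mover_reduction = params$mo_mover_reduction,
    rescue_strength = params$rescue_strength[keep],
    toxicity_prob = params$toxicity_prob[keep],
    replicate_count = params$replicate_count,
    n_controls_per_plate = params$n_controls_per_plate,
    seed = params$seed)
  tab <- simulate_screen(sub, stage_prefix = "rescreen")
  # keep the original drug identities
  old <- sprintf("D%04d", seq_along(hit_ids))
  map <- setNames(hit_ids, old)
  tr <- tab$observations$group == "TREATED"
  tab$observations$drug_id[tr] <- map[tab$observations$drug_id[tr]]
  tab$drugs$drug_id <- map[tab$drugs$drug_id]
  screen_table(tab$observations, tab$drugs, params$replicate_count)
}
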