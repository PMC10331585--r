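#' @title NMJ image quantification
#' @name nmj_imaging
#' @description
#' Re-implementation of the high-content quantification stages as the
#' simplest operators satisfying the described behavior: body detection is a
#' global two-class threshold plus largest connected component with hole
#' filling; the analysis region is the body eroded by 7 px; AChR clusters
#' are thresholded connected components with an area filter; the axonal
#' region is the thresholded axon channel; co-localization is a mask
#' intersection fraction; the dorsal spinal cord is extracted by 20 px
#' median smoothing plus a density threshold; axons are individualized by
#' skeletonizing the cord-subtracted axon region and cutting the skeleton at
#' branch points, with geodesic lengths using the \eqn{\sqrt 2} diagonal
#' rule. These are re-implementations of the behavior, not emulations of any
#' proprietary analysis module.
NULL

#' Otsu two-class threshold
#'
#' Maximizes between-class variance over a 256-bin histogram of the values.
#'
#' @param values numeric vector (e.g. pixel intensities).
#' @return the threshold value; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) {
    stage_error("nmj_imaging", "no values to threshold")
  }
  lo <- min(values); hi <- max(values)
  if (lo == hi) return(lo)
  nbins <- 256L
  b <- pmin(floor((values - lo) / (hi - lo) * nbins) + 1L, nbins)
  h <- tabulate(b, nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  lo + k / nbins * (hi - lo)
}

label_components <- function(mask, connectivity = 8L) {
  .label_components(mask, as.integer(connectivity))
}

largest_component <- function(mask, connectivity = 8L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# fill enclosed background regions: background components not touching the
# image border are holes
fill_holes <- function(mask) {
  bg <- !mask
  lab <- label_components(bg, 4L)
  h <- nrow(mask); w <- ncol(mask)
  border <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  border <- border[border > 0L]
  mask | (bg & !(lab %in% border))
}

#' Detect the embryo body region
#'
#' Thresholds the channel (automatic two-class threshold by default, or a
#' fixed value), keeps the largest connected component and fills holes. The
#' automatic threshold works on log intensities so that a long bright tail
#' (receptor clusters, cord) cannot pull the body/background split upward.
#'
#' @param channel intensity matrix.
#' @param threshold `"otsu"` (two-class threshold of log intensities) or a
#'   numeric intensity threshold.
#' @return logical body mask.
#' @export
find_body_region <- function(channel, threshold = "otsu") {
  channel <- as.matrix(channel)
  thr <- if (identical(threshold, "otsu")) {
    expm1(otsu_threshold(log1p(channel)))
  } else {
    as.numeric(threshold)
  }
  fg <- channel > thr
  if (!any(fg)) {
    stage_error("nmj_imaging", "no foreground pixel above the threshold")
  }
  fill_holes(largest_component(fg))
}

#' Erode a mask by a fixed margin
#'
#' Morphological erosion by a disk of radius `margin_px` (default), or a
#' square of half-width `margin_px`. This restricts analysis to the interior
#' of a detected region. `margin_px = 0` is the identity.
#'
#' @param mask logical matrix.
#' @param margin_px non-negative integer margin.
#' @param shape `"disk"` or `"square"` structuring element.
#' @return eroded logical mask (with a warning when it annihilates).
#' @export
shrink_mask <- function(mask, margin_px = 7, shape = c("disk", "square")) {
  shape <- match.arg(shape)
  mask <- as.matrix(mask)
  if (margin_px < 0) {
    stage_error("nmj_imaging", "margin_px must be non-negative")
  }
  if (margin_px == 0) return(mask)
  out <- .erode_mask(mask, as.integer(margin_px), shape == "disk")
  if (!any(out)) {
    warning("erosion annihilated the mask", call. = FALSE)
  }
  out
}

#' Detect AChR cluster spots
#'
#' Thresholds the AChR channel within the region of interest, labels
#' connected components, and keeps components whose area lies in
#' `[min_area_px, max_area_px]`. With `split = "local_maxima"`, components
#' holding several intensity peaks (3x3-neighborhood local maxima, greedily
#' suppressed within `split_min_sep_px`) are counted once per peak, with the
#' component's area shared equally among its peaks. Zero spots is a valid
#' result.
#'
#' @param achr_channel AChR intensity matrix.
#' @param roi_mask logical region of interest.
#' @param threshold `"otsu"` (within the ROI) or a numeric value.
#' @param min_area_px,max_area_px component area filter (px^2).
#' @param split `"none"` (connected components, default) or
#'   `"local_maxima"`.
#' @param split_min_sep_px minimum peak separation for splitting.
#' @return a `spot_set`: list with `spots` (data.frame row, col, area_px2,
#'   mean_intensity) and `mask` (logical union of retained components).
#' @export
detect_spots <- function(achr_channel, roi_mask, threshold = "otsu",
                         min_area_px = 4, max_area_px = 400,
                         split = c("none", "local_maxima"),
                         split_min_sep_px = 4) {
  split <- match.arg(split)
  achr_channel <- as.matrix(achr_channel)
  roi_mask <- as.matrix(roi_mask)
  if (!any(roi_mask)) {
    return(structure(list(
      spots = data.frame(row = numeric(0), col = numeric(0),
                         area_px2 = numeric(0), mean_intensity = numeric(0)),
      mask = roi_mask & FALSE), class = "spot_set"))
  }
  thr <- if (identical(threshold, "otsu")) otsu_threshold(achr_channel[roi_mask])
         else as.numeric(threshold)
  fg <- achr_channel > thr & roi_mask
  lab <- label_components(fg, 8L)
  n <- max(lab)
  rows <- list()
  keep_mask <- fg & FALSE
  if (n > 0) {
    areas <- tabulate(lab[lab > 0L], n)
    for (k in seq_len(n)) {
      if (areas[k] < min_area_px || areas[k] > max_area_px) next
      idx <- which(lab == k, arr.ind = TRUE)
      keep_mask[lab == k] <- TRUE
      vals <- achr_channel[lab == k]
      peaks <- if (split == "local_maxima") {
        component_peaks(achr_channel, idx, split_min_sep_px)
      } else {
        matrix(c(mean(idx[, 1]), mean(idx[, 2])), 1, 2)
      }
      np <- nrow(peaks)
      rows[[length(rows) + 1L]] <- data.frame(
        row = peaks[, 1], col = peaks[, 2],
        area_px2 = areas[k] / np, mean_intensity = mean(vals))
    }
  }
  spots <- if (length(rows)) do.call(rbind, rows) else
    data.frame(row = numeric(0), col = numeric(0), area_px2 = numeric(0),
               mean_intensity = numeric(0))
  rownames(spots) <- NULL
  structure(list(spots = spots, mask = keep_mask), class = "spot_set")
}

# local maxima of a component: pixels >= all 8 neighbors, greedily
# suppressed (highest first) within min_sep; falls back to the centroid
component_peaks <- function(channel, idx, min_sep) {
  h <- nrow(channel); w <- ncol(channel)
  is_max <- vapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]
    v <- channel[i, j]
    ni <- max(1, i - 1):min(h, i + 1)
    nj <- max(1, j - 1):min(w, j + 1)
    v >= max(channel[ni, nj])
  }, logical(1))
  cand <- idx[is_max, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(matrix(c(mean(idx[, 1]), mean(idx[, 2])), 1, 2))
  }
  vals <- channel[cand]
  cand <- cand[order(-vals), , drop = FALSE]
  kept <- cand[1, , drop = FALSE]
  for (r in seq_len(nrow(cand))[-1]) {
    d <- sqrt((kept[, 1] - cand[r, 1])^2 + (kept[, 2] - cand[r, 2])^2)
    if (all(d >= min_sep)) kept <- rbind(kept, cand[r, , drop = FALSE])
  }
  kept
}

#' Segment the axonal region and measure its area
#'
#' Thresholds the axon channel within the ROI (this region contains both the
#' spinal cord band and the descending axons).
#'
#' @param axon_channel axon-marker intensity matrix.
#' @param roi_mask logical region of interest.
#' @param threshold `"otsu"` (within the ROI) or numeric.
#' @param pixel_size_um physical pixel size.
#' @return list with `mask`, `area_px2` and `area_um2`.
#' @export
axon_area <- function(axon_channel, roi_mask, threshold = "otsu",
                      pixel_size_um = 1.0) {
  axon_channel <- as.matrix(axon_channel)
  roi_mask <- as.matrix(roi_mask)
  if (!any(roi_mask)) {
    stage_error("nmj_imaging", "empty ROI for axon-area segmentation")
  }
  vals <- axon_channel[roi_mask]
  if (min(vals) == max(vals)) {
    mask <- roi_mask & FALSE
  } else {
    thr <- if (identical(threshold, "otsu")) otsu_threshold(vals)
           else as.numeric(threshold)
    mask <- axon_channel > thr & roi_mask
  }
  a <- sum(mask)
  list(mask = mask, area_px2 = a, area_um2 = a * pixel_size_um^2)
}

#' Co-localization of AChR clusters with the axonal region
#'
#' Percentage of spot-mask pixels inside the analysis ROI that also fall on
#' the axonal-region mask: `100 * |spots & axons & roi| / |spots & roi|`.
#' Returns 0 when the ROI contains no spot pixels.
#'
#' @param spotset a `spot_set` from [detect_spots()] or a logical spot mask.
#' @param axon_mask logical axonal-region mask.
#' @param analysis_roi logical ROI (defaults to everything).
#' @return overlap percentage in `[0, 100]`.
#' @export
overlap_percent <- function(spotset, axon_mask,
                            analysis_roi = NULL) {
  spot_mask <- if (inherits(spotset, "spot_set")) spotset$mask
               else as.matrix(spotset)
  axon_mask <- as.matrix(axon_mask)
  stopifnot(identical(dim(spot_mask), dim(axon_mask)))
  if (is.null(analysis_roi)) {
    analysis_roi <- matrix(TRUE, nrow(spot_mask), ncol(spot_mask))
  }
  denom <- sum(spot_mask & analysis_roi)
  if (denom == 0) return(0)
  100 * sum(spot_mask & axon_mask & analysis_roi) / denom
}

#' Extract the dorsal spinal cord by median smoothing
#'
#' Median-smooths the axon channel with a window of radius
#' `median_radius_px` (radius 0 is the identity), thresholds the smoothed
#' image at the `density_quantile` of its values within the body, and keeps
#' the largest component: the densest staining region, i.e. the cord band.
#' Thin structures such as individual axons are erased by the smoothing and
#' do not survive.
#'
#' @param axon_channel axon-marker intensity matrix.
#' @param body_mask logical body mask.
#' @param median_radius_px smoothing radius (default 20).
#' @param density_quantile `"otsu"` (default: two-class threshold of the
#'   smoothed intensity within the body, which lands in the gap between the
#'   diffuse trunk staining and the dense cord band) or a numeric quantile
#'   of the smoothed within-body intensity.
#' @return list with `cord_mask` (the thresholded densest region),
#'   `band_mask` (the full dorsal band: every body pixel in the cord's row
#'   range, which is what gets subtracted before axon individualization --
#'   the smoothed cord loses a sliver at the body edges, and those slivers
#'   must not masquerade as axons) and `smoothed` (the filtered channel).
#' @export
extract_cord <- function(axon_channel, body_mask, median_radius_px = 20,
                         density_quantile = "otsu") {
  axon_channel <- as.matrix(axon_channel)
  body_mask <- as.matrix(body_mask)
  if (!any(body_mask)) {
    stage_error("nmj_imaging", "empty body mask for cord extraction")
  }
  img <- matrix(as.integer(pmin(pmax(round(axon_channel), 0), 65535)),
                nrow(axon_channel), ncol(axon_channel))
  sm <- .median_filter_int(img, as.integer(median_radius_px))
  thr <- if (identical(density_quantile, "otsu")) {
    otsu_threshold(sm[body_mask])
  } else {
    quantile(sm[body_mask], density_quantile, names = FALSE)
  }
  cand <- sm >= thr & body_mask
  cord <- if (any(cand)) largest_component(cand) else cand
  band <- cord
  rows <- which(rowSums(cord) > 0)
  if (length(rows) > 0) {
    band <- body_mask
    band[-(rows[1]:rows[length(rows)]), ] <- FALSE
  }
  list(cord_mask = cord, band_mask = band, smoothed = sm)
}

# 8-neighbor count for every pixel of a logical matrix
neighbor_counts <- function(skel) {
  h <- nrow(skel); w <- ncol(skel)
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- skel
  ncount <- matrix(0L, h, w)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ncount <- ncount + pad[2:(h + 1) + di, 2:(w + 1) + dj]
  }
  ncount
}

# crossing number: 0->1 transitions around the 8-neighborhood in circular
# order. 1 = endpoint, 2 = path pixel, >2 = true branch point (a raw
# neighbor count misclassifies diagonal staircase steps as branches)
crossing_numbers <- function(skel) {
  h <- nrow(skel); w <- ncol(skel)
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- skel
  sh <- function(di, dj) pad[2:(h + 1) + di, 2:(w + 1) + dj]
  # clockwise from north
  ring <- list(sh(-1, 0), sh(-1, 1), sh(0, 1), sh(1, 1),
               sh(1, 0), sh(1, -1), sh(0, -1), sh(-1, -1))
  cn <- matrix(0L, h, w)
  for (k in 1:8) {
    nxt <- ring[[k %% 8 + 1]]
    cn <- cn + (ring[[k]] == 0L & nxt == 1L)
  }
  cn
}

# iteratively remove endpoint spurs shorter than prune_px: walk from each
# endpoint along the path; if a junction is reached within prune_px pixels,
# delete the walked pixels (boutons and thinning artifacts produce such
# spurs, which would otherwise cut an axon in two at the junction)
prune_spurs <- function(skel, prune_px) {
  if (prune_px <= 0) return(skel)
  h <- nrow(skel); w <- ncol(skel)
  neighbors_of <- function(p, prev) {
    ci <- (p - 1) %% h + 1; cj <- (p - 1) %/% h + 1
    ni <- max(1, ci - 1):min(h, ci + 1)
    nj <- max(1, cj - 1):min(w, cj + 1)
    nb <- as.integer(outer(ni, (nj - 1) * h, `+`))
    nb <- nb[skel[nb]]
    setdiff(nb, c(p, prev))
  }
  adjacent <- function(a, b) {
    ai <- (a - 1) %% h; aj <- (a - 1) %/% h
    bi <- (b - 1) %% h; bj <- (b - 1) %/% h
    abs(ai - bi) <= 1 && abs(aj - bj) <= 1
  }
  repeat {
    cn <- crossing_numbers(skel)
    endpoints <- which(skel & cn == 1L)
    removed_any <- FALSE
    for (p in endpoints) {
      if (!skel[p]) next
      path <- integer(0)
      cur <- p
      prev <- NA_integer_
      hit_junction <- FALSE
      while (length(path) < prune_px) {
        if (cur != p && cn[cur] > 2L) {
          hit_junction <- TRUE  # reached a branch point; keep it
          break
        }
        path <- c(path, cur)
        nb <- neighbors_of(cur, c(prev, path))
        if (length(nb) == 0) break          # isolated segment, keep
        if (length(nb) == 2 && adjacent(nb[1], nb[2])) {
          # diagonal staircase pair: continue through the nearer pixel
          nb <- nb[order(abs((nb - 1) %% h - (cur - 1) %% h) +
                           abs((nb - 1) %/% h - (cur - 1) %/% h))]
        } else if (length(nb) > 1) {
          hit_junction <- TRUE              # adjacent to a branch cluster
          break
        }
        prev <- cur
        cur <- nb[1]
      }
      if (hit_junction && length(path) < prune_px) {
        skel[path] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  skel
}

# skeleton length with the sqrt(2) diagonal rule: orthogonal edges count 1,
# diagonal edges count sqrt(2) unless short-circuited by an orthogonal path
skeleton_length_px <- function(skel) {
  # crop to the occupied bounding box; callers pass full-frame masks
  rows <- which(rowSums(skel) > 0)
  cols <- which(colSums(skel) > 0)
  if (length(rows) == 0) return(0)
  skel <- skel[rows[1]:rows[length(rows)], cols[1]:cols[length(cols)],
               drop = FALSE]
  h <- nrow(skel); w <- ncol(skel)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- skel
  p <- pad[2:(h + 1), 2:(w + 1)]
  e <- pad[2:(h + 1), 3:(w + 2)]
  s <- pad[3:(h + 2), 2:(w + 1)]
  se <- pad[3:(h + 2), 3:(w + 2)]
  sw <- pad[3:(h + 2), 1:w]
  west <- pad[2:(h + 1), 1:w]
  n_ortho <- sum(p & e) + sum(p & s)
  n_diag <- sum(p & se & !(e | s)) + sum(p & sw & !(west | s))
  n_ortho + sqrt(2) * n_diag
}

#' Individualize axons and measure their lengths
#'
#' Skeletonizes the axon-only mask, cuts the skeleton at branch points
#' (pixels with more than two 8-connected skeleton neighbors), and treats
#' each surviving branch of geodesic length at least `min_length_um` as one
#' axon. Lengths use 8-connectivity with \eqn{\sqrt 2} diagonal steps; each
#' axon's mean width is its mask component's area divided by the skeleton
#' length inside that component.
#'
#' Before cutting, endpoint spurs shorter than `prune_px` (thinning
#' artifacts and synaptic boutons) are pruned so they do not sever the main
#' axon path.
#'
#' @param axon_only_mask logical mask of axons with the cord removed.
#' @param pixel_size_um physical pixel size.
#' @param min_length_um minimum retained branch length (default 10).
#' @param prune_px maximum spur length removed before branch cutting
#'   (default 9 px).
#' @return an `axon_measure`: list with `per_axon` (data.frame axon_id,
#'   length_um, mean_width_px), `count`, `mean_length_um` (`NA` when empty)
#'   and `skeleton`.
#' @export
individualize_axons <- function(axon_only_mask, pixel_size_um = 1.0,
                                min_length_um = 10, prune_px = 9) {
  mask <- as.matrix(axon_only_mask)
  empty <- structure(
    list(per_axon = data.frame(axon_id = integer(0), length_um = numeric(0),
                               mean_width_px = numeric(0)),
         count = 0L, mean_length_um = NA_real_,
         skeleton = mask & FALSE),
    class = "axon_measure")
  if (!any(mask)) return(empty)
  skel <- prune_spurs(.thin_mask(mask), prune_px)
  if (!any(skel)) return(empty)

  branches <- skel & crossing_numbers(skel) <= 2L
  lab <- label_components(branches, 8L)
  n <- max(lab)
  if (n == 0L) return(empty)

  mask_lab <- label_components(mask, 8L)
  mask_areas <- tabulate(mask_lab[mask_lab > 0L])
  # total skeleton length per mask component, for width estimation
  skel_len_by_comp <- vapply(seq_along(mask_areas), function(k) {
    skeleton_length_px(skel & mask_lab == k)
  }, numeric(1))

  rows <- list()
  for (k in seq_len(n)) {
    piece <- lab == k
    len_px <- skeleton_length_px(piece)
    len_um <- len_px * pixel_size_um
    if (len_um < min_length_um) next
    comp <- mask_lab[which(piece)[1]]
    width <- if (skel_len_by_comp[comp] > 0) {
      mask_areas[comp] / skel_len_by_comp[comp]
    } else {
      NA_real_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      axon_id = k, length_um = len_um, mean_width_px = width)
  }
  if (length(rows) == 0) return(empty)
  per_axon <- do.call(rbind, rows)
  rownames(per_axon) <- NULL
  structure(list(per_axon = per_axon, count = nrow(per_axon),
                 mean_length_um = mean(per_axon$length_um),
                 skeleton = skel),
            class = "axon_measure")
}

#' Fraction of short axons
#'
#' Percentage of axons shorter than `cutoff_um` (default 70), the standard
#' short-axon disease readout.
#'
#' @param lengths_um axon lengths in micrometers.
#' @param cutoff_um strict upper bound defining "short".
#' @return percentage in `[0, 100]`, or `NA` for an empty list.
#' @export
#' @examples
#' short_axon_fraction(c(60, 80, 90, 50))  # 50
short_axon_fraction <- function(lengths_um, cutoff_um = 70) {
  stopifnot(all(lengths_um >= 0))
  if (length(lengths_um) == 0) return(NA_real_)
  100 * sum(lengths_um < cutoff_um) / length(lengths_um)
}

#' Background-subtracted mean intensity over an ROI
#'
#' Mean of `max(intensity - background, 0)` over the ROI. By default the
#' background is the median intensity outside the body mask.
#'
#' @param channel intensity matrix.
#' @param roi logical ROI mask (must be nonempty).
#' @param background numeric background level, or `NULL` to estimate it.
#' @param body_mask body mask used for the default background estimate.
#' @return mean background-subtracted intensity.
#' @export
roi_mean_intensity <- function(channel, roi, background = NULL,
                               body_mask = NULL) {
  channel <- as.matrix(channel)
  roi <- as.matrix(roi)
  if (!any(roi)) {
    stage_error("nmj_imaging", "empty ROI for intensity measurement")
  }
  if (!is.null(body_mask) && !any(roi & body_mask)) {
    stage_error("nmj_imaging", "ROI lies entirely outside the body")
  }
  if (is.null(background)) {
    if (is.null(body_mask) || !any(!body_mask)) {
      stage_error("nmj_imaging",
                  "background estimation needs a body mask with exterior")
    }
    background <- median(channel[!body_mask])
  }
  mean(pmax(channel[roi] - background, 0))
}

#' Quantification configuration
#'
#' All tunable parameters of [quantify_embryo()] with their defaults.
#'
#' @param body_threshold body detection threshold (`"otsu"` or numeric).
#' @param shrink_margin_px ROI erosion margin (default 7 px).
#' @param spot_threshold,spot_min_area_px,spot_max_area_px spot detection
#'   parameters, see [detect_spots()].
#' @param spot_split,spot_split_min_sep_px merged-cluster splitting rule,
#'   see [detect_spots()].
#' @param axon_threshold axonal-region threshold.
#' @param median_radius_px,density_quantile cord extraction parameters.
#' @param min_axon_length_um minimum individualized axon length.
#' @param short_axon_cutoff_um short-axon cutoff (default 70 um).
#' @param overlap_roi_fraction central fraction of the body (along the
#'   anterior-posterior axis) used for co-localization (default 0.5).
#' @return a `quantify_config` list.
#' @export
quantify_config <- function(body_threshold = "otsu", shrink_margin_px = 7,
                            spot_threshold = "otsu", spot_min_area_px = 4,
                            spot_max_area_px = 400, spot_split = "none",
                            spot_split_min_sep_px = 4,
                            axon_threshold = "otsu",
                            median_radius_px = 20,
                            density_quantile = "otsu",
                            min_axon_length_um = 10,
                            short_axon_cutoff_um = 70,
                            overlap_roi_fraction = 0.5) {
  structure(as.list(environment()), class = "quantify_config")
}

# central `fraction` of the body's column extent
mid_body_roi <- function(body_mask, fraction) {
  cols <- which(colSums(body_mask) > 0)
  c0 <- min(cols); c1 <- max(cols)
  center <- (c0 + c1) / 2
  half <- (c1 - c0 + 1) * fraction / 2
  roi <- body_mask & FALSE
  jr <- max(c0, ceiling(center - half)):min(c1, floor(center + half))
  roi[, jr] <- body_mask[, jr]
  roi
}

#' Quantify one embryo image
#'
#' Orchestrates the full quantification: body detection on the AChR channel
#' (the stain fills the trunk), 7 px ROI erosion, spot detection, axonal
#' region and co-localization in the mid-body ROI, cord extraction by 20 px
#' median smoothing, axon individualization on the cord-subtracted region,
#' and the summary metrics. Deterministic for a fixed configuration.
#'
#' @param image an [nmj_image()].
#' @param config a [quantify_config()].
#' @return a one-row `cellular_metrics` data.frame: embryo_id, group,
#'   drug_id, n_achr_clusters, overlap_percent, mean_axon_length_um,
#'   short_axon_percent, axon_count, mean_spot_area_px2,
#'   achr_mean_intensity, axon_mean_intensity, axon_area_um2,
#'   body_length_um, body_to_axon_ratio.
#' @export
quantify_embryo <- function(image, config = quantify_config()) {
  stopifnot(inherits(image, "nmj_image"))
  px <- image$pixel_size_um

  body <- find_body_region(image$achr_channel, config$body_threshold)
  roi <- shrink_mask(body, config$shrink_margin_px)
  spots <- detect_spots(image$achr_channel, roi, config$spot_threshold,
                        config$spot_min_area_px, config$spot_max_area_px,
                        config$spot_split, config$spot_split_min_sep_px)
  ax <- axon_area(image$axon_channel, roi, config$axon_threshold, px)
  mid <- mid_body_roi(body, config$overlap_roi_fraction)
  ovl <- overlap_percent(spots, ax$mask, mid)
  cord <- extract_cord(image$axon_channel, body, config$median_radius_px,
                       config$density_quantile)
  axon_only <- ax$mask & !cord$band_mask
  axons <- individualize_axons(axon_only, px, config$min_axon_length_um)

  cols <- which(colSums(body) > 0)
  body_length_um <- (max(cols) - min(cols) + 1) * px
  achr_int <- if (any(spots$mask)) {
    roi_mean_intensity(image$achr_channel, spots$mask, body_mask = body)
  } else {
    NA_real_
  }
  axon_int <- if (any(ax$mask)) {
    roi_mean_intensity(image$axon_channel, ax$mask, body_mask = body)
  } else {
    NA_real_
  }
  out <- data.frame(
    embryo_id = image$embryo_id,
    group = if (is.null(image$group)) NA_character_ else image$group,
    drug_id = if (is.null(image$drug_id)) NA_character_ else image$drug_id,
    n_achr_clusters = nrow(spots$spots),
    overlap_percent = ovl,
    mean_axon_length_um = axons$mean_length_um,
    short_axon_percent = short_axon_fraction(
      axons$per_axon$length_um, config$short_axon_cutoff_um),
    axon_count = axons$count,
    mean_spot_area_px2 = if (nrow(spots$spots) > 0)
      mean(spots$spots$area_px2) else NA_real_,
    achr_mean_intensity = achr_int,
    axon_mean_intensity = axon_int,
    axon_area_um2 = ax$area_um2,
    body_length_um = body_length_um,
    body_to_axon_ratio = if (is.na(axons$mean_length_um)) NA_real_
      else body_length_um / axons$mean_length_um,
    stringsAsFactors = FALSE)
  class(out) <- c("cellular_metrics", class(out))
  out
}

#' Quantify a batch of images
#'
#' @param images list of [nmj_image()] objects.
#' @param config a [quantify_config()].
#' @return row-bound `cellular_metrics` data.frame, order-stable.
#' @export
quantify_batch <- function(images, config = quantify_config()) {
  out <- do.call(rbind, lapply(images, quantify_embryo, config = config))
  rownames(out) <- NULL
  out
}
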