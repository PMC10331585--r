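#' @title Synthetic NMJ micrographs with ground truth
#' @name synthetic_image
#' @description
#' Renders two-channel micrographs of a laterally mounted embryo trunk: the
#' axon channel holds an elliptical body at low intensity, a bright dorsal
#' spinal-cord band, and motor axons descending ventrally from the cord as
#' anti-aliased polylines; the AChR channel holds the body plus Gaussian
#' receptor-cluster spots, a controllable fraction of which sit on the axon
#' mask. The generating geometry (polylines with true arc length, spot list,
#' cord band) is returned alongside the image so quantification can be
#' tested against ground truth.
NULL

#' Two-channel NMJ image container
#'
#' @param axon_channel,achr_channel numeric matrices of equal shape with
#'   non-negative intensities (axon marker and AChR marker channels).
#' @param pixel_size_um physical pixel size in micrometers.
#' @param embryo_id identifier for the embryo.
#' @param group optional group label (e.g. `WT_CONTROL`).
#' @param drug_id optional treatment drug id.
#' @return an `nmj_image` object.
#' @export
nmj_image <- function(axon_channel, achr_channel, pixel_size_um = 1.0,
                      embryo_id = "embryo", group = NULL, drug_id = NULL) {
  axon_channel <- as.matrix(axon_channel)
  achr_channel <- as.matrix(achr_channel)
  if (!identical(dim(axon_channel), dim(achr_channel))) {
    stage_error("nmj_imaging", "channels must have identical shapes")
  }
  if (any(axon_channel < 0) || any(achr_channel < 0)) {
    stage_error("nmj_imaging", "intensities must be non-negative")
  }
  stopifnot(pixel_size_um > 0)
  structure(list(axon_channel = axon_channel, achr_channel = achr_channel,
                 pixel_size_um = pixel_size_um, embryo_id = embryo_id,
                 group = group, drug_id = drug_id),
            class = "nmj_image")
}

#' @export
print.nmj_image <- function(x, ...) {
  cat(sprintf("nmj_image '%s': %d x %d px at %.2f um/px\n", x$embryo_id,
              nrow(x$axon_channel), ncol(x$axon_channel), x$pixel_size_um))
  invisible(x)
}

#' Ground-truth description of a synthetic NMJ image
#'
#' Low-level container validated against the frame: spots must lie inside
#' the image and axon polylines must originate inside the cord band.
#' Intensity defaults put the signal roughly two orders of magnitude above
#' the read noise, as in well-exposed confocal projections.
#'
#' @param shape `c(height, width)` in pixels.
#' @param pixel_size_um physical pixel size (default 1).
#' @param cord list `(top, thickness)` in px: the dorsal spinal-cord band.
#' @param axons list of axons, each `list(points = n x 2 matrix of (row,
#'   col) vertices, length_um = true arc length)`.
#' @param spots data.frame with columns `row`, `col`, `radius` (px), `peak`
#'   (intensity), `on_axon` (logical).
#' @param on_axon_fraction designed fraction of spots on the axon mask.
#' @param background per-channel baseline `c(axon, achr)`.
#' @param body_base per-channel body intensity `c(axon, achr)`.
#' @param signal `c(cord, axon)` rendering intensities for the axon channel.
#' @param noise_sd per-channel additive Gaussian noise sd `c(axon, achr)`.
#' @param seed integer seed for the rendering noise.
#' @return an `image_truth` object.
#' @export
image_truth <- function(shape = c(220, 400), pixel_size_um = 1.0,
                        cord = list(top = 30, thickness = 44),
                        axons = list(),
                        spots = data.frame(row = numeric(0),
                                           col = numeric(0),
                                           radius = numeric(0),
                                           peak = numeric(0),
                                           on_axon = logical(0)),
                        on_axon_fraction = NA_real_,
                        background = c(axon = 200, achr = 200),
                        body_base = c(axon = 600, achr = 3000),
                        signal = c(cord = 12000, axon = 12000),
                        noise_sd = c(axon = 150, achr = 150),
                        seed = 1) {
  h <- shape[1]; w <- shape[2]
  stopifnot(h >= 32, w >= 32, pixel_size_um > 0,
            cord$top >= 1, cord$thickness >= 1,
            cord$top + cord$thickness - 1 <= h,
            all(noise_sd >= 0))
  if (!is.na(on_axon_fraction)) {
    stopifnot(on_axon_fraction >= 0, on_axon_fraction <= 1)
  }
  spots <- as.data.frame(spots)
  if (nrow(spots) > 0) {
    inside <- spots$row - spots$radius >= 1 & spots$col - spots$radius >= 1 &
      spots$row + spots$radius <= h & spots$col + spots$radius <= w
    if (!all(inside)) {
      stage_error("synthetic_data", "spot geometry outside the frame")
    }
  }
  cord_bottom <- cord$top + cord$thickness - 1
  for (ax in axons) {
    pts <- ax$points
    if (any(pts[, 1] < 1) || any(pts[, 1] > h) ||
        any(pts[, 2] < 1) || any(pts[, 2] > w)) {
      stage_error("synthetic_data", "axon geometry outside the frame")
    }
    if (pts[1, 1] < cord$top || pts[1, 1] > cord_bottom) {
      stage_error("synthetic_data",
                  "axon polylines must originate in the cord band")
    }
  }
  structure(
    list(shape = c(h, w), pixel_size_um = pixel_size_um, cord = cord,
         axons = axons, spots = spots, on_axon_fraction = on_axon_fraction,
         background = background, body_base = body_base, signal = signal,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "image_truth")
}

# elliptical trunk mask; the body fills most of the frame
body_mask_for <- function(shape, margin = c(15, 10)) {
  h <- shape[1]; w <- shape[2]
  ci <- (h + 1) / 2; cj <- (w + 1) / 2
  a <- h / 2 - margin[1]; b <- w / 2 - margin[2]
  ii <- matrix(seq_len(h), h, w)
  jj <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((ii - ci) / a)^2 + ((jj - cj) / b)^2 <= 1
}

# polyline of total arc length n_steps * step descending from (row0, col0)
wobbly_axon <- function(row0, col0, length_px, step = 4, wobble_sd = 0.02) {
  n_steps <- max(1L, round(length_px / step))
  theta <- cumsum(rnorm(n_steps, 0, wobble_sd))
  theta <- pmin(pmax(theta, -0.3), 0.3)
  rows <- row0 + cumsum(step * cos(theta))
  cols <- col0 + cumsum(step * sin(theta))
  pts <- cbind(c(row0, rows), c(col0, cols))
  list(points = pts, length_px = n_steps * step)
}

#' Randomized NMJ image truth
#'
#' High-level geometry generator. Axons start at the ventral edge of the
#' cord band at evenly spaced positions across the mid-trunk and descend
#' with a small random wobble; their true arc length is drawn from a normal
#' distribution (floored at 15 um). Spots are placed on randomly chosen axon
#' vertices (on-axon) or at body positions away from the axon mask and cord
#' (off-axon), with centers separated enough for the spots to stay
#' resolvable. Deterministic given `seed`.
#'
#' @param n_axons number of motor axons.
#' @param axon_length_um,axon_length_sd_um mean and sd of true axon length.
#' @param n_spots number of AChR cluster spots.
#' @param on_axon_fraction fraction of spots on the axon mask.
#' @param spot_radius_um range of spot radii in micrometers (uniform draw;
#'   converted to pixels with `pixel_size_um`).
#' @param spot_peak peak spot intensity above the body base.
#' @param noise_sd per-channel noise sd (scalar or length 2).
#' @param shape,pixel_size_um,cord_top,cord_thickness frame geometry
#'   (`cord_top`/`cord_thickness` in pixels).
#' @param seed integer seed.
#' @return an [image_truth()] object.
#' @export
random_image_truth <- function(n_axons = 12, axon_length_um = 110,
                               axon_length_sd_um = 8, n_spots = 40,
                               on_axon_fraction = 0.9,
                               spot_radius_um = c(3, 6),
                               spot_peak = 18000, noise_sd = 150,
                               shape = c(220, 400), pixel_size_um = 1.0,
                               cord_top = 30, cord_thickness = 44,
                               seed = 1) {
  spot_radius_px <- pmax(1.5, spot_radius_um / pixel_size_um)
  stopifnot(n_axons >= 0, n_spots >= 0,
            on_axon_fraction >= 0, on_axon_fraction <= 1)
  h <- shape[1]; w <- shape[2]
  cord_bottom <- cord_top + cord_thickness - 1
  with_stream(seed, "image-geometry", {
    axons <- list()
    if (n_axons > 0) {
      x0 <- if (n_axons == 1) round(0.5 * w) else
        round(seq(0.22 * w, 0.78 * w, length.out = n_axons))
      lengths_px <- pmax(15, rnorm(n_axons, axon_length_um,
                                   axon_length_sd_um)) / pixel_size_um
      # truncate each axon at the body interior (inner ellipse, 12 px
      # margin) so strokes and their terminal clusters stay in the trunk
      ci <- (h + 1) / 2; cj <- (w + 1) / 2
      a_in <- h / 2 - 15 - 12; b_in <- w / 2 - 10 - 12
      max_row <- ci + a_in * sqrt(pmax(0, 1 - ((x0 - cj) / b_in)^2))
      lengths_px <- pmin(lengths_px, max_row - cord_bottom, (h - 6) -
                           cord_bottom)
      axons <- lapply(seq_len(n_axons), function(k) {
        ax <- wobbly_axon(cord_bottom, x0[k], lengths_px[k])
        list(points = ax$points,
             length_um = ax$length_px * pixel_size_um)
      })
    }
    body <- body_mask_for(shape)
    axon_pts <- if (length(axons)) {
      do.call(rbind, lapply(axons, `[[`, "points"))
    } else {
      matrix(numeric(0), 0, 2)
    }
    spots <- place_spots(n_spots, on_axon_fraction, spot_radius_px,
                         spot_peak, axons, axon_pts, body,
                         cord_top, cord_bottom, shape)
    image_truth(shape = shape, pixel_size_um = pixel_size_um,
                cord = list(top = cord_top, thickness = cord_thickness),
                axons = axons, spots = spots,
                on_axon_fraction = on_axon_fraction,
                noise_sd = rep_len(noise_sd, 2), seed = seed)
  })
}

# rejection-sample spot centers: on-axon spots sit on axon vertices below
# the cord, off-axon spots keep clear of axons and cord; all spots keep
# clear of each other and the frame border
place_spots <- function(n_spots, on_axon_fraction, spot_radius_px,
                        spot_peak, axons, axon_pts, body,
                        cord_top, cord_bottom, shape) {
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      radius = numeric(0), peak = numeric(0),
                      on_axon = logical(0))
  if (n_spots == 0) return(empty)
  h <- shape[1]; w <- shape[2]
  n_on <- round(on_axon_fraction * n_spots)
  if (n_on > 0 && length(axons) == 0) {
    stage_error("synthetic_data", "on-axon spots requested but no axons")
  }
  below <- axon_pts[axon_pts[, 1] > cord_bottom + 4, , drop = FALSE]
  placed <- empty
  sep_ok <- function(r, c, rad, margin) {
    if (nrow(placed) == 0) return(TRUE)
    all(sqrt((placed$row - r)^2 + (placed$col - c)^2) >
          placed$radius + rad + margin)
  }
  for (k in seq_len(n_spots)) {
    on <- k <= n_on
    rad <- runif(1, spot_radius_px[1], spot_radius_px[2])
    done <- FALSE
    # relax the center separation when the geometry is crowded (few short
    # axons with many requested clusters); merged clusters are biologically
    # plausible and recorded as-is in the truth
    for (margin in c(4, 1, -2)) {
      for (try in 1:200) {
        if (on) {
          p <- below[sample(nrow(below), 1), ]
          r <- p[1]; c <- p[2]
        } else {
          # off-axon spots live in the myotome region spanned by the axons
          # (so the analysis ROI sees them), clear of the axon strokes
          r <- runif(1, cord_bottom + 12, h - 8)
          c <- runif(1, 0.18 * w, 0.82 * w)
          # keep the whole spot well inside the body so the 7 px ROI
          # erosion cannot clip it
          ci <- (h + 1) / 2; cj <- (w + 1) / 2
          a <- h / 2 - 15 - 10; b <- w / 2 - 10 - 10
          if (((r - ci) / a)^2 + ((c - cj) / b)^2 > 1) next
          if (nrow(axon_pts) > 0 &&
              min(sqrt((axon_pts[, 1] - r)^2 + (axon_pts[, 2] - c)^2)) <
              rad + 4) next
        }
        if (r - rad < 1 || r + rad > h || c - rad < 1 || c + rad > w) next
        if (!sep_ok(r, c, rad, margin)) next
        placed <- rbind(placed, data.frame(
          row = r, col = c, radius = rad, peak = spot_peak, on_axon = on))
        done <- TRUE
        break
      }
      if (done) break
    }
    if (!done) {
      # capacity exhausted (e.g. many clusters on few short axons): place on
      # the geometry anyway; overlapping clusters merge, as real ones do
      if (on) {
        p <- below[sample(nrow(below), 1), ]
        r <- min(max(p[1], rad + 1), h - rad)
        c <- min(max(p[2], rad + 1), w - rad)
      } else {
        r <- (h + 1) / 2; c <- (w + 1) / 2
      }
      placed <- rbind(placed, data.frame(
        row = r, col = c, radius = rad, peak = spot_peak, on_axon = on))
    }
  }
  rownames(placed) <- NULL
  placed
}

# render an anti-aliased polyline of the given half-width into `mat`
# (keeps the running maximum so crossing strokes do not add up)
render_polyline <- function(mat, pts, width = 3, intensity = 12000) {
  half <- width / 2
  h <- nrow(mat); w <- ncol(mat)
  for (s in seq_len(nrow(pts) - 1)) {
    p <- pts[s, ]; q <- pts[s + 1, ]
    i0 <- max(1, floor(min(p[1], q[1]) - half - 1))
    i1 <- min(h, ceiling(max(p[1], q[1]) + half + 1))
    j0 <- max(1, floor(min(p[2], q[2]) - half - 1))
    j1 <- min(w, ceiling(max(p[2], q[2]) + half + 1))
    ii <- matrix(i0:i1, i1 - i0 + 1, j1 - j0 + 1)
    jj <- matrix(j0:j1, i1 - i0 + 1, j1 - j0 + 1, byrow = TRUE)
    v <- q - p
    len2 <- sum(v^2)
    t <- if (len2 == 0) 0 else
      pmin(pmax(((ii - p[1]) * v[1] + (jj - p[2]) * v[2]) / len2, 0), 1)
    d <- sqrt((ii - (p[1] + t * v[1]))^2 + (jj - (p[2] + t * v[2]))^2)
    prof <- pmin(pmax(half + 0.5 - d, 0), 1)
    blk <- mat[i0:i1, j0:j1]
    mat[i0:i1, j0:j1] <- pmax(blk, intensity * prof)
  }
  mat
}

# render an anti-aliased solid disk, keeping the running maximum
render_disk <- function(mat, row, col, radius, intensity) {
  h <- nrow(mat); w <- ncol(mat)
  ext <- ceiling(radius + 1)
  i0 <- max(1, floor(row - ext)); i1 <- min(h, ceiling(row + ext))
  j0 <- max(1, floor(col - ext)); j1 <- min(w, ceiling(col + ext))
  ii <- matrix(i0:i1, i1 - i0 + 1, j1 - j0 + 1)
  jj <- matrix(j0:j1, i1 - i0 + 1, j1 - j0 + 1, byrow = TRUE)
  d <- sqrt((ii - row)^2 + (jj - col)^2)
  prof <- pmin(pmax(radius + 0.5 - d, 0), 1)
  mat[i0:i1, j0:j1] <- pmax(mat[i0:i1, j0:j1], intensity * prof)
  mat
}

# render a Gaussian spot (sigma = radius / 2), additive
render_spot <- function(mat, row, col, radius, peak) {
  h <- nrow(mat); w <- ncol(mat)
  ext <- ceiling(2.5 * radius)
  i0 <- max(1, floor(row - ext)); i1 <- min(h, ceiling(row + ext))
  j0 <- max(1, floor(col - ext)); j1 <- min(w, ceiling(col + ext))
  ii <- matrix(i0:i1, i1 - i0 + 1, j1 - j0 + 1)
  jj <- matrix(j0:j1, i1 - i0 + 1, j1 - j0 + 1, byrow = TRUE)
  s <- radius / 2
  g <- peak * exp(-((ii - row)^2 + (jj - col)^2) / (2 * s^2))
  mat[i0:i1, j0:j1] <- mat[i0:i1, j0:j1] + g
  mat
}

#' Render a synthetic NMJ image from its ground truth
#'
#' Channel 1 (axon marker) gets the body, the cord band and the axon
#' polylines at 3 px stroke width; channel 2 (AChR marker) gets the body and
#' the Gaussian spots. Additive Gaussian noise (clipped at zero) is drawn
#' from the truth's seed, so rendering is bitwise-reproducible.
#'
#' @param truth an [image_truth()] object.
#' @param embryo_id,group,drug_id metadata stamped on the image.
#' @param axon_width_px stroke width of rendered axons (default 3).
#' @return a list with elements `image` (an [nmj_image()]), `truth`, and
#'   `masks` (logical matrices `body`, `cord`, `axon` -- noise-free rendered
#'   axon strokes -- and `spots`) for oracle tests.
#' @export
simulate_nmj_image <- function(truth, embryo_id = "embryo", group = NULL,
                               drug_id = NULL, axon_width_px = 3) {
  stopifnot(inherits(truth, "image_truth"))
  h <- truth$shape[1]; w <- truth$shape[2]
  body <- body_mask_for(truth$shape)
  cord_rows <- truth$cord$top:(truth$cord$top + truth$cord$thickness - 1)
  cord <- matrix(FALSE, h, w)
  cord[cord_rows, ] <- TRUE
  cord <- cord & body

  axon <- matrix(truth$background[["axon"]], h, w)
  axon[body] <- truth$body_base[["axon"]]
  axon[cord] <- truth$signal[["cord"]]
  stroke <- matrix(0, h, w)
  for (ax in truth$axons) {
    stroke <- render_polyline(stroke, ax$points, width = axon_width_px,
                              intensity = truth$signal[["axon"]])
  }
  # presynaptic terminals: on-axon clusters carry an axon-marker bouton
  # covering the cluster footprint, so NMJ sites co-localize fully
  if (nrow(truth$spots) > 0) {
    for (k in which(truth$spots$on_axon)) {
      sp <- truth$spots[k, ]
      stroke <- render_disk(stroke, sp$row, sp$col, sp$radius + 1,
                            truth$signal[["axon"]])
    }
  }
  axon <- pmax(axon, stroke)

  achr <- matrix(truth$background[["achr"]], h, w)
  achr[body] <- truth$body_base[["achr"]]
  spot_mask <- matrix(FALSE, h, w)
  if (nrow(truth$spots) > 0) {
    for (k in seq_len(nrow(truth$spots))) {
      sp <- truth$spots[k, ]
      achr <- render_spot(achr, sp$row, sp$col, sp$radius, sp$peak)
      i0 <- max(1, floor(sp$row - sp$radius))
      i1 <- min(h, ceiling(sp$row + sp$radius))
      j0 <- max(1, floor(sp$col - sp$radius))
      j1 <- min(w, ceiling(sp$col + sp$radius))
      ii <- matrix(i0:i1, i1 - i0 + 1, j1 - j0 + 1)
      jj <- matrix(j0:j1, i1 - i0 + 1, j1 - j0 + 1, byrow = TRUE)
      spot_mask[i0:i1, j0:j1] <- spot_mask[i0:i1, j0:j1] |
        ((ii - sp$row)^2 + (jj - sp$col)^2 <= sp$radius^2)
    }
  }

  if (any(truth$noise_sd > 0)) {
    noise <- with_stream(truth$seed, "image-noise", {
      list(axon = rnorm(h * w, 0, truth$noise_sd[[1]]),
           achr = rnorm(h * w, 0, truth$noise_sd[[2]]))
    })
    axon <- pmax(axon + matrix(noise$axon, h, w), 0)
    achr <- pmax(achr + matrix(noise$achr, h, w), 0)
  }

  list(image = nmj_image(axon, achr, truth$pixel_size_um, embryo_id,
                         group, drug_id),
       truth = truth,
       masks = list(body = body, cord = cord, axon = stroke > 0,
                    spots = spot_mask))
}

#' Phenotype-graded truth parameters
#'
#' Interpolates the image geometry between a morphant-like phenotype
#' (`effect = 0`: few, short axons; sparse, mostly off-axon clusters) and a
#' WT-like phenotype (`effect = 1`: many long axons, dense on-axon
#' clusters), with biological between-embryo variation: the cluster count is
#' Poisson around its phenotype mean, the axon count Poisson (floored at 3),
#' the embryo's mean axon length normal with a 6 um embryo-to-embryo
#' spread, and the on-axon cluster fraction jittered (sd 0.04) so that
#' co-localization never saturates degenerately across a control group.
#' Used by the demo pipeline to derive each drug's cellular
#' phenotype from its behavioral rescue strength.
#'
#' @param effect rescue strength in `[0, 1]`.
#' @param seed integer seed.
#' @param ... overrides forwarded to [random_image_truth()].
#' @return an [image_truth()] object.
#' @export
phenotype_truth <- function(effect, seed = 1, ...) {
  stopifnot(effect >= 0, effect <= 1)
  draws <- with_stream(seed, "phenotype", list(
    n_axons = max(3, rpois(1, 6 + 6 * effect)),
    length_um = max(25, rnorm(1, 55 + 55 * effect, 6)),
    n_spots = max(4, rpois(1, 12 + 28 * effect)),
    on_axon = min(0.97, max(0.03, 0.3 + 0.6 * effect + rnorm(1, 0, 0.04)))))
  random_image_truth(
    n_axons = draws$n_axons,
    axon_length_um = draws$length_um,
    n_spots = draws$n_spots,
    on_axon_fraction = draws$on_axon,
    seed = seed, ...)
}
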