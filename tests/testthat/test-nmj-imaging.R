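# one rendered default image reused across blocks
wt_sim <- simulate_nmj_image(random_image_truth(seed = 3))
wt_img <- wt_sim$image

test_that("body detection finds the trunk and its edge cases", {
  expect_error(find_body_region(matrix(5, 20, 20)), "no foreground")
  body <- find_body_region(wt_img$achr_channel)
  covered <- sum(body & wt_sim$masks$body) / sum(wt_sim$masks$body)
  expect_gte(covered, 0.99)
  # two blobs: the larger is returned
  two <- matrix(0, 40, 40)
  two[5:10, 5:10] <- 100
  two[20:35, 20:35] <- 100
  mask <- find_body_region(two, threshold = 50)
  expect_false(mask[7, 7])
  expect_true(mask[25, 25])
})

test_that("mask erosion matches a brute-force oracle", {
  m <- matrix(FALSE, 40, 40)
  m[11:30, 11:30] <- TRUE
  expect_identical(shrink_mask(m, 0), m)
  sq <- shrink_mask(m, 7, shape = "square")
  expect_equal(sum(sq), 6 * 6)
  expect_true(all(which(sq, arr.ind = TRUE) >= 18) &&
                all(which(sq, arr.ind = TRUE) <= 23))
  # disk erosion equals the pixel oracle on a random mask
  set.seed(4)
  rnd <- matrix(runif(30 * 30) > 0.35, 30, 30)
  expect_identical(suppressWarnings(unname(shrink_mask(rnd, 3))),
                   oracle_erode(rnd, 3))
  expect_warning(empty <- shrink_mask(m, 10), "annihilated")
  expect_false(any(empty))
})

test_that("spot detection counts, filters, and splits", {
  roi <- matrix(TRUE, 60, 60)
  expect_equal(nrow(detect_spots(matrix(1, 60, 60), roi & FALSE)$spots), 0)

  # noise-free well-separated spots are recovered exactly, with centroids
  img <- matrix(100, 60, 60)
  centers <- rbind(c(15, 15), c(15, 45), c(45, 15), c(45, 45), c(30, 30))
  for (k in seq_len(nrow(centers))) {
    img <- nmjscreen:::render_spot(img, centers[k, 1], centers[k, 2],
                                   radius = 4, peak = 5000)
  }
  found <- detect_spots(img, roi)
  expect_equal(nrow(found$spots), 5)
  ord <- order(found$spots$row, found$spots$col)
  co <- centers[order(centers[, 1], centers[, 2]), ]
  expect_lt(max(abs(found$spots$row[ord] - co[, 1])), 1)
  expect_true(all(found$spots$area_px2 >= 4))

  # two merged peaks: component rule counts 1, local-maxima rule counts 2,
  # matching the brute-force maxima oracle
  img2 <- matrix(100, 60, 60)
  img2 <- nmjscreen:::render_spot(img2, 30, 27, radius = 4, peak = 5000)
  img2 <- nmjscreen:::render_spot(img2, 30, 33, radius = 4, peak = 5000)
  none <- detect_spots(img2, roi, threshold = 1000, split = "none")
  expect_equal(nrow(none$spots), 1)
  split <- detect_spots(img2, roi, threshold = 1000,
                        split = "local_maxima")
  maxima <- oracle_local_maxima(img2, none$mask)
  # suppress plateau duplicates closer than the split scale
  d <- as.matrix(dist(maxima))
  n_distinct <- sum(!duplicated(lapply(seq_len(nrow(maxima)), function(i)
    sort(which(d[i, ] < 4)))))
  expect_equal(nrow(split$spots), n_distinct)
  expect_equal(nrow(split$spots), 2)
})

test_that("axon area responds to signal and pixel size", {
  roi <- matrix(TRUE, 50, 50)
  expect_equal(axon_area(matrix(7, 50, 50), roi)$area_px2, 0)
  a1 <- axon_area(wt_img$axon_channel, matrix(TRUE, 220, 400),
                  pixel_size_um = 1)
  rendered <- sum(wt_sim$masks$axon | wt_sim$masks$cord)
  expect_lt(abs(a1$area_px2 - rendered) / rendered, 0.10)
  a2 <- axon_area(wt_img$axon_channel, matrix(TRUE, 220, 400),
                  pixel_size_um = 2)
  expect_equal(a2$area_px2, a1$area_px2)
  expect_equal(a2$area_um2, 4 * a1$area_um2)
})

test_that("overlap percentage behaves at its limits and in between", {
  spot <- matrix(FALSE, 20, 20); spot[5:8, 5:8] <- TRUE
  axon <- matrix(FALSE, 20, 20); axon[1:10, 1:10] <- TRUE
  expect_equal(overlap_percent(spot, axon), 100)
  expect_equal(overlap_percent(spot, !axon), 0)
  expect_equal(overlap_percent(spot & FALSE, axon), 0)
  # half the spot mask on the axon mask
  axon2 <- matrix(FALSE, 20, 20); axon2[5:8, 5:6] <- TRUE
  expect_equal(overlap_percent(spot, axon2), 50)
  # generator calibration: equal-size spots at on_axon_fraction 0.5
  ovl <- vapply(4:8, function(s) {
    truth <- random_image_truth(n_spots = 20, on_axon_fraction = 0.5,
                                spot_radius_um = c(4, 4), noise_sd = 0,
                                seed = s)
    sim <- simulate_nmj_image(truth)
    body <- find_body_region(sim$image$achr_channel)
    roi <- shrink_mask(body, 7)
    overlap_percent(detect_spots(sim$image$achr_channel, roi),
                    axon_area(sim$image$axon_channel, roi)$mask)
  }, numeric(1))
  expect_lt(abs(mean(ovl) - 50), 5)
})

test_that("cord extraction recovers the band and respects radius 0", {
  body <- find_body_region(wt_img$achr_channel)
  cord <- extract_cord(wt_img$axon_channel, body)
  band <- wt_sim$masks$cord
  expect_gte(sum(cord$cord_mask & band) / sum(band), 0.9)
  # radius 0 smoothing is the identity
  id <- extract_cord(wt_img$axon_channel, body, median_radius_px = 0)
  expect_equal(id$smoothed,
               matrix(as.integer(pmin(round(wt_img$axon_channel), 65535)),
                      220, 400))
  # an image with only a cord band leaves (almost) no axon-only region
  bare <- simulate_nmj_image(random_image_truth(n_axons = 0, n_spots = 0,
                                                noise_sd = 0, seed = 1))
  b2 <- find_body_region(bare$image$achr_channel)
  c2 <- extract_cord(bare$image$axon_channel, b2)
  a2 <- axon_area(bare$image$axon_channel, shrink_mask(b2, 7))
  residue <- sum(a2$mask & !c2$cord_mask)
  expect_lt(residue, 0.05 * sum(c2$cord_mask))
})

test_that("axon individualization measures lengths within tolerance", {
  one <- straight_axon_mask(length_px = 120)
  ax <- individualize_axons(one, 1)
  expect_equal(ax$count, 1)
  expect_lt(abs(ax$per_axon$length_um - 120) / 120, 0.05)
  # two disjoint axons
  two <- straight_axon_mask()
  two[60:140, 80:82] <- TRUE
  expect_equal(individualize_axons(two, 1)$count, 2)
  # isolated specks below the length filter
  specks <- matrix(FALSE, 50, 50)
  specks[cbind(c(10, 30, 40), c(10, 25, 40))] <- TRUE
  expect_equal(individualize_axons(specks, 1)$count, 0)
  # empty mask
  expect_equal(individualize_axons(matrix(FALSE, 10, 10), 1)$count, 0)
})

test_that("short-axon fraction uses a strict 70 um cutoff", {
  expect_equal(short_axon_fraction(c(60, 80, 90, 50)), 50)
  expect_equal(short_axon_fraction(c(70, 80)), 0)
  expect_equal(short_axon_fraction(c(10, 69.9)), 100)
  expect_true(is.na(short_axon_fraction(numeric(0))))
})

test_that("ROI mean intensity subtracts background correctly", {
  const <- matrix(40, 30, 30)
  roi <- matrix(FALSE, 30, 30); roi[10:20, 10:20] <- TRUE
  expect_equal(roi_mean_intensity(const, roi, background = 40), 0)
  expect_error(roi_mean_intensity(const, roi & FALSE, background = 0),
               "empty ROI")
  body <- matrix(FALSE, 30, 30); body[5:25, 5:25] <- TRUE
  outside <- matrix(FALSE, 30, 30); outside[1:3, 1:3] <- TRUE
  expect_error(roi_mean_intensity(const, outside, body_mask = body),
               "outside the body")
  # rendered Gaussian over zero background vs the closed-form disk mean:
  # mean over a disk of radius R of A exp(-d^2 / (2 s^2))
  # = A * 2 s^2 / R^2 * (1 - exp(-R^2 / (2 s^2)))
  img <- nmjscreen:::render_spot(matrix(0, 61, 61), 31, 31, radius = 6,
                                 peak = 1000)
  R <- 12; s <- 3
  ii <- matrix(1:61, 61, 61); jj <- t(ii)
  disk <- (ii - 31)^2 + (jj - 31)^2 <= R^2
  analytic <- 1000 * 2 * s^2 / R^2 * (1 - exp(-R^2 / (2 * s^2)))
  measured <- roi_mean_intensity(img, disk, background = 0)
  expect_lt(abs(measured - analytic) / analytic, 0.05)
})

test_that("embryo quantification is deterministic and orders phenotypes", {
  m1 <- quantify_embryo(wt_img)
  m2 <- quantify_embryo(wt_img)
  expect_identical(m1, m2)
  mo_img <- simulate_nmj_image(phenotype_truth(0, seed = 3))$image
  m_mo <- quantify_embryo(mo_img)
  expect_gt(m1$n_achr_clusters, m_mo$n_achr_clusters)
  expect_gt(m1$overlap_percent, m_mo$overlap_percent)
  expect_gt(m1$mean_axon_length_um, m_mo$mean_axon_length_um)
  expect_lt(m1$short_axon_percent, m_mo$short_axon_percent)
  # batch keeps order and row count
  imgs <- list(wt_img, mo_img, wt_img)
  batch <- quantify_batch(imgs)
  expect_equal(nrow(batch), 3)
  expect_equal(batch$n_achr_clusters[1], batch$n_achr_clusters[3])
})

test_that("overlap stays in [0, 100] and tracks the on-axon fraction", {
  fracs <- c(0, 0.25, 0.5, 0.75, 1)
  ovl <- vapply(fracs, function(f) {
    sim <- simulate_nmj_image(random_image_truth(
      n_spots = 20, on_axon_fraction = f, seed = 11))
    m <- quantify_embryo(sim$image)
    expect_gte(m$overlap_percent, 0)
    expect_lte(m$overlap_percent, 100)
    m$overlap_percent
  }, numeric(1))
  expect_true(all(diff(ovl) > 0))
})

test_that("spot recall stays high at the default noise level", {
  recall <- vapply(4:7, function(s) {
    truth <- random_image_truth(seed = s)
    sim <- simulate_nmj_image(truth)
    m <- quantify_embryo(sim$image)
    m$n_achr_clusters / nrow(truth$spots)
  }, numeric(1))
  expect_gte(min(recall), 0.9)
})
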