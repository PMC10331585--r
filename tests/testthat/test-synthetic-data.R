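test_that("generators are pure functions of their seed", {
  p <- cohort_params(n_drugs = 12, rescue_strength = runif(12), seed = 42)
  expect_identical(simulate_screen(p), simulate_screen(p))
  np <- network_params(10, recurrent_target_spec = c(T1 = 3), seed = 7)
  expect_identical(simulate_drug_target_tables(np),
                   simulate_drug_target_tables(np))
  truth <- random_image_truth(n_axons = 4, n_spots = 8, seed = 5)
  expect_identical(simulate_nmj_image(truth)$image,
                   simulate_nmj_image(truth)$image)
  # different stage streams: adding drugs must not perturb control draws
  p0 <- cohort_params(n_drugs = 0, seed = 42)
  ctrl <- function(tab) tab$observations[
    tab$observations$group != "TREATED", ]
  expect_identical(ctrl(simulate_screen(p0))$distance_m[1:16],
                   ctrl(simulate_screen(p))$distance_m[1:16])
})

test_that("rescue limits reproduce the control distributions", {
  n <- 250
  full <- simulate_screen(cohort_params(
    n_drugs = n, rescue_strength = 1, seed = 3))
  tr <- full$observations[full$observations$group == "TREATED", ]
  wt <- full$observations[full$observations$group == "WT_CONTROL", ]
  expect_equal(mean(tr$distance_m), mean(wt$distance_m), tolerance = 0.05)
  expect_equal(sum(tr$distance_m == 0), 0)

  null <- simulate_screen(cohort_params(
    n_drugs = n, rescue_strength = 0, seed = 3))
  trn <- null$observations[null$observations$group == "TREATED", ]
  expect_equal(mean(trn$distance_m == 0), 0.792, tolerance = 0.05)
})

test_that("morphant phenotype rates calibrate at n = 10,000", {
  tab <- simulate_screen(cohort_params(n_drugs = 0, n_plates = 313,
                                       seed = 2024))
  obs <- tab$observations
  mo <- obs[obs$group == "MO_CONTROL", ]
  wt <- obs[obs$group == "WT_CONTROL", ]
  expect_gte(nrow(mo), 10000)
  zero_pct <- 100 * mean(mo$distance_m == 0)
  expect_lt(abs(zero_pct - 79.2), 1)
  movers <- mo$distance_m[mo$distance_m > 0]
  reduction_pct <- 100 * (1 - mean(movers) / mean(wt$distance_m))
  expect_lt(abs(reduction_pct - 85), 2)
})

test_that("rescreen subsets drugs and validates hit ids", {
  p <- cohort_params(n_drugs = 5, rescue_strength = 1, seed = 6)
  empty <- simulate_rescreen(p, character(0))
  expect_equal(sum(empty$observations$group == "TREATED"), 0)
  expect_error(simulate_rescreen(p, "D9999"), "unknown hit id")
  re <- simulate_rescreen(p, c("D0002", "D0004"))
  expect_setequal(unique(re$observations$drug_id[
    re$observations$group == "TREATED"]), c("D0002", "D0004"))
  # independent stream: rescreen distances differ from the screen's
  scr <- simulate_screen(p)
  expect_false(identical(
    re$observations$distance_m[re$observations$group == "TREATED"][1:4],
    scr$observations$distance_m[scr$observations$drug_id %in% "D0002"]))
})

test_that("drug-target tables honor the designed structure", {
  np <- network_params(12, n_targets = 15,
                       recurrent_target_spec = c(T1 = 3, T2 = 4),
                       unknown_fraction = 0.25, edge_density = 0.2,
                       seed = 10)
  tabs <- simulate_drug_target_tables(np)
  expect_equal(length(unique(
    tabs$pairs$drug_id[tabs$pairs$target_id == "T1"])), 3)
  expect_equal(length(unique(
    tabs$pairs$drug_id[tabs$pairs$target_id == "T2"])), 4)
  expect_length(tabs$unknown_ids, 3)  # floor(0.25 * 12)
  expect_false(any(tabs$unknown_ids %in% tabs$pairs$drug_id))
  expect_true(all(tabs$edges$confidence >= 0 & tabs$edges$confidence <= 1))

  all_unknown <- simulate_drug_target_tables(
    network_params(8, unknown_fraction = 1, seed = 1))
  expect_equal(nrow(all_unknown$pairs), 0)
  expect_length(all_unknown$unknown_ids, 8)

  no_edges <- simulate_drug_target_tables(
    network_params(8, recurrent_target_spec = c(T1 = 3),
                   edge_density = 0, seed = 1))
  expect_equal(nrow(no_edges$edges), 0)

  expect_error(simulate_drug_target_tables(
    network_params(4, recurrent_target_spec = c(T1 = 4),
                   unknown_fraction = 0.25, seed = 1)),
    "multiplicity exceeds")
})

test_that("network tables round-trip through TSV", {
  tabs <- simulate_drug_target_tables(
    network_params(10, recurrent_target_spec = c(T1 = 3), seed = 4))
  fp <- withr::local_tempfile(fileext = ".tsv")
  fe <- withr::local_tempfile(fileext = ".tsv")
  write_network_tables(tabs, fp, fe)
  back <- read_network_tables(fp, fe)
  expect_equal(back$pairs, tabs$pairs)
  expect_equal(back$edges, tabs$edges)
})

test_that("image truth validates its geometry", {
  expect_error(image_truth(spots = data.frame(
    row = 5, col = 500, radius = 3, peak = 1000, on_axon = FALSE)),
    "outside the frame")
  expect_error(image_truth(axons = list(list(
    points = cbind(c(150, 160), c(50, 50)), length_um = 10))),
    "originate in the cord band")
})

test_that("rendering matches its stated noise and geometry", {
  # zero spots, zero noise: AChR channel is exactly background + body
  truth <- random_image_truth(n_axons = 2, n_spots = 0, noise_sd = 0,
                              seed = 1)
  sim <- simulate_nmj_image(truth)
  expect_setequal(unique(as.numeric(sim$image$achr_channel)),
                  c(truth$background[["achr"]], truth$body_base[["achr"]]))

  # 12 isolated spots at low noise are recovered exactly
  truth2 <- random_image_truth(n_axons = 3, n_spots = 12, noise_sd = 20,
                               seed = 2)
  sim2 <- simulate_nmj_image(truth2)
  body <- find_body_region(sim2$image$achr_channel)
  spots <- detect_spots(sim2$image$achr_channel, shrink_mask(body, 7))
  expect_equal(nrow(spots$spots), 12)

  # a designed 120 um axon at 1 um/px measures within 5%
  truth3 <- random_image_truth(n_axons = 1, axon_length_um = 120,
                               axon_length_sd_um = 0, n_spots = 0,
                               noise_sd = 0, seed = 3)
  expect_equal(truth3$axons[[1]]$length_um, 120)
  sim3 <- simulate_nmj_image(truth3)
  body3 <- find_body_region(sim3$image$achr_channel)
  cord3 <- extract_cord(sim3$image$axon_channel, body3)
  ax3 <- axon_area(sim3$image$axon_channel, shrink_mask(body3, 7))
  axons3 <- individualize_axons(ax3$mask & !cord3$band_mask, 1)
  expect_equal(axons3$count, 1)
  expect_lt(abs(axons3$per_axon$length_um - 120) / 120, 0.05)
})

test_that("images round-trip through TIFF with sidecar metadata", {
  truth <- random_image_truth(n_axons = 2, n_spots = 4, seed = 9)
  img <- simulate_nmj_image(truth, embryo_id = "e7", group = "MO_CONTROL",
                            drug_id = "D0001")$image
  f <- withr::local_tempfile(fileext = ".tiff")
  write_nmj_image(img, f)
  back <- read_nmj_image(f)
  expect_equal(back$axon_channel, round(img$axon_channel))
  expect_equal(back$achr_channel, round(img$achr_channel))
  expect_equal(back$pixel_size_um, 1.0)
  expect_equal(back$embryo_id, "e7")
  expect_equal(back$group, "MO_CONTROL")
  expect_equal(back$drug_id, "D0001")
})
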