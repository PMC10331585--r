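test_that("Z'-factor matches the closed form and its limits", {
  # zero spread in both controls -> exactly 1
  expect_equal(z_prime(list(mu = 5, sigma = 0), list(mu = 1, sigma = 0)), 1)
  # direct evaluation: 1 - 3 * (10 + 10) / |100 - 0|
  expect_equal(z_prime(list(mu = 100, sigma = 10), list(mu = 0, sigma = 10)),
               0.4)
  expect_error(z_prime(list(mu = 1, sigma = 0.1), list(mu = 1, sigma = 0.1)),
               "medians coincide")
  # strictly decreasing in either spread, invariant under label exchange
  base <- z_prime(list(mu = 10, sigma = 1), list(mu = 0, sigma = 1))
  for (s in c(1.5, 2, 5)) {
    expect_lt(z_prime(list(mu = 10, sigma = s), list(mu = 0, sigma = 1)),
              base)
    expect_lt(z_prime(list(mu = 10, sigma = 1), list(mu = 0, sigma = s)),
              base)
  }
  expect_equal(z_prime(list(mu = 0, sigma = 1), list(mu = 10, sigma = 2)),
               z_prime(list(mu = 10, sigma = 2), list(mu = 0, sigma = 1)))
})

test_that("median normalization maps the WT median to 1", {
  wt <- c(0.8, 1.0, 1.2, 1.4)
  expect_equal(median(median_normalize(wt, wt)), 1)
  expect_equal(median_normalize(0, wt), 0)
  expect_equal(median_normalize(c(0.5, 1.0), c(2, 2, 2)), c(0.25, 0.5))
  expect_error(median_normalize(1, c(0, 0, 0)), "median is zero")
})

test_that("robust z-score follows the median/MAD convention", {
  expect_equal(robust_z(1.0, c(0.8, 1.0, 1.2, 1.0)), 0)
  # hand evaluation: median 1.0, raw MAD 0.1, x' = 0.7 -> -3
  expect_equal(robust_z(0.7, c(0.8, 1.0, 1.2, 1.0)), -3)
  expect_warning(z <- robust_z(1.5, c(1, 1, 1, 1)), "MAD is zero")
  expect_true(is.finite(z) && z > 0)
  # untreated morphants score far below the WT scale on synthetic data
  tab <- simulate_screen(cohort_params(n_drugs = 0, n_plates = 3, seed = 11))
  obs <- tab$observations[tab$observations$plate == 1, ]
  wt <- obs$distance_m[obs$group == "WT_CONTROL"]
  mo <- obs$distance_m[obs$group == "MO_CONTROL"]
  z_mo <- robust_z(median_normalize(mo, wt), median_normalize(wt, wt))
  expect_lt(mean(z_mo), -2)
})

test_that("classification matches the worked examples", {
  expect_equal(classify_drug(c(0.3, 0.2, -0.1, 0.1), rep(TRUE, 4)), "HIT_A")
  expect_equal(classify_drug(c(0.5, 0.4, -2.5, -2.8), rep(TRUE, 4)), "HIT_B")
  expect_equal(classify_drug(c(NA, NA, NA, 0.5),
                             c(FALSE, FALSE, FALSE, TRUE)), "TOXIC")
  expect_equal(classify_drug(c(0.5, -2.0, -3.0, -2.5), rep(TRUE, 4)),
               "NON_HIT")
  expect_error(classify_drug(c(0, 0), c(TRUE, TRUE)), "expected 4 fish")
})

test_that("classification agrees with exhaustive rule enumeration", {
  # all 4^4 patterns over {dead, z <= -1, -1 < z <= 0, z > 0}
  status_z <- c(NA, -2.5, -0.5, 0.5)
  grid <- expand.grid(s1 = 1:4, s2 = 1:4, s3 = 1:4, s4 = 1:4)
  for (r in seq_len(nrow(grid))) {
    s <- as.integer(grid[r, ])
    z <- status_z[s]
    alive <- s != 1
    expect_equal(classify_drug(z, alive),
                 oracle_classify(z, alive),
                 info = paste(s, collapse = ","))
  }
})

test_that("screen scoring partitions drugs and flags missing controls", {
  params <- cohort_params(n_drugs = 30, rescue_strength = runif(30),
                          toxicity_prob = 0.2, seed = 5)
  res <- screen_scores(simulate_screen(params))
  expect_equal(sum(res$counts), 30)
  expect_setequal(res$per_drug$drug_id, sprintf("D%04d", 1:30))
  # all-null cohort: no toxicity, hits only from noise (rare)
  null_res <- screen_scores(simulate_screen(
    cohort_params(n_drugs = 50, seed = 8)))
  expect_equal(null_res$counts[["TOXIC"]], 0)
  expect_lte(null_res$counts[["HIT_A"]] + null_res$counts[["HIT_B"]], 2)
  # full rescue at tiny dispersion is called HIT_A deterministically
  tight <- screen_scores(simulate_screen(
    cohort_params(n_drugs = 5, rescue_strength = 1,
                  wt_distance_cv = 0.02, seed = 2)))
  expect_true(all(tight$per_drug$category == "HIT_A"))
  # missing controls error names the plate
  tab <- simulate_screen(cohort_params(n_drugs = 2, seed = 1))
  tab$observations <- tab$observations[
    !(tab$observations$plate == 2 &
        tab$observations$group == "MO_CONTROL"), ]
  expect_error(screen_scores(screen_table(tab$observations, tab$drugs)),
               "plate 2")
})

test_that("z-scores are invariant to multiplicative plate effects", {
  params <- cohort_params(n_drugs = 8, rescue_strength = runif(8), seed = 9)
  tab <- simulate_screen(params)
  res1 <- screen_scores(tab)
  scaled <- tab
  scaled$observations$distance_m <- scaled$observations$distance_m * 3.7
  res2 <- screen_scores(scaled)
  expect_equal(res2$per_fish$z, res1$per_fish$z)
  expect_identical(res2$per_drug$category, res1$per_drug$category)
})

test_that("NPA endpoints, midpoint and printed variant", {
  expect_equal(npa(10, mu_neg = 2, mu_pos = 10), 100)
  expect_equal(npa(2, mu_neg = 2, mu_pos = 10), 0)
  expect_equal(npa(6, mu_neg = 2, mu_pos = 10), 50)
  expect_equal(npa(6, mu_neg = 2, mu_pos = 10, variant = "as_printed"), -50)
  expect_error(npa(1, 3, 3), "medians coincide")
  # affine invariance of the standard orientation
  for (seed in 1:5) {
    set.seed(seed)
    x <- runif(1, 0, 5); mn <- runif(1); mp <- mn + runif(1, 0.5, 2)
    a <- runif(1, 0.5, 3); b <- runif(1, -2, 2)
    expect_equal(npa(a * x + b, a * mn + b, a * mp + b), npa(x, mn, mp))
  }
})

test_that("rescreen NPA passes full rescue and fails null drugs", {
  params <- cohort_params(n_drugs = 2, rescue_strength = c(1, 0), seed = 4)
  res <- rescreen_npa(simulate_rescreen(params, c("D0001", "D0002")))
  expect_true(res$pass[res$drug_id == "D0001"])
  expect_false(res$pass[res$drug_id == "D0002"])
  expect_gt(res$mean_npa[res$drug_id == "D0001"], 80)
  expect_lt(res$mean_npa[res$drug_id == "D0002"], 20)
  # a mean exactly at the cutoff passes (inclusive)
  tab <- toy_screen(treated_obs("D1", rep(1, 4)),
                    wt = c(2, 2, 2, 2), mo = c(0, 0, 0, 0))
  at_cutoff <- rescreen_npa(tab)
  expect_equal(at_cutoff$mean_npa, 50)
  expect_true(at_cutoff$pass)
})

test_that("dose-response summary gates toxic doses", {
  mk <- function(e, ptox, seed) simulate_screen(
    cohort_params(n_drugs = 5, rescue_strength = e, toxicity_prob = ptox,
                  seed = seed))
  tabs <- list("0.1" = mk(0.1, 0, 1), "1" = mk(0.5, 0, 2),
               "10" = mk(1, 0, 3), "30" = mk(1, 1, 4))
  out <- dose_response_summary(tabs)
  expect_true(out$toxic[out$dose == 30])
  expect_false(out$included[out$dose == 30])
  means <- out$mean_distance_m[out$included]
  expect_true(all(diff(means) > 0))  # monotone designed effect
  expect_error(dose_response_summary(tabs[1]), "at least two doses")
  # single survivor: mean reported, sem absent
  one <- toy_screen(treated_obs("D1", c(1, 0, 0, 0),
                                alive = c(TRUE, FALSE, FALSE, FALSE)))
  out2 <- dose_response_summary(list("1" = one, "2" = one))
  expect_equal(out2$mean_distance_m, c(1, 1))
  expect_true(all(is.na(out2$sem)))
})
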