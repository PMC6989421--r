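# Cohort averaging, leave-one-out bookkeeping and the normalisation model.

test_that("degenerate cohorts give exact means and zero variances", {
  co <- make_aligned_cohort(n = 5, noise_sd = 0, ranges = zero_ranges)
  m <- surgical_model(co, exclude = "P001")
  expect_setequal(m$contributing, paste0("P00", 2:5))
  common <- landmark_coords(co[[2]]$landmarks_post) -
    landmark_coords(co[[2]]$landmarks_pre)
  expect_equal(m$mean_change, common, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(m$variances, rep(0, nrow(m$mean_change)))

  # cohort of 2, exclude one: the model is the other's change vectors
  m2 <- surgical_model(co[1:2], exclude = "P001")
  expect_equal(m2$contributing, "P002")
  expect_equal(m2$mean_change, common, tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(surgical_model(co[1:2], exclude = c("P001", "P002")),
               "no contributing")
  expect_error(surgical_model(co, exclude = "nope"), "not in cohort")
})

test_that("leave-one-out bookkeeping and order invariance hold", {
  co <- make_aligned_cohort(n = 6, seed = 3)
  m <- surgical_model(co, exclude = "P003")
  expect_false("P003" %in% m$contributing)
  expect_length(m$contributing, 5)
  # arbitrary exclusion lists
  m2 <- surgical_model(co, exclude = c("P001", "P004", "P006"))
  expect_length(m2$contributing, 3)
  # exchangeability: shuffled cohort gives the identical model
  set.seed(9)
  ms <- surgical_model(co[sample(6)], exclude = "P003")
  expect_identical(ms$mean_change, m$mean_change)
  expect_identical(ms$variances, m$variances)
  expect_identical(ms$contributing, m$contributing)
})

test_that("cohort means converge to the generator's field", {
  co <- make_aligned_cohort(n = 20, seed = 11, noise_sd = 1,
                            ranges = zero_ranges, n_lat = 11, n_lon = 16)
  m <- surgical_model(co, exclude = "P001")
  expect_length(m$contributing, 19)
  # all patients share one shape, so the aligned truth is the same for all:
  # compare the averaged change vectors to the held-out patient's noise-free
  # change (the field itself)
  ds <- co[["P001"]]
  truth <- apply_rigid(ds$alignment$pre,
                       landmark_coords(ds$truth$landmarks_post_true)) -
    landmark_coords(ds$landmarks_pre)
  err <- m$mean_change - truth
  mid <- ds$landmarks_pre$region %in% c("nasal", "maxillary")
  bound <- 3 * 1 / sqrt(19)
  expect_gte(mean(abs(err[mid, ]) <= bound), 0.99)
  expect_lt(sqrt(mean(err[mid, ]^2)), 2 / sqrt(19))
})

test_that("per-landmark variance follows the stated estimators", {
  co <- make_aligned_cohort(n = 2, seed = 5, noise_sd = 0,
                            ranges = zero_ranges)
  # displace one craniometric landmark by +/- d in x across the two patients
  nm <- "cran_ocular_r_1"
  d <- 1.5
  for (i in 1:2) {
    lc <- landmark_coords(co[[i]]$landmarks_pre)
    lc[rownames(lc) == nm, 1] <- lc[rownames(lc) == nm, 1] +
      (if (i == 1) d else -d)
    co[[i]]$landmarks_pre <- set_landmark_coords(co[[i]]$landmarks_pre, lc)
  }
  st <- craniometric_stats(co, variance_estimator = "sample")
  k <- which(st$names == nm)
  # sample covariance trace of {+d, -d}: 2 d^2
  expect_equal(st$variances[k], 2 * d^2, tolerance = 1e-9)
  st2 <- craniometric_stats(co, variance_estimator = "of_mean")
  expect_equal(st2$variances[k], d^2, tolerance = 1e-9)
  expect_equal(st$mean[k, ],
               (landmark_coords(co[[1]]$landmarks_pre, st$names)[k, ] +
                  landmark_coords(co[[2]]$landmarks_pre, st$names)[k, ]) / 2,
               tolerance = 1e-9)
})

test_that("variance estimates match the generating noise", {
  set.seed(61)
  # seeded Gaussian cloud around fixed positions, known sigma
  base <- make_aligned_cohort(n = 2, noise_sd = 0, ranges = zero_ranges)
  tmpl <- base[[1]]
  sigma <- 0.8
  co <- lapply(1:40, function(i) {
    ds <- tmpl
    ds$patient_id <- sprintf("Q%02d", i)
    lc <- landmark_coords(ds$landmarks_pre)
    ds$landmarks_pre <- set_landmark_coords(
      ds$landmarks_pre, lc + matrix(rnorm(length(lc), sd = sigma), ncol = 3))
    ds$landmarks_post <- set_landmark_coords(ds$landmarks_post,
                                             landmark_coords(ds$landmarks_post))
    ds
  })
  st <- craniometric_stats(co, variance_estimator = "sample")
  # E[trace variance] = 3 sigma^2; Monte-Carlo tolerance over 36 landmarks
  expect_equal(mean(st$variances), 3 * sigma^2, tolerance = 0.15)
})

test_that("normalisation matches the cohort mean and inverts exactly", {
  co <- make_aligned_cohort(n = 4, seed = 13)
  st <- craniometric_stats(co)
  ds <- co[["P002"]]
  norm <- normalisation_model(ds, st)
  cran <- landmark_coords(ds$landmarks_pre, st$names)
  # forward-then-reverse restores every craniometric landmark
  rt <- predict(norm, predict(norm, cran, "forward"), "reverse")
  expect_lt(max(sqrt(rowSums((rt - cran)^2))), 1e-6)
  # reverse warp is an exact interpolant (zero smoothing)
  expect_equal(norm$reverse$alpha, 0)
  expect_lt(max(sqrt(rowSums(residuals(norm$reverse)^2))), 1e-8)

  # a patient identical to the cohort mean: both warps are the zero field
  mean_ds <- ds
  lc <- landmark_coords(mean_ds$landmarks_pre)
  lc[match(st$names, rownames(lc)), ] <- st$mean
  mean_ds$landmarks_pre <- set_landmark_coords(mean_ds$landmarks_pre, lc)
  n0 <- normalisation_model(mean_ds, st)
  q <- matrix(runif(30, -80, 80), 10, 3)
  expect_equal(predict(n0, q, "forward"), q, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(predict(n0, q, "reverse"), q, tolerance = 1e-8,
               ignore_attr = TRUE)

  # zero-variance stats interpolate exactly at the centres
  st0 <- st; st0$variances[] <- 0
  scaled <- ds
  lc2 <- landmark_coords(scaled$landmarks_pre)
  lc2[match(st$names, rownames(lc2)), ] <- st$mean * 1.2
  scaled$landmarks_pre <- set_landmark_coords(scaled$landmarks_pre, lc2)
  nsc <- normalisation_model(scaled, st0)
  fw <- predict(nsc, st$mean * 1.2, "forward")
  expect_lt(max(sqrt(rowSums((fw - st$mean)^2))), 1e-8)

  # missing craniometric landmark errors by name
  broken <- ds
  broken$landmarks_pre <- ds$landmarks_pre[
    ds$landmarks_pre$name != st$names[1], ]
  expect_error(normalisation_model(broken, st), st$names[1], fixed = TRUE)
})
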