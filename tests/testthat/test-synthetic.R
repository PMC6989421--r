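# The synthetic head / surgery / cohort generator.

test_that("head generation is deterministic and schema-complete", {
  h1 <- generate_head(head_params(seed = 4), n_lat = 11, n_lon = 16)
  h2 <- generate_head(head_params(seed = 4), n_lat = 11, n_lon = 16)
  expect_identical(h1$skin$vertices, h2$skin$vertices)
  expect_identical(h1$bone$vertices, h2$bone$vertices)
  expect_identical(landmark_coords(h1$landmarks),
                   landmark_coords(h2$landmarks))
  # emitted roles/regions exactly match the packaged dictionary
  d <- landmark_dictionary()
  expect_identical(h1$landmarks$name, d$name)
  expect_identical(h1$landmarks$role, d$role)
  expect_identical(h1$landmarks$region, d$region)
  # meshes are closed, consistently oriented surfaces
  expect_true(craniowarp:::is_consistently_oriented(h1$bone))
  expect_true(craniowarp:::is_consistently_oriented(h1$skin))
})

test_that("zero asymmetry gives mirror-symmetric landmark pairs", {
  h <- generate_head(head_params(asymmetry = 0, turricephaly = 1.1,
                                 brachycephaly = 0.95, retrusion = 5))
  d <- landmark_dictionary()
  lc <- landmark_coords(h$landmarks)
  paired <- d[!is.na(d$pair) & d$side == "r", ]
  right <- lc[paired$name, , drop = FALSE]
  left <- lc[paired$pair, , drop = FALSE]
  expect_lt(max(abs(right[, 1] + left[, 1])), 1e-9)
  expect_lt(max(abs(right[, 2:3] - left[, 2:3])), 1e-9)
  # asymmetry breaks the symmetry
  ha <- generate_head(head_params(asymmetry = 4))
  lca <- landmark_coords(ha$landmarks)
  expect_gt(max(abs(lca[paired$name, 1] + lca[paired$pair, 1])), 0.5)
})

test_that("overall scale multiplies all pairwise landmark distances", {
  h1 <- generate_head(head_params(scale = 1.0, seed = 2))
  h2 <- generate_head(head_params(scale = 1.2, seed = 2))
  d1 <- dist(landmark_coords(h1$landmarks))
  d2 <- dist(landmark_coords(h2$landmarks))
  expect_lt(max(abs(d2 / d1 - 1.2)), 1e-9)
})

test_that("shape factors produce the intended proportions", {
  base <- landmark_coords(generate_head(head_params())$landmarks)
  tall <- landmark_coords(generate_head(head_params(turricephaly = 1.2))$landmarks)
  short <- landmark_coords(generate_head(head_params(brachycephaly = 1.2))$landmarks)
  expect_equal(diff(range(tall[, 3])) / diff(range(base[, 3])), 1.2,
               tolerance = 1e-9)
  expect_equal(diff(range(short[, 2])) / diff(range(base[, 2])), 1 / 1.2,
               tolerance = 1e-9)
  retr <- landmark_coords(generate_head(head_params(retrusion = 8))$landmarks)
  mid <- generate_head(head_params())$landmarks$region == "maxillary"
  expect_lt(max(retr[mid, 2]), max(base[mid, 2]))
})

test_that("null surgery is the identity and noise hits landmarks only", {
  h <- generate_head(head_params(), n_lat = 11, n_lon = 16)
  s0 <- simulate_surgery(h, surgery_params(advancement = c(0, 0, 0),
                                           descent = 0, noise_sd = 0))
  expect_identical(s0$skin$vertices, h$skin$vertices)
  expect_identical(landmark_coords(s0$landmarks),
                   landmark_coords(h$landmarks))
  s1 <- simulate_surgery(h, surgery_params(noise_sd = 1.5, seed = 9))
  expect_identical(s1$skin$vertices,
                   simulate_surgery(h, surgery_params(noise_sd = 0))$skin$vertices)
  dev <- landmark_coords(s1$landmarks) - landmark_coords(s1$landmarks_true)
  expect_equal(sd(as.numeric(dev)), 1.5, tolerance = 0.15)
  # determinism of the noise under the seed
  s1b <- simulate_surgery(h, surgery_params(noise_sd = 1.5, seed = 9))
  expect_identical(landmark_coords(s1$landmarks),
                   landmark_coords(s1b$landmarks))
})

test_that("the surgical field is facial: skull base moves < 1% of mid-face", {
  h <- generate_head(head_params())
  f <- surgical_field(surgery_params(advancement = c(0, 15, 0), descent = 0))
  lc <- landmark_coords(h$landmarks)
  mag <- sqrt(rowSums(f(lc)^2))
  base <- h$landmarks$role %in% c("reference", "bone_static")
  mid <- h$landmarks$region %in% c("nasal", "maxillary")
  expect_lt(max(mag[base]), 0.01 * max(mag[mid]))
})

test_that("the bipartition field diverges the maxilla and medialises orbits", {
  h <- generate_head(head_params())
  f <- surgical_field(surgery_params(bipartition = TRUE))
  lc <- landmark_coords(h$landmarks)
  dx <- f(lc)[, 1]
  d <- landmark_dictionary()
  maxr <- d$region == "maxillary" & d$side == "r" & d$role != "skin"
  maxl <- d$region == "maxillary" & d$side == "l" & d$role != "skin"
  # para-midline widening: right side moves +x, left side -x
  expect_true(all(dx[maxr] > 0))
  expect_true(all(dx[maxl] < 0))
  ocr <- d$region == "ocular" & d$side == "r" & d$role != "skin"
  ocl <- d$region == "ocular" & d$side == "l" & d$role != "skin"
  expect_true(all(dx[ocr] < 0))
  expect_true(all(dx[ocl] > 0))
})

test_that("mandibular auto-rotation moves only the mandible", {
  h <- generate_head(head_params())
  s_off <- simulate_surgery(h, surgery_params(noise_sd = 0))
  s_on <- simulate_surgery(h, surgery_params(noise_sd = 0,
                                             mandible_rotation = TRUE))
  d <- sqrt(rowSums((landmark_coords(s_on$landmarks) -
                       landmark_coords(s_off$landmarks))^2))
  mand <- h$landmarks$region == "mandibular"
  expect_gt(min(d[mand]), 0)
  expect_equal(max(d[!mand]), 0)
})

test_that("cohorts are reproducible, correspondable and share the field", {
  co <- generate_cohort(n = 5, ranges = zero_ranges,
                        surgery = surgery_params(noise_sd = 0),
                        seed = 3, n_lat = 9, n_lon = 12)
  for (i in 2:5) {
    expect_identical(landmark_coords(co[[i]]$landmarks_pre),
                     landmark_coords(co[[1]]$landmarks_pre))
    expect_identical(co[[i]]$skin_post$vertices, co[[1]]$skin_post$vertices)
  }
  co2 <- generate_cohort(n = 20, seed = 8, n_lat = 9, n_lon = 12)
  expect_length(unique(vapply(co2, `[[`, "", "patient_id")), 20)
  for (ds in co2)
    expect_true(correspondable(ds$landmarks_pre, ds$landmarks_post))
  # reproducibility
  co3 <- generate_cohort(n = 20, seed = 8, n_lat = 9, n_lon = 12)
  expect_identical(landmark_coords(co2[[7]]$landmarks_post),
                   landmark_coords(co3[[7]]$landmarks_post))
})

test_that("cohort mean change converges to the field at sigma/sqrt(n)", {
  err <- vapply(c(5, 20, 80), function(n) {
    co <- generate_cohort(n = n, ranges = zero_ranges,
                          surgery = surgery_params(noise_sd = 1),
                          seed = 13, n_lat = 9, n_lon = 12)
    chg <- Reduce(`+`, lapply(co, function(ds)
      landmark_coords(ds$landmarks_post) -
        landmark_coords(ds$landmarks_pre))) / n
    truth <- landmark_coords(co[[1]]$truth$landmarks_post_true) -
      landmark_coords(co[[1]]$landmarks_pre)
    apex <- which.max(sqrt(rowSums(truth^2)))   # mid-face apex landmark
    sqrt(sum((chg[apex, ] - truth[apex, ])^2))
  }, numeric(1))
  expect_lt(err[3], err[1])
  expect_true(all(err < 3 * sqrt(3) / sqrt(c(5, 20, 80))))
})
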