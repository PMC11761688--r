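test_that("clutch scenes honor geometry preconditions and statistics", {
  expect_error(make_clutch_scene(0, 10, 50), class = "paintkit_invalid_parameter")
  expect_error(make_clutch_scene(5, 10, 500, fov = c(1000, 1000)),
               class = "paintkit_invalid_parameter")

  sc <- make_clutch_scene(1, 100, 50, fov = c(5000, 5000), seed = 7)
  ev <- eigen(cov(cbind(sc$sites$x, sc$sites$y)), only.values = TRUE)$values
  expect_true(all(abs(ev - 2500) / 2500 < 0.3))

  big <- make_clutch_scene(1000, 20, 50, fov = c(150000, 150000), seed = 1)
  expect_equal(nrow(big$sites), 20000)
  expect_equal(length(unique(big$sites$structure_id)), 1000)
  expect_true(all(big$sites$x >= 0 & big$sites$x <= 150000))
  expect_true(all(big$sites$y >= 0 & big$sites$y <= 150000))
})

test_that("tube scenes scatter sites transversely and move as requested", {
  # static limit: no motion function at drift 0
  st <- make_tube_scene(2, 75, 50, drift_speed = 0, seed = 3)
  expect_null(st$motion)

  # one straight horizontal tube: y-spread equals tube_sigma
  ctrl <- list(cbind(seq(1000, 19000, length.out = 5), rep(10000, 5)))
  tb <- make_tube_scene(1, 75, 400, drift_speed = 0, seed = 5,
                        control_points = ctrl)
  expect_lt(abs(sd(tb$sites$y) - 75) / 75, 0.25)

  # drift 10 nm/s for 100 s displaces by about 1000 nm
  mv <- make_tube_scene(3, 50, 20, drift_speed = 10, fov = c(30000, 30000), seed = 9)
  disp <- mv$motion(0:2, 100)
  mag <- sqrt(rowSums(disp^2))
  expect_true(all(abs(mag - 1000) / 1000 < 0.3))
  expect_equal(unname(mv$motion(0:2, 0)[, 1] * 0), c(0, 0, 0))
})

test_that("binding event simulation follows Poisson/exponential kinetics", {
  sc <- make_clutch_scene(10, 10, 30, fov = c(10000, 10000), seed = 2)
  k0 <- kinetics_params(site_on_rate = 0, duration = 100)
  expect_equal(nrow(simulate_binding(sc, k0, seed = 1)), 0)

  k <- kinetics_params(site_on_rate = 0.1, mean_residence = 0.1, duration = 100)
  tr <- simulate_binding(sc, k, seed = 4)
  expect_lt(abs(nrow(tr) - 1000), 3 * sqrt(1000))
  expect_lt(abs(mean(tr$duration) - 0.1) / 0.1, 0.1)
  expect_true(!is.unsorted(tr$start))
  expect_true(all(tr$duration > 0))

  # determinism: same seed, identical trace
  expect_identical(tr, simulate_binding(sc, k, seed = 4))
  expect_false(identical(tr, simulate_binding(sc, k, seed = 5)))
})

test_that("direct-mode localizations respect frame overlap and noise model", {
  sc <- make_clutch_scene(1, 1, 1, fov = c(1000, 1000), seed = 1)
  k <- kinetics_params(duration = 1, exposure = 0.05)
  tr <- structure(data.frame(site = 1L, start = 0.1, duration = 0.2),
                  class = c("binding_trace", "data.frame"))
  tab <- events_to_localizations(sc, tr, k, precision_model = 0, seed = 1)
  expect_equal(nrow(tab), 4)               # 0.2 s / 0.05 s
  expect_equal(tab$frame, 3:6)             # consecutive
  expect_equal(tab$x, rep(sc$sites$x, 4))  # noiseless limit
  expect_equal(tab$y, rep(sc$sites$y, 4))

  # isotropic noise: RMS radial error = precision * sqrt(2)
  k2 <- kinetics_params(site_on_rate = 3, mean_residence = 0.2, duration = 100)
  tr2 <- simulate_binding(sc, k2, seed = 7)
  tab2 <- events_to_localizations(sc, tr2, k2, precision_model = 20, seed = 8)
  expect_gt(nrow(tab2), 1000)
  rms <- sqrt(mean((tab2$x - sc$sites$x)^2 + (tab2$y - sc$sites$y)^2))
  expect_lt(abs(rms - 20 * sqrt(2)) / (20 * sqrt(2)), 0.1)
})

test_that("localization count equals the overlapped-frame count of each event", {
  sc <- make_clutch_scene(5, 4, 40, fov = c(8000, 8000), seed = 3)
  k <- kinetics_params(site_on_rate = 0.1, mean_residence = 0.12, duration = 30)
  tr <- simulate_binding(sc, k, seed = 11)
  tab <- events_to_localizations(sc, tr, k, precision_model = 10, seed = 12)
  # independent recount of >=50%-overlap frames per event
  e <- k$exposure
  count_frames <- function(s, d) {
    ks <- max(1, floor(s / e) + 1):min(k$n_frames, floor((s + d) / e) + 1)
    ov <- pmin(s + d, ks * e) - pmax(s, (ks - 1) * e)
    sum(ov >= e / 2)
  }
  expect_equal(nrow(tab), sum(mapply(count_frames, tr$start, tr$duration)))
})

test_that("localization rate matches the kinetic scaling law", {
  sc <- make_clutch_scene(20, 10, 40, fov = c(20000, 20000), seed = 5)
  k <- kinetics_params(site_on_rate = 0.05, mean_residence = 0.1, duration = 100)
  tr <- simulate_binding(sc, k, seed = 6)
  # default half-frame overlap rule: rate ~ n * k_on * tau/exposure
  tab <- events_to_localizations(sc, tr, k, precision_model = 20, seed = 7)
  rate <- nrow(tab) / k$duration
  expect_lt(abs(rate - expected_localization_rate(sc, k)) /
            expected_localization_rate(sc, k), 0.2)
  # any-overlap convention: rate ~ n * k_on * (tau/exposure + 1)
  tab0 <- events_to_localizations(sc, tr, k, precision_model = 20, seed = 7,
                                  overlap_min = 1e-9)
  rate0 <- nrow(tab0) / k$duration
  exp0 <- expected_localization_rate(sc, k, overlap_min = 0)
  expect_lt(abs(rate0 - exp0) / exp0, 0.2)
})

test_that("rendered stacks conserve photons and frame count", {
  fov <- c(3200, 3200)
  sc <- structure(list(sites = data.frame(x = 1600, y = 1600, structure_id = 0L),
                       fov = fov, motion = NULL, scene_kind = "clutch"),
                  class = "gt_scene")
  k <- kinetics_params(site_on_rate = 1e-12, photon_rate = 20000,
                       duration = 0.5, exposure = 0.05)
  cam <- camera_model(pixel_size = 100, psf_sigma = 150, background_rate = 5, fov = fov)

  # empty trace: frames are pure background
  tr0 <- structure(data.frame(site = integer(0), start = numeric(0),
                              duration = numeric(0)),
                   class = c("binding_trace", "data.frame"))
  st0 <- render_stack(sc, tr0, k, cam, seed = 1)
  expect_equal(dim(st0)[3], 10)
  expect_lt(abs(mean(st0) - 5), 3 * sqrt(5 / length(st0)))

  # one full-frame event, no background: photons are Poisson-conserved
  cam0 <- camera_model(pixel_size = 100, psf_sigma = 150, background_rate = 0, fov = fov)
  tr1 <- structure(data.frame(site = 1L, start = 0.05, duration = 0.05),
                   class = c("binding_trace", "data.frame"))
  st1 <- render_stack(sc, tr1, k, cam0, seed = 2)
  n_expect <- 20000 * 0.05
  expect_lt(abs(sum(st1[, , 2]) - n_expect), 3 * sqrt(n_expect))
  expect_equal(sum(st1[, , -2]), 0)

  # determinism
  expect_identical(st1, render_stack(sc, tr1, k, cam0, seed = 2))
})

test_that("the default acquisition is 4000 frames of 50 ms over 200 s", {
  k <- kinetics_params()
  expect_equal(k$exposure, 0.05)
  expect_equal(k$duration, 200)
  expect_equal(k$n_frames, 4000L)
})

test_that("scenes, traces and stacks round-trip through their file formats", {
  sc <- make_clutch_scene(3, 5, 30, fov = c(4000, 4000), seed = 13)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_scene(sc, f1)
  sc2 <- read_scene(f1)
  expect_equal(sc2$sites$x, sc$sites$x, tolerance = 1e-6)
  expect_equal(sc2$fov, sc$fov)
  expect_equal(sc2$scene_kind, "clutch")

  k <- kinetics_params(site_on_rate = 0.1, duration = 10)
  tr <- simulate_binding(sc, k, seed = 14)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, f2)
  tr2 <- read_trace(f2)
  expect_equal(tr2$start, tr$start, tolerance = 1e-6)

  cam <- camera_model(pixel_size = 100, psf_sigma = 150, background_rate = 3,
                      fov = sc$fov)
  st <- render_stack(sc, tr, kinetics_params(site_on_rate = 0.1, duration = 0.25),
                     cam, seed = 15)
  f3 <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(st, f3)
  st2 <- read_stack_tiff(f3, pixel_size = 100, exposure = 0.05)
  expect_equal(dim(st2), dim(st))
  expect_equal(max(abs(st2 - st)), 0)
})
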