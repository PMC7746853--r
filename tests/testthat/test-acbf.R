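test_that("edge stopping function matches its closed forms", {
  expect_true(all(esf_g(matrix(0.5, 10, 10)) == 1))
  # 1-D ramp of slope s, negligible smoothing: g = 1/(1+s^2) in the interior
  s <- 0.05
  img <- matrix(rep(s * (1:30), each = 20), 20, 30)
  g <- esf_g(img, kernel_size = 1, sigma = 1)
  expect_equal(g[5:15, 5:25], matrix(1 / (1 + s^2), 11, 21), tolerance = 1e-10)
  # sharper edges give smaller g
  soft <- matrix(rep(seq(0, 1, length.out = 20), each = 20), 20, 20)
  hard <- cbind(matrix(0, 20, 10), matrix(1, 20, 10))
  expect_lt(min(esf_g(hard, 3, 1)), min(esf_g(soft, 3, 1)))
})

test_that("gac baseline: zero stopping freezes, constant stopping expands, bsf confines", {
  phi <- rd_regularize(init_level_set(
    list(seed_ellipse(c(16, 16), c(5, 5))), c(32, 32)))
  img <- matrix(0.5, 32, 32)
  expect_equal(gac_step(img, phi, matrix(0, 32, 32), v = -1), rd_regularize(phi))
  # expansion under constant outward speed
  p <- phi
  areas <- numeric(10)
  for (k in 1:10) {
    p <- gac_step(img, p, matrix(1, 32, 32), v = -1)
    areas[k] <- region_area(p)
  }
  expect_true(all(diff(c(region_area(phi), areas)) > 0))
  # confinement by a binary stopping mask
  mask <- make_lesion_mask(phantom_spec(height = 32, width = 32,
                                        lesions = list(list(center = c(16, 16),
                                                            radii = c(10, 8),
                                                            amplitude = 0,
                                                            rotation = 0)),
                                        noise_sigma = 0, seed = 1))
  p <- rd_regularize(init_level_set(list(seed_ellipse(c(16, 16), c(3, 3))),
                                    c(32, 32)))
  for (k in 1:40) p <- gac_step(img, p, mask, v = -1)
  expect_true(all(heaviside(p)[dilate_once(mask) == 0] == 0))
})

test_that("mode inference reads the converged field on the seed boundary", {
  seeds <- list(seed_rectangle(c(8, 8), c(2, 2)))
  expect_equal(infer_alpha(matrix(-1, 16, 16), seeds), -1)
  expect_equal(infer_alpha(matrix(1, 16, 16), seeds), 1)
  # split field with an exactly balanced boundary sum is ambiguous:
  # the 4x3 seed has 5 boundary pixels on each side of the row split
  phi <- rbind(matrix(-1, 8, 16), matrix(1, 8, 16))
  bal <- list(seed_rectangle(c(8.5, 8), c(1.5, 1.5)))
  expect_error(infer_alpha(phi, bal), "ambiguous")
})

test_that("with alpha = 0 and kappa = 1 the hybrid step is the simplified step", {
  set.seed(41)
  for (k in 1:10) {
    img <- matrix(runif(30 * 30), 30, 30)
    phi <- rd_regularize(matrix(sample(c(-1, 1), 900, replace = TRUE), 30, 30))
    st <- list(phi = phi, kappa = matrix(1, 30, 30), alpha = 0, iteration = 0L)
    a <- acbf_step(img, st, dt = 7)$phi
    b <- cv_step_simplified(img, phi, cv_params(dt = 7))
    expect_lt(max(abs(a - b)), 1e-12)
  }
})

test_that("in the local phase the region means cannot influence the update", {
  set.seed(42)
  phi <- rd_regularize(init_level_set(
    list(seed_ellipse(c(12, 12), c(4, 4))), c(24, 24)))
  kappa <- matrix(1, 24, 24)
  st <- list(phi = phi, kappa = kappa, alpha = -1, iteration = 0L)
  img1 <- matrix(runif(576), 24, 24)
  img2 <- matrix(runif(576), 24, 24)
  expect_identical(acbf_step(img1, st, dt = 1)$phi,
                   acbf_step(img2, st, dt = 1)$phi)
  # all-zero stopping region: the evolution force vanishes entirely
  st0 <- list(phi = phi, kappa = matrix(0, 24, 24), alpha = 1, iteration = 0L)
  expect_equal(acbf_step(img1, st0, dt = 1)$phi, rd_regularize(phi))
})

test_that("convergence criterion follows the error-length/error-area rules", {
  h <- data.frame(length = c(40, 40), area = c(100, 100))
  expect_true(check_convergence(h, list(theta = 0, stable_checks = 1)))
  h2 <- data.frame(length = c(40, 41, 42), area = c(100, 105, 110))
  expect_false(check_convergence(h2, list(theta = 0, stable_checks = 1)))
  h3 <- data.frame(length = c(40, 47, 50), area = c(100, 107, 110))
  expect_true(check_convergence(h3, list(theta = 10, stable_checks = 2)))
  expect_false(check_convergence(h3, list(theta = 5, stable_checks = 2)))
})

test_that("full pipeline recovers a noiseless lesion essentially exactly", {
  fx <- noiseless_phantom(side = 96, radii = c(18, 14), seed = 13,
                          amplitude = 2)
  fit <- acbf(fx$image, list(seed_ellipse(c(48, 48), c(8, 8))),
              acbf_control(use_bf = FALSE), truth = fx$truth)
  expect_true(fit$converged)
  expect_gte(fit$dice, 99)
  expect_equal(fit$mode, "expanding")
})

test_that("runs switch phase exactly once and end within tolerance", {
  spec <- phantom_spec(seed = 23)
  truth <- make_lesion_mask(spec)
  img <- render_phantom(truth, spec)
  fit <- acbf(img, list(seed_ellipse(c(64, 64), c(8, 8))), acbf_control())
  transitions <- sum(diff(fit$history$alpha) != 0)
  expect_equal(transitions, 1)
  expect_true(all(fit$history$alpha %in% c(0, fit$alpha)))
  last <- fit$history[nrow(fit$history), ]
  expect_lte(abs(last$error_length), fit$control$theta)
  expect_lte(abs(last$error_area), fit$control$theta)
  # no leakage past the stopping mask
  expect_true(all(fit$mask[dilate_once(fit$kappa) == 0] == 0))
})

test_that("seed placement selects expanding or shrinking local motion", {
  spec <- phantom_spec(seed = 31)
  truth <- make_lesion_mask(spec)
  img <- render_phantom(truth, spec)
  f_in <- acbf(img, list(seed_ellipse(c(64, 64), c(8, 8))), acbf_control())
  expect_equal(f_in$alpha, -1)
  local_in <- f_in$history[f_in$history$alpha == -1, ]
  expect_true(all(diff(local_in$area) >= 0))
  f_out <- acbf(img, list(seed_ellipse(c(64, 64), c(34, 34))), acbf_control())
  expect_equal(f_out$alpha, 1)
  local_out <- f_out$history[f_out$history$alpha == 1, ]
  expect_true(all(diff(local_out$area) <= 0))
  # both end on the lesion
  expect_gte(dice(f_in$mask, truth), 90)
  expect_gte(dice(f_out$mask, truth), 90)
})

test_that("control constructor validates its fields", {
  expect_error(acbf_control(dt = 0))
  expect_error(acbf_control(dt_local = -1))
  expect_error(acbf_control(check_interval = 0))
  expect_error(acbf_control(polarity = "sideways"))
  ctl <- acbf_control(sigma_s = 2)
  expect_equal(ctl$window_radius, 6L)
})
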