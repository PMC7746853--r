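test_that("unperturbed disc mask has the analytic area up to discretisation", {
  spec <- phantom_spec(height = 64, width = 64,
                       lesions = list(list(center = c(32, 32),
                                           radii = c(10, 10),
                                           amplitude = 0, rotation = 0)),
                       noise_sigma = 0, seed = 1)
  area <- sum(make_lesion_mask(spec))
  expect_gte(area, pi * 100 - 40)
  expect_lte(area, pi * 100 + 40)
})

test_that("two disjoint lesions give exactly two connected components", {
  spec <- phantom_spec(height = 96, width = 96,
                       lesions = list(list(center = c(30, 30), radii = c(10, 8),
                                           amplitude = 1, rotation = 0.3),
                                      list(center = c(68, 66), radii = c(9, 12),
                                           amplitude = 1, rotation = 1.1)),
                       seed = 2)
  mask <- make_lesion_mask(spec)
  expect_equal(count_components(mask), 2L)
  expect_true(all(mask %in% c(0, 1)))
})

test_that("identical (spec, seed) pairs are bit-identical; masks stay in frame", {
  spec <- phantom_spec(seed = 9)
  expect_identical(make_lesion_mask(spec), make_lesion_mask(spec))
  m <- make_lesion_mask(spec)
  img1 <- render_phantom(m, spec)
  img2 <- render_phantom(m, spec)
  expect_identical(img1, img2)
  expect_true(all(m[1, ] == 0) && all(m[nrow(m), ] == 0) &&
                all(m[, 1] == 0) && all(m[, ncol(m)] == 0))
})

test_that("zero-noise rendering is exactly the two-valued clean image", {
  fx <- noiseless_phantom(seed = 4)
  img <- fx$image
  expect_setequal(unique(as.vector(img)), c(0.25, 0.55))
  expect_identical(img == 0.25, fx$truth == 1)
})

test_that("per-region means of speckled phantoms are unbiased (MC oracle)", {
  spec0 <- phantom_spec(seed = 1)
  mask <- make_lesion_mask(spec0)
  means_in <- means_out <- numeric(25)
  for (k in 1:25) {
    spec <- phantom_spec(seed = 100 + k)
    g <- render_phantom(mask, spec)
    means_in[k] <- mean(g[mask == 1])
    means_out[k] <- mean(g[mask == 0])
  }
  expect_lt(abs(mean(means_in) - spec0$lesion_level),
            3 * sd(means_in) / sqrt(25) + 1e-3)
  expect_lt(abs(mean(means_out) - spec0$background),
            3 * sd(means_out) / sqrt(25) + 1e-3)
})

test_that("wider PSF lowers pixel noise variance and lengthens autocorrelation", {
  mask <- matrix(0, 64, 64) # flat background: pure noise statistics
  mask[30:34, 30:34] <- 1
  var_by_psf <- lag1_by_psf <- list()
  for (ps in c(1, 3)) {
    vs <- ac <- numeric(20)
    for (k in 1:20) {
      spec <- phantom_spec(height = 64, width = 64,
                           lesions = list(list(center = c(32, 32),
                                               radii = c(3, 3), amplitude = 0,
                                               rotation = 0)),
                           psf_sigma = ps, seed = 200 + k)
      g <- render_phantom(mask, spec)
      noise <- (g - ifelse(mask == 1, spec$lesion_level, spec$background))
      bg <- noise[10:25, 10:55] # away from the lesion and the frame
      vs[k] <- var(as.vector(bg))
      ac[k] <- cor(as.vector(bg[, -1]), as.vector(bg[, -ncol(bg)]))
    }
    var_by_psf[[as.character(ps)]] <- mean(vs)
    lag1_by_psf[[as.character(ps)]] <- mean(ac)
  }
  expect_lt(var_by_psf[["3"]], var_by_psf[["1"]])
  expect_gt(lag1_by_psf[["3"]], lag1_by_psf[["1"]])
})

test_that("geometry and parameter errors are rejected", {
  expect_error(phantom_spec(lesions = list(list(center = c(10, 64),
                                                radii = c(20, 16),
                                                amplitude = 0, rotation = 0))),
               "frame")
  expect_error(phantom_spec(lesions = list(list(center = c(64, 64),
                                                radii = c(8, 6),
                                                amplitude = 7, rotation = 0))),
               "amplitude")
  expect_error(phantom_spec(lesions = list(list(center = c(64, 64),
                                                radii = c(1, 6),
                                                amplitude = 0, rotation = 0))),
               "radii")
  expect_error(phantom_spec(noise_sigma = -0.1), "noise_sigma")
  expect_error(phantom_spec(background = 0.4, lesion_level = 0.4), "contrast")
})

test_that("make_dataset is reproducible, nonempty and inside the frame", {
  d1 <- make_dataset(1, seed = 5)
  expect_length(d1, 1)
  a <- make_dataset(12, seed = 7)
  b <- make_dataset(12, seed = 7)
  for (i in seq_along(a)) {
    expect_identical(a[[i]]$image, b[[i]]$image)
    expect_identical(a[[i]]$mask, b[[i]]$mask)
    m <- a[[i]]$mask
    expect_gt(sum(m), 0)
    expect_true(all(m[1, ] == 0) && all(m[nrow(m), ] == 0) &&
                  all(m[, 1] == 0) && all(m[, ncol(m)] == 0))
  }
})
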