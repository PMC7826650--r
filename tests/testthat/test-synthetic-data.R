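test_that("spec validation rejects degenerate variance structures", {
  expect_error(random_effects_spec(0, -1, 1, 10), "sigma_b")
  expect_error(random_effects_spec(0, 1, 0, 10), "sigma_w")
  expect_error(random_effects_spec(0, 1, 1, 1), "n_lesions")
  expect_equal(true_icc(random_effects_spec(0, sqrt(3), 1, 10)), 0.75)
})

test_that("near-zero within-lesion variance makes visits agree", {
  spec <- random_effects_spec(mu = 0, sigma_b = 1, sigma_w = 1e-9,
                              n_lesions = 10)
  m <- ft_matrix(simulate_feature_table(spec, seed = 1), "feature")
  expect_equal(m[, 1L], m[, 2L], tolerance = 1e-6)
})

test_that("large-sample tables recover the generative variance components", {
  spec <- random_effects_spec(mu = 10, sigma_b = sqrt(3), sigma_w = 1,
                              n_lesions = 5000)
  m <- ft_matrix(simulate_feature_table(spec, seed = 1), "feature")
  # Monte-Carlo SE of the ICC at n = 5000, k = 2 is about (1-rho^2)/sqrt(n/2)
  se_icc <- (1 - 0.75^2) * sqrt(2 / 5000)
  expect_lt(abs(icc_1_1(m)$icc - 0.75), 3 * se_icc)
  # within/between components from the ANOVA mean squares
  msw <- sum((m - rowMeans(m))^2) / nrow(m)
  msb <- 2 * sum((rowMeans(m) - mean(m))^2) / (nrow(m) - 1)
  sigma_b2 <- (msb - msw) / 2
  expect_lt(abs(msw - 1), 3 * sqrt(2 / 5000))          # var of chi2 mean
  expect_lt(abs(sigma_b2 - 3), 3 * 3 * sqrt(2 / 5000) * 2)
})

test_that("generation is bit-reproducible given the seed", {
  spec <- random_effects_spec(10, 1, 0.5, 50)
  expect_identical(simulate_feature_table(spec, seed = 7),
                   simulate_feature_table(spec, seed = 7))
  expect_false(identical(simulate_feature_table(spec, seed = 7),
                         simulate_feature_table(spec, seed = 8)))
})

test_that("lambda_skew = 0 yields log-normal values that a log restores", {
  spec <- random_effects_spec(mu = 1, sigma_b = 0.8, sigma_w = 0.4,
                              n_lesions = 134, lambda_skew = 0)
  # distributional round trip: the forward transform at the generative lambda
  # passes a Gaussianity test in at least the expected fraction of replicates
  p_raw <- p_log <- numeric(20L)
  for (r in seq_len(20L)) {
    ft <- simulate_feature_table(spec, seed = r)
    expect_true(all(ft$value > 0))
    p_raw[r] <- shapiro.test(ft$value)$p.value
    p_log[r] <- shapiro.test(log(ft$value))$p.value
  }
  expect_gte(mean(p_log > 0.05), 0.9)   # null holds after the forward map
  expect_lte(mean(p_raw > 0.05), 0.35)  # skew is actually induced
})

test_that("inverse/forward Box-Cox round trip is the identity on tables", {
  # Gaussian scale kept inside the invertibility domain of every lambda
  # (lambda*y + 1 > 0 requires y < 1 at lambda = -1, y > -0.5 at lambda = 2)
  for (lam in c(-1, 0, 0.5, 1, 2)) {
    spec <- random_effects_spec(mu = 0.2, sigma_b = 0.05, sigma_w = 0.03,
                                n_lesions = 40, lambda_skew = lam)
    ft <- simulate_feature_table(spec, seed = 3)
    restored <- boxcox_transform(ft$value, lam)
    spec_g <- random_effects_spec(mu = 0.2, sigma_b = 0.05, sigma_w = 0.03,
                                  n_lesions = 40)
    expect_equal(restored, simulate_feature_table(spec_g, seed = 3)$value,
                 tolerance = 1e-10)
  }
})

test_that("non-invertible skew maps are rejected, naming lambda and range", {
  # lambda = 2 with mu = 0: lambda*y + 1 <= 0 happens for y <= -0.5
  spec <- random_effects_spec(mu = 0, sigma_b = 1, sigma_w = 1,
                              n_lesions = 200, lambda_skew = 2)
  expect_error(simulate_feature_table(spec, seed = 1), "lambda = 2")
})

test_that("multi-feature tables draw independent streams per feature", {
  specs <- list(random_effects_spec(0, 1, 1, 100, feature = "a"),
                random_effects_spec(0, 1, 1, 100, feature = "b"))
  ft <- simulate_feature_table(specs, seed = 1)
  wide <- ft_widen(ft)
  expect_lt(abs(cor(wide$a, wide$b)), 0.3)
})

test_that("phantom volumes follow the noiseless forward model exactly", {
  spec <- phantom_spec(grid_shape = c(5L, 5L, 5L), noise_sd = 0,
                       lesion_geometry = list(centre = c(3, 3, 3),
                                              semiaxes = c(1.2, 1.2, 1.2)))
  ph <- simulate_vfa_phantom(spec)
  for (i in seq_along(spec$flip_angles)) {
    expected <- spgr_signal(spec$m0, ph$t1, spec$flip_angles[i], spec$tr)
    expect_equal(ph$series$volumes[[i]], expected)
  }
  # single-voxel check against the hand-evaluated equation, T1 = 800 ms
  e <- exp(-4 / 800)
  for (a in c(2, 10, 20)) {
    ar <- a * pi / 180
    expect_equal(spgr_signal(1000, 800, a, 4),
                 1000 * sin(ar) * (1 - e) / (1 - e * cos(ar)))
  }
})

test_that("ellipsoid mask equals the exhaustive voxel-scan rasterisation", {
  ctr <- c(16.5, 16.5, 16.5)
  ax <- c(4, 4, 2)
  m <- ellipsoid_mask(c(32L, 32L, 32L), ctr, ax)
  oracle <- array(0L, dim = c(32L, 32L, 32L))
  for (i in 1:32) for (j in 1:32) for (k in 1:32) {
    oracle[i, j, k] <- (sum(((c(i, j, k) - ctr) / ax)^2) <= 1) * 1L
  }
  expect_identical(m, oracle)
  expect_identical(sum(m), sum(oracle))
})

test_that("phantom noise is reproducible and spec violations are caught", {
  spec <- phantom_spec(grid_shape = c(6L, 6L, 6L), noise_sd = 2,
                       lesion_geometry = list(centre = c(3.5, 3.5, 3.5),
                                              semiaxes = c(1.5, 1.5, 1.5)))
  expect_identical(simulate_vfa_phantom(spec), simulate_vfa_phantom(spec))
  expect_error(phantom_spec(flip_angles = numeric(0)), "flip angle")
  expect_error(phantom_spec(flip_angles = c(0, 10)), "flip angle")
  expect_error(phantom_spec(grid_shape = c(8L, 8L, 8L)), "fit inside")
})
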