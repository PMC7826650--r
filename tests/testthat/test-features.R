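test_that("voxel volume is an exact count and mesh tracks analytic solids", {
  cube <- array(0L, c(14L, 14L, 14L))
  cube[3:12, 3:12, 3:12] <- 1L
  sf <- shape_features(cube, c(1, 1, 1))
  expect_equal(unname(sf["shape_voxel_volume"]), 1000)
  expect_equal(unname(sf["shape_mesh_volume"]), 1000, tolerance = 0.06)

  ball <- ellipsoid_mask(c(21L, 21L, 21L), c(11, 11, 11), c(8, 8, 8))
  sb <- shape_features(ball, c(1, 1, 1))
  expect_equal(unname(sb["shape_mesh_volume"]), 4 / 3 * pi * 8^3,
               tolerance = 0.05)
  expect_equal(unname(sb["shape_surface_area"]), 4 * pi * 8^2,
               tolerance = 0.05)
  expect_gte(unname(sb["shape_sphericity"]), 0.95)
  expect_lte(unname(sb["shape_sphericity"]), 1.0)
})

test_that("elongation and major axis follow the PCA of the voxel cloud", {
  el <- ellipsoid_mask(c(21L, 13L, 13L), c(11, 7, 7), c(8, 4, 4))
  sf <- shape_features(el, c(1, 1, 1))
  expect_equal(unname(sf["shape_elongation"]), 0.5, tolerance = 0.05)
  # oracle: PCA of the same analytic rasterisation, done directly
  coords <- arrayInd(which(el == 1L), dim(el))
  ev <- sort(eigen(cov(coords))$values, decreasing = TRUE)
  expect_equal(unname(sf["shape_major_axis_length"]), 4 * sqrt(ev[1L]),
               tolerance = 1e-8)
  expect_equal(unname(sf["shape_elongation"]), sqrt(ev[2L] / ev[1L]),
               tolerance = 1e-8)
})

test_that("single-voxel masks flag mesh features undefined", {
  m <- array(0L, c(3L, 3L, 3L))
  m[2L, 2L, 2L] <- 1L
  sf <- shape_features(m, c(2, 2, 2))
  expect_equal(unname(sf["shape_voxel_volume"]), 8)
  expect_true(is.na(sf["shape_mesh_volume"]))
  expect_true(is.na(sf["shape_sphericity"]))
})

test_that("shape features ignore image intensities entirely", {
  mask <- ellipsoid_mask(c(12L, 12L, 12L), c(6.5, 6.5, 6.5), c(3, 3, 2))
  set.seed(4)
  img <- array(rnorm(12^3, 100, 20), c(12L, 12L, 12L))
  f_raw <- extract_features(img, mask, bin_width = 5)
  f_norm <- extract_features(img, mask, bin_width = 5, normalise = TRUE)
  shape_cols <- grep("^shape_", names(f_raw), value = TRUE)
  expect_identical(f_raw[shape_cols], f_norm[shape_cols])
})

test_that("first-order features match hand values and brute-force formulas", {
  f <- first_order_features(c(1, 2, 3), voxel_volume = 2)
  expect_equal(unname(f["firstorder_mean"]), 2)
  expect_equal(unname(f["firstorder_energy"]), 14)
  expect_equal(unname(f["firstorder_total_energy"]), 28)
  expect_equal(unname(f["firstorder_skewness"]), 0)  # symmetric sample

  set.seed(5)
  x <- rnorm(64, 10, 3)
  g <- first_order_features(x, voxel_volume = 1.5)
  m2 <- mean((x - mean(x))^2)
  expect_equal(unname(g["firstorder_variance"]), m2)
  expect_equal(unname(g["firstorder_skewness"]),
               mean((x - mean(x))^3) / m2^1.5)
  expect_equal(unname(g["firstorder_rms"]), sqrt(mean(x^2)))
  expect_equal(unname(g["firstorder_total_energy"]), sum(x^2) * 1.5)
})

test_that("skewness is flagged undefined below three voxels", {
  f <- first_order_features(c(1, 2))
  expect_true(is.na(f["firstorder_skewness"]))
  expect_equal(unname(f["firstorder_mean"]), 1.5)
})

test_that("the 1x1x3 hand-enumerated GLCM is reproduced", {
  lev <- array(c(1L, 1L, 2L), c(1L, 1L, 3L))
  tm <- texture_matrices(lev, 2L)
  k <- which(apply(tm$directions, 1L, function(d) all(d == c(0L, 0L, 1L))))
  expect_equal(tm$glcm[[k]], rbind(c(2, 1), c(1, 0)))
})

test_that("a uniform ROI forms one zone covering the whole ROI", {
  lev <- array(1L, c(3L, 4L, 2L))
  tm <- texture_matrices(lev, 1L)
  expect_equal(sum(tm$glszm), 1)
  expect_equal(which(tm$glszm[1L, ] > 0), 24L)
})

test_that("all texture matrices equal exhaustive brute-force enumeration", {
  for (seed in 1:4) {
    dims <- list(c(4L, 4L, 4L), c(5L, 4L, 3L), c(3L, 5L, 5L), c(5L, 5L, 5L))[[seed]]
    lev <- gen_roi(dims, n_levels = 3L, p_mask = 0.75, seed = seed)
    tm <- texture_matrices(lev, 3L)
    for (k in seq_len(nrow(dirs13))) {
      kk <- which(apply(tm$directions, 1L, function(d) all(d == dirs13[k, ])))
      expect_length(kk, 1L)
      expect_equal(tm$glcm[[kk]], bf_glcm(lev, 3L, dirs13[k, ]),
                   info = sprintf("glcm seed %d dir %d", seed, k))
      oracle_rl <- bf_glrlm(lev, 3L, dirs13[k, ])
      got <- tm$glrlm[[kk]]
      expect_equal(got[, seq_len(ncol(oracle_rl)), drop = FALSE], oracle_rl,
                   info = sprintf("glrlm seed %d dir %d", seed, k))
      if (ncol(got) > ncol(oracle_rl)) {
        expect_true(all(got[, -seq_len(ncol(oracle_rl))] == 0))
      }
    }
    oz <- bf_glszm(lev, 3L)
    expect_equal(tm$glszm[, seq_len(ncol(oz)), drop = FALSE], oz,
                 info = paste("glszm seed", seed))
    expect_equal(tm$gldm, bf_gldm(lev, 3L), info = paste("gldm seed", seed))
    on <- bf_ngtdm(lev, 3L)
    expect_equal(tm$ngtdm$s, on$s, info = paste("ngtdm s seed", seed))
    expect_equal(tm$ngtdm$n, on$n)
    expect_equal(tm$ngtdm$n_vp, on$n_vp)
  }
})

test_that("texture features equal direct evaluation of their formulas", {
  lev <- gen_roi(c(4L, 4L, 4L), n_levels = 3L, p_mask = 0.8, seed = 9L)
  tm <- texture_matrices(lev, 3L)
  feats <- texture_features(tm)

  idm_dirs <- vapply(tm$glcm, function(m) {
    p <- m / sum(m)
    sum(p / (1 + (row(p) - col(p))^2))
  }, numeric(1L))
  expect_equal(unname(feats["glcm_idm"]), mean(idm_dirs))

  cs_dirs <- vapply(tm$glcm, function(m) {
    p <- m / sum(m)
    i <- row(p); j <- col(p)
    sum((i + j - sum(i * p) - sum(j * p))^3 * p)
  }, numeric(1L))
  expect_equal(unname(feats["glcm_cluster_shade"]), mean(cs_dirs))

  gln_dirs <- vapply(tm$glrlm, function(m) sum(rowSums(m)^2) / sum(m),
                     numeric(1L))
  expect_equal(unname(feats["glrlm_gln"]), mean(gln_dirs))
  rln_dirs <- vapply(tm$glrlm, function(m) sum(colSums(m)^2) / sum(m),
                     numeric(1L))
  expect_equal(unname(feats["glrlm_rln"]), mean(rln_dirs))

  z <- tm$glszm
  nz <- sum(z)
  expect_equal(unname(feats["glszm_sae"]), sum(z / col(z)^2) / nz)
  expect_equal(unname(feats["glszm_szn"]), sum(colSums(z)^2) / nz)
  expect_equal(unname(feats["glszm_sznn"]), sum(colSums(z)^2) / nz^2)
  expect_equal(unname(feats["glszm_gln"]), sum(rowSums(z)^2) / nz)
  expect_equal(unname(feats["glszm_lalgle"]),
               sum(z * col(z)^2 / row(z)^2) / nz)

  dm <- tm$gldm
  expect_equal(unname(feats["gldm_dn"]), sum(colSums(dm)^2) / sum(dm))
  expect_equal(unname(feats["gldm_gln"]), sum(rowSums(dm)^2) / sum(dm))

  ng <- tm$ngtdm
  expect_equal(unname(feats["ngtdm_coarseness"]), 1 / sum(ng$p * ng$s))
})

test_that("degenerate texture limits behave as documented", {
  # one grey level everywhere: all co-occurrence mass at zero difference
  lev <- array(1L, c(2L, 2L, 2L))
  tm <- texture_matrices(lev, 1L)
  feats <- texture_features(tm)
  expect_equal(unname(feats["glcm_idm"]), 1)
  # homogeneous ROI: all s_i = 0, coarseness capped
  expect_equal(unname(feats["ngtdm_coarseness"]), 1e6)
  expect_error(texture_matrices(lev, 0L), "n_levels")
})

test_that("grey-level features survive affine intensity changes after
           normalisation and discretisation", {
  mask <- ellipsoid_mask(c(10L, 10L, 10L), c(5.5, 5.5, 5.5), c(3, 3, 3))
  set.seed(10)
  img <- array(rnorm(1000, 60, 15), c(10L, 10L, 10L))
  f1 <- extract_features(img, mask, normalise = TRUE)
  f2 <- extract_features(2.2 * img - 31, mask, normalise = TRUE)
  texture_cols <- grep("^(glcm|glrlm|glszm|gldm|ngtdm)_", names(f1),
                       value = TRUE)
  expect_equal(f1[texture_cols], f2[texture_cols], tolerance = 1e-9)
})

test_that("energy, non-uniformity and coarseness features track lesion
           volume (volume confounding)", {
  set.seed(12)
  radii <- c(2.2, 3.2, 4.2, 5.2)
  vals <- sapply(radii, function(r) {
    n <- ceiling(2 * r) + 5L
    mask <- ellipsoid_mask(rep(n, 3L), rep((n + 1) / 2, 3L), rep(r, 3L))
    img <- array(rnorm(n^3, 50, 10), rep(n, 3L))
    f <- extract_features(img, mask)
    c(f["firstorder_energy"], f["firstorder_total_energy"],
      f["glrlm_gln"], f["glszm_gln"], f["gldm_dn"], f["ngtdm_coarseness"],
      n_vox = sum(mask))
  })
  for (r in seq_len(nrow(vals) - 1L)) {
    expect_gt(abs(cor(vals[r, ], vals["n_vox", ], method = "spearman")), 0.9)
  }
})
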