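test_that("the Shapiro-Wilk gate uses the Bonferroni threshold exactly", {
  set.seed(1)
  g <- gaussian_gate(rnorm(268), alpha = 0.05, n_features = 105L)
  expect_equal(g$threshold, 0.05 / 105)
  expect_true(g$pass)
  # boundary behaviour: pass iff p >= threshold
  expect_identical(g$pass, g$p >= 0.05 / 105)
})

test_that("the gate keeps Gaussian data and rejects log-normal data at the
           expected rates", {
  set.seed(2)
  keep <- replicate(60, gaussian_gate(rnorm(268))$pass)
  expect_gte(mean(keep), 1 - 0.05 / 105 - 3 * sqrt(0.0005 / 60) - 0.05)
  reject <- replicate(60, !gaussian_gate(exp(rnorm(268)))$pass)
  expect_gte(mean(reject), 0.95)
})

test_that("constant input fails the gate with a degenerate flag", {
  g <- gaussian_gate(rep(1, 10))
  expect_false(g$pass)
  expect_true(g$degenerate)
  expect_true(is.na(g$p))
})

test_that("the Box-Cox transform obeys its fixed points and limits", {
  for (lam in c(-2, -0.5, 0, 0.5, 1, 3)) {
    expect_equal(boxcox_transform(1, lam), 0)
  }
  x <- c(0.5, 1.7, 4)
  expect_equal(boxcox_transform(x, 1), x - 1)
  expect_equal(boxcox_transform(x, 0), log(x))
  # continuity at lambda -> 0
  expect_equal(boxcox_transform(c(0.5, 2), 1e-8),
               boxcox_transform(c(0.5, 2), 0), tolerance = 1e-6)
  expect_error(boxcox_transform(c(-1, 2), 1), "positive")
})

test_that("forward and inverse transforms are mutual inverses", {
  x <- c(0.2, 1, 3.7, 10)
  for (lam in c(-1, 0, 0.5, 1, 2)) {
    expect_equal(boxcox_inverse(boxcox_transform(x, lam), lam), x,
                 tolerance = 1e-10)
  }
  expect_error(boxcox_inverse(c(-3, 0), 1), "lambda = 1")
})

test_that("Box-Cox is strictly increasing, preserving ranks", {
  set.seed(3)
  x <- exp(rnorm(50))
  y <- sort(x)
  for (lam in c(-1.5, 0, 0.7, 2)) {
    expect_true(all(diff(boxcox_transform(y, lam)) > 0))
    expect_equal(cor(x, boxcox_transform(x, lam), method = "spearman"), 1)
  }
})

test_that("optimal lambda recovers generative transforms", {
  set.seed(4)
  lam_ln <- replicate(5, boxcox_lambda(exp(rnorm(268))))
  expect_true(all(abs(lam_ln) < 0.25))
  # identity truth: weakly identified at modest n, so judge the replicate mean
  lam_id <- replicate(10, boxcox_lambda(rnorm(268, 10, 1)))
  expect_lt(abs(mean(lam_id) - 1), 0.75)
  # squared shifted-Gaussian truth: sqrt restores Gaussianity
  lam_sq <- replicate(10, boxcox_lambda(rnorm(268, 5, 1)^2))
  expect_lt(abs(mean(lam_sq) - 0.5), 0.25)
})

test_that("the PPCC and profile-likelihood criteria agree on clean data", {
  set.seed(5)
  x <- exp(rnorm(500))
  expect_lt(abs(boxcox_lambda(x, "ppcc") - boxcox_lambda(x, "mle")), 0.2)
  expect_error(boxcox_lambda(c(1, -2, 3)), "positive")
  expect_error(boxcox_lambda(rep(2, 10)), "constant")
})

test_that("an all-Gaussian table is classified entirely pre-Box-Cox", {
  specs <- lapply(1:6, function(i)
    random_effects_spec(10, 1, 0.5, 134, feature = sprintf("f%02d", i)))
  ft <- simulate_feature_table(specs, seed = 6)
  cls <- classify_features(ft, n_features = 105L)
  expect_equal(unname(cls$counts), c(6L, 0L, 0L))
  expect_identical(cls$table$value, ft$value)  # untouched
})

test_that("features skewed at generation are transformed back to Gaussian", {
  specs <- c(
    lapply(1:5, function(i)
      random_effects_spec(2, 0.6, 0.3, 134, lambda_skew = 0,
                          feature = sprintf("skew%02d", i))),
    lapply(1:5, function(i)
      random_effects_spec(10, 1, 0.5, 134, feature = sprintf("gauss%02d", i))))
  ft <- simulate_feature_table(specs, seed = 7)
  cls <- classify_features(ft, n_features = 105L)
  skew_rows <- cls$records[grepl("^skew", cls$records$feature), ]
  gauss_rows <- cls$records[grepl("^gauss", cls$records$feature), ]
  # the Gaussian half passes upfront; the skewed half needs the transform
  expect_gte(sum(gauss_rows$status == "gaussian_pre"), 4L)
  expect_gte(sum(skew_rows$status == "gaussian_post"), 4L)
  # fitted lambdas sit near the generative lambda = 0
  expect_true(all(abs(skew_rows$lambda[skew_rows$status == "gaussian_post"])
                  < 0.4))
  # transformed values replace originals for transformed features only
  wide_in <- ft_widen(ft)
  wide_out <- ft_widen(cls$table)
  expect_identical(wide_out$gauss01, wide_in$gauss01)
  expect_false(identical(wide_out$skew01, wide_in$skew01))
})

test_that("non-positive features are shifted before transformation and the
           shift is recorded", {
  set.seed(8)
  vals <- exp(rnorm(268)) - 2  # skewed with negative values
  ft <- feature_table(data.frame(
    lesion_id = rep(sprintf("L%03d", 1:134), 2L),
    visit = rep(1:2, each = 134L), feature = "neg_skew", value = vals))
  cls <- classify_features(ft, n_features = 105L)
  rec <- cls$records[1L, ]
  expect_false(rec$status == "gaussian_pre")
  expect_gt(rec$shift, -min(vals))
  expect_true(is.finite(rec$lambda))
})
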