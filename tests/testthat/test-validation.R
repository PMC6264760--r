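test_that("LOO equals a hand-rolled fold loop on a 6-compound toy set", {
  set.seed(3)
  X <- matrix(rnorm(12), 6, 2,
              dimnames = list(paste0("c", 1:6), c("a", "b")))
  y <- 1 + X[, "a"] - 0.5 * X[, "b"] + rnorm(6, 0, 0.4)
  ds <- dataset_from_xy(X, y)
  rep_ <- loo_cv(ds, c("a", "b"))

  pred <- vapply(1:6, function(i) {
    f <- lm(y[-i] ~ X[-i, "a"] + X[-i, "b"])
    sum(coef(f) * c(1, X[i, "a"], X[i, "b"]))
  }, numeric(1))
  press <- sum((y - pred)^2)
  expect_equal(rep_$q2_loo, 1 - press / sum((y - mean(y))^2), tolerance = 1e-10)
  expect_equal(rep_$per_compound$predicted, pred, tolerance = 1e-10)
  expect_equal(rep_$sd_cv, sqrt(press / (6 - 2 - 1)), tolerance = 1e-10)
  # every training compound appears exactly once
  expect_identical(rep_$per_compound$compound_id, paste0("c", 1:6))
})

test_that("LOO is exact on noiseless data and degrades under permutation", {
  x <- seq(-3, 3, length.out = 9)
  ds <- dataset_from_xy(matrix(x, ncol = 1), 2 * x - 1)
  expect_equal(loo_cv(ds, "x01")$q2_loo, 1, tolerance = 1e-9)

  set.seed(8)
  n <- 20
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(paste0("c", 1:n), c("a", "b")))
  y <- X[, "a"] + rnorm(n, 0, 0.3)
  q2_perm <- vapply(1:50, function(i) {
    loo_cv(dataset_from_xy(X, sample(y)), c("a", "b"))$q2_loo
  }, numeric(1))
  expect_lt(median(q2_perm), 0)          # permutation null predicts nothing
})

test_that("PRESS dominates RSS and Q2 never exceeds training R2", {
  for (s in 1:100) {
    set.seed(s)
    n <- 12
    X <- matrix(rnorm(n * 2), n, 2, dimnames = list(paste0("c", 1:n), c("a", "b")))
    y <- 0.8 * X[, "a"] + rnorm(n)
    ds <- dataset_from_xy(X, y)
    m <- fit_ols(ds, c("a", "b"))
    v <- loo_cv(ds, c("a", "b"))
    rss <- sum(residuals(m)^2)
    expect_gte(v$press, rss - 1e-10)
    expect_lte(v$q2_loo, m$r2 + 1e-10)
  }
})

test_that("Q2 is invariant under affine rescaling of the response", {
  set.seed(14)
  ds <- toy_dataset(n = 15, D = 4, d_true = 2, noise = 0.5, seed = 14)
  q2 <- loo_cv(ds, c("x01", "x02"))$q2_loo
  y2 <- -2.5 * ds$activities$pec50 + 7
  ds2 <- dataset_from_xy(ds$descriptors, y2)
  expect_equal(loo_cv(ds2, c("x01", "x02"))$q2_loo, q2, tolerance = 1e-10)
})

test_that("a singular LOO fold names the left-out compound", {
  n <- 7
  X <- cbind(ind = c(1, rep(0, n - 1)), z = rnorm(n))
  rownames(X) <- paste0("c", 1:n)
  ds <- dataset_from_xy(X, rnorm(n))
  # leaving out c1 makes `ind` constant in the fold
  expect_error(loo_cv(ds, c("ind", "z")), "c1",
               class = "ermqsar_singular_fit")
})

test_that("test-set R2 is the squared Pearson correlation with its invariances", {
  set.seed(16)
  ds <- toy_dataset(n = 20, D = 4, d_true = 2, noise = 0.4, seed = 16)
  m <- fit_ols(ds, c("x01", "x02"))
  Xte <- matrix(rnorm(10 * 4), 10, 4,
                dimnames = list(paste0("t", 1:10), colnames(ds$descriptors)))
  pred <- predict(m, Xte)

  expect_equal(test_set_r2(m, Xte, pred), 1)              # perfect agreement
  expect_equal(test_set_r2(m, Xte, pred + 3), 1)          # shift-invariant
  obs <- pred + rnorm(10, 0, 0.5)
  expect_equal(test_set_r2(m, Xte, obs), cor(obs, pred)^2, tolerance = 1e-10)
  expect_equal(test_set_r2(m, Xte, -2 * obs + 1),
               test_set_r2(m, Xte, obs), tolerance = 1e-10)  # affine-invariant

  expect_error(test_set_r2(m, Xte, rep(1, 10)),
               class = "ermqsar_undefined_correlation")
  expect_error(test_set_r2(m, Xte[1:2, ], obs[1:2]),
               class = "ermqsar_domain_error")

  # five-point hand check: predictions are affine in the descriptor, so the
  # squared correlation with the observations is the hand-computed Pearson^2
  # between descriptor and observations
  x5 <- c(1, 2, 3, 4, 5); o5 <- c(1.2, 1.9, 3.3, 3.8, 5.1)
  r_hand <- (sum(x5 * o5) - 5 * mean(x5) * mean(o5)) /
    (sqrt(sum(x5^2) - 5 * mean(x5)^2) * sqrt(sum(o5^2) - 5 * mean(o5)^2))
  m1 <- fit_ols(dataset_from_xy(matrix(x5, ncol = 1), o5), "x01")
  expect_equal(test_set_r2(m1, matrix(x5, ncol = 1,
                                      dimnames = list(NULL, "x01")), o5),
               r_hand^2, tolerance = 1e-10)

  # predictive form scores the shifted predictor strictly worse
  expect_lt(test_set_r2(m, Xte, obs + 5, predictive = TRUE),
            test_set_r2(m, Xte, obs, predictive = TRUE))
})

test_that("the subset-size cap is strictly below the training fraction", {
  expect_identical(max_subset_size(26), 5L)
  expect_identical(max_subset_size(25), 4L)   # exact multiple rounds down
  expect_identical(max_subset_size(10), 1L)
  expect_error(max_subset_size(5), class = "ermqsar_domain_error")
  expect_error(max_subset_size(4), class = "ermqsar_domain_error")
  expect_error(max_subset_size(26, fraction = 1.2), class = "ermqsar_config_error")
})

test_that("the full validation report covers both splits", {
  g <- generate_pool(synthetic_spec(
    n_compounds = 30, pool_size = 10, true_subset_size = 2,
    true_coefficients = c(1, -1), noise_sd = 0.3, test_fraction = 0.3,
    seed = 27))
  rep_ <- validation_report(g$dataset, g$truth$true_subset)
  expect_s3_class(rep_$model, "qsar_lm")
  expect_true(is.numeric(rep_$r2_test))
  expect_equal(nrow(rep_$predictions), 30)
  expect_setequal(unique(rep_$predictions$split), c("train", "test"))
  expect_gt(rep_$q2_loo, 0.5)
})
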