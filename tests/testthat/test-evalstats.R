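test_that("error statistics match hand-evaluated cases", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(1, 1)), 1)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 5)), sqrt(4 / 3))
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 5)), -1)
  expect_equal(mape(c(1, 2), c(2, 3)), 75)
  expect_equal(fge(c(1, 2), c(2, 3)), 0.75)
  expect_equal(pi_coverage(c(1, 2, 3, 4), c(0.5, 2.5, 2.5, 4), c(1.5, 3, 2.8, 4)), 0.5)
  expect_equal(pi_coverage(1:3, c(1, 2, 3), c(1, 2, 3)), 1)  # closed bounds
})

test_that("error statistics refuse degenerate input loudly", {
  expect_error(rmse(1:3, 1:2), "mismatch")
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(mape(c(0, 1), c(1, 1)), "division")
  expect_error(fge(c(0, 1), c(1, 1)), "division")
  expect_error(pi_coverage(1:3, c(2, 1, 1), c(1, 2, 3)), "crossed")
})

test_that("the percentage and fractional errors are proportional by construction", {
  set.seed(4)
  for (i in 1:20) {
    y <- runif(30, 0.05, 3)
    yhat <- y * exp(rnorm(30, 0, 0.3))
    expect_equal(mape(y, yhat), 100 * fge(y, yhat), tolerance = 1e-12)
  }
})

test_that("r_squared is invariant under common positive affine rescaling", {
  set.seed(5)
  y <- runif(25, 0.1, 3); yhat <- y + rnorm(25, 0, 0.2)
  expect_equal(r_squared(2.5 * y + 1, 2.5 * yhat + 1), r_squared(y, yhat),
               tolerance = 1e-12)
})

test_that("k-fold assignment partitions indices with near-equal sizes", {
  f <- kfold_indices(110, 5, seed = 1)
  expect_equal(unname(table(f)), rep(22L, 5), ignore_attr = TRUE)
  f2 <- kfold_indices(7, 3, seed = 1)
  expect_equal(sort(unname(table(f2)), decreasing = TRUE), c(3L, 2L, 2L),
               ignore_attr = TRUE)
  expect_equal(length(f2), 7)
  expect_true(all(f2 %in% 1:3))
  expect_identical(kfold_indices(50, 5, seed = 9), kfold_indices(50, 5, seed = 9))
  expect_error(kfold_indices(4, 5), "at least")
  expect_error(kfold_indices(10, 1), "k >= 2")
})

test_that("cross-validation explains the noiseless fixture", {
  ds <- std_fixture(noise_cv = 0)
  cv <- cross_validate("gb", ds, k = 5, seed = 3)
  expect_equal(nrow(cv$folds), 5)
  expect_gte(cv$mean[["r_squared"]], 0.95)
  cv2 <- cross_validate("gb", ds, k = 5, seed = 3)
  expect_identical(cv$folds, cv2$folds)
})

test_that("leave-one-out runs at the fold-count boundary", {
  ds <- solubility_dataset(std_fixture()[1:10, ])
  cv <- cross_validate(learner_config("gb", n_estimators = 20), ds,
                       k = 10, seed = 1)
  expect_equal(nrow(cv$folds), 10)
  expect_true(all(cv$folds$n == 1))
})

test_that("rank test reproduces the hand-worked two-group example", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$h, 12 / 42 * (12 + 75) - 21, tolerance = 1e-10)
  expect_equal(kw$h, 3.857, tolerance = 1e-3)
  # identical group multisets carry no signal
  kw0 <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(kw0$h, 0, tolerance = 1e-12)
  # degenerate all-equal values
  kwd <- kruskal_wallis(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kwd$h, 0)
  expect_true(kwd$degenerate)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
})

test_that("rank test matches a brute-force oracle including ties", {
  set.seed(6)
  for (i in 1:30) {
    n <- sample(6:12, 1)
    values <- sample(1:5, n, replace = TRUE)   # heavy ties
    groups <- sample(letters[1:3], n, replace = TRUE)
    if (length(unique(groups)) < 2 || length(unique(values)) == 1) next
    expect_equal(kruskal_wallis(values, groups)$h, oracle_kw(values, groups),
                 tolerance = 1e-10)
  }
})

test_that("rank statistic is invariant under monotone transforms", {
  set.seed(7)
  values <- runif(20, 0.1, 3)
  groups <- rep(c("a", "b", "c", "d"), each = 5)
  h1 <- kruskal_wallis(values, groups)$h
  expect_equal(kruskal_wallis(log(values), groups)$h, h1, tolerance = 1e-12)
  expect_equal(kruskal_wallis(values^3, groups)$h, h1, tolerance = 1e-12)
})

test_that("feature screening reports one row per feature", {
  scr <- feature_screening(std_fixture())
  expect_equal(scr$feature, c("temperature", "pressure", "molecular_weight",
                              "melting_point"))
  expect_true(all(scr$h >= 0))
  expect_true(all(scr$p_value >= 0 & scr$p_value <= 1))
})

test_that("local attribution recovers linear structure", {
  bg <- std_fixture()
  rec <- bg[15, ]
  # constant model: all scores vanish
  att0 <- local_attribution(function(ds) rep(1.5, nrow(ds)), rec, bg, seed = 1)
  expect_true(all(abs(att0$scores) < 1e-6))
  # model that only sees pressure: score = slope x sd(P), others ~ 0
  att1 <- local_attribution(function(ds) 2 * ds$pressure, rec, bg, seed = 1)
  sdP <- ghef:::pop_sd(bg$pressure)
  expect_equal(unname(att1$scores["pressure"]), 2 * sdP, tolerance = 0.05 * 2 * sdP)
  expect_true(all(abs(att1$scores[c("temperature")]) < 0.05 * 2 * sdP))
  # full linear model: scores proportional to coefficients
  att2 <- local_attribution(function(ds) {
    0.02 * ds$temperature + 0.05 * ds$pressure - 0.001 * ds$molecular_weight
  }, rec, bg, n_samples = 4000, seed = 2)
  expect_equal(unname(att2$scores["temperature"]),
               0.02 * ghef:::pop_sd(bg$temperature), tolerance = 0.02 * 0.02 * 11.2)
  expect_equal(unname(att2$scores["pressure"]), 0.05 * sdP,
               tolerance = 0.02 * 0.05 * sdP)
})

test_that("attribution recovers additive slope signs across seeds", {
  bg <- std_fixture()
  rec <- bg[40, ]
  model <- function(ds) 0.03 * ds$pressure - 0.0005 * ds$molecular_weight
  signs <- vapply(1:50, function(seed) {
    a <- local_attribution(model, rec, bg, n_samples = 400, seed = seed)$scores
    a["pressure"] > 0 && a["molecular_weight"] < 0
  }, logical(1))
  expect_true(all(signs))
})

test_that("zero-variance background features are flagged with zero score", {
  bg <- std_fixture()
  bg_one <- solubility_dataset(bg[bg$compound == "Rifampin", ])
  att <- local_attribution(function(ds) 2 * ds$pressure, bg_one[3, ], bg_one,
                           seed = 1)
  expect_true(att$zero_variance[["molecular_weight"]])
  expect_equal(unname(att$scores["molecular_weight"]), 0)
})
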