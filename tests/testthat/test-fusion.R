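test_that("weight fitting recovers an exactly correct member", {
  set.seed(1)
  y <- runif(40, 0.1, 3)
  P <- cbind(y, y + 1)
  w <- fit_weights(P, y, seed = 1)
  expect_gte(w[1], 0.98)
  expect_equal(sum(w), 1, tolerance = 1e-12)
})

test_that("fitted ensemble never loses to its best member on the fitting set", {
  for (seed in 1:5) {
    set.seed(seed)
    y <- runif(30, 0.1, 3)
    P <- cbind(y + rnorm(30, 0, 0.2), y + rnorm(30, 0, 0.4), y + rnorm(30, 0, 0.3))
    w <- fit_weights(P, y, seed = seed)
    fused <- weighted_predict(w, P)
    member_rmse <- apply(P, 2, function(p) rmse(y, p))
    expect_lte(rmse(y, fused), min(member_rmse) + 1e-9)
  }
})

test_that("weighted prediction is an exact convex combination", {
  P <- matrix(c(0.2, 0.6), 1, 2)
  expect_equal(weighted_predict(c(0.25, 0.75), P), 0.5)
  expect_equal(weighted_predict(c(1, 0), P), 0.2)
  set.seed(2)
  Pn <- matrix(runif(60), 20, 3)
  wn <- c(0.2, 0.3, 0.5)
  fused <- weighted_predict(wn, Pn)
  expect_true(all(fused >= apply(Pn, 1, min) - 1e-12))
  expect_true(all(fused <= apply(Pn, 1, max) + 1e-12))
  expect_error(weighted_predict(c(0.5, 0.5), Pn), "mismatch")
  expect_error(weighted_predict(c(0.7, 0.2, 0.2), Pn), "sum to 1")
})

test_that("reliability map is monotone, capped, and scale-aware", {
  expect_equal(reliability_from_rmse(0, 1), 0.999)
  expect_equal(reliability_from_rmse(1, 1), 0.5)
  expect_gt(reliability_from_rmse(0.1, 1), reliability_from_rmse(0.2, 1))
  expect_error(reliability_from_rmse(0.1, 0), "y_scale")
  expect_error(reliability_from_rmse(-0.1, 1), "non-negative")
})

test_that("mass functions are valid and behave at the limits", {
  frame <- dst_frame(c(0, 1), k = 10)
  m <- build_mass_function(0.5, 0.1, 0.8, frame)
  expect_equal(sum(m$m) + m$m_theta, 1, tolerance = 1e-12)
  expect_equal(m$m_theta, 0.2, tolerance = 1e-12)
  # vacuous when reliability is zero
  v <- build_mass_function(0.5, 0.1, 0, frame)
  expect_equal(v$m_theta, 1)
  expect_true(all(v$m == 0))
  # narrow bandwidth concentrates on the bin containing the prediction
  sharp <- build_mass_function(0.53, 1e-6, 0.9, frame)
  hit <- which.max(sharp$m)
  expect_gt(sharp$m[hit], 0.9 - 1e-9)
  expect_true(frame$edges[hit] <= 0.53 && 0.53 <= frame$edges[hit + 1])
  # truncation is flagged, not fatal
  trunc <- build_mass_function(2.5, 0.5, 0.9, frame)
  expect_true(trunc$truncated)
  expect_equal(sum(trunc$m) + trunc$m_theta, 1, tolerance = 1e-12)
})

test_that("Dempster combination matches hand-worked two-source cases", {
  frame <- dst_frame(edges = c(0, 1, 2))
  # single focal bin with ignorance: 0.6/0.4 (+) 0.5/0.5 -> 0.8/0.2
  m1 <- ghef:::mass_function(frame, c(0.6, 0), 0.4)
  m2 <- ghef:::mass_function(frame, c(0.5, 0), 0.5)
  m12 <- dempster_combine(m1, m2)
  expect_equal(m12$m, c(0.8, 0), tolerance = 1e-12)
  expect_equal(m12$m_theta, 0.2, tolerance = 1e-12)
  # conflicting singletons renormalize
  m3 <- ghef:::mass_function(frame, c(0.6, 0.4), 0)
  m4 <- ghef:::mass_function(frame, c(0.5, 0.5), 0)
  m34 <- dempster_combine(m3, m4)
  expect_equal(attr(m34, "conflict"), 0.5, tolerance = 1e-12)
  expect_equal(m34$m, c(0.6, 0.4), tolerance = 1e-12)
  # totally conflicting sources are an explicit error
  m5 <- ghef:::mass_function(frame, c(1, 0), 0)
  m6 <- ghef:::mass_function(frame, c(0, 1), 0)
  expect_error(dempster_combine(m5, m6), "conflict")
})

test_that("combination matches brute-force enumeration on random masses", {
  for (k in 2:6) {
    for (rep in 1:5) {
      frame <- dst_frame(c(0, 1), k = k)
      m1 <- random_mass(frame, seed = k * 100 + rep)
      m2 <- random_mass(frame, seed = k * 100 + rep + 50)
      got <- dempster_combine(m1, m2)
      want <- oracle_dempster(m1, m2)
      expect_equal(got$m, want$m, tolerance = 1e-12)
      expect_equal(got$m_theta, want$m_theta, tolerance = 1e-12)
      expect_equal(attr(got, "conflict"), want$conflict, tolerance = 1e-12)
    }
  }
})

test_that("combination is commutative and associative with vacuous identity", {
  frame <- dst_frame(c(0, 1), k = 5)
  a <- random_mass(frame, 1); b <- random_mass(frame, 2); c <- random_mass(frame, 3)
  ab <- dempster_combine(a, b); ba <- dempster_combine(b, a)
  expect_equal(ab$m, ba$m, tolerance = 1e-12)
  abc1 <- dempster_combine(dempster_combine(a, b), c)
  abc2 <- dempster_combine(a, dempster_combine(b, c))
  expect_equal(abc1$m, abc2$m, tolerance = 1e-10)
  expect_equal(abc1$m_theta, abc2$m_theta, tolerance = 1e-10)
  av <- dempster_combine(a, vacuous_mass(frame))
  expect_equal(av$m, a$m, tolerance = 1e-12)
  expect_equal(av$m_theta, a$m_theta, tolerance = 1e-12)
})

test_that("belief and plausibility bracket every interval query", {
  frame <- dst_frame(c(0, 1), k = 8)
  m <- random_mass(frame, 7)
  whole <- bel_pl(m, range(frame$edges))
  expect_equal(unname(whole), c(1, 1), tolerance = 1e-12)
  v <- vacuous_mass(frame)
  sub <- bel_pl(v, c(frame$edges[2], frame$edges[4]))
  expect_equal(unname(sub), c(0, 1))
  # mass 0.7 on bin 3 plus 0.3 ignorance, queried at exactly bin 3
  m3 <- ghef:::mass_function(frame, c(0, 0, 0.7, rep(0, 5)), 0.3)
  got <- bel_pl(m3, c(frame$edges[3], frame$edges[4]))
  expect_equal(unname(got), c(0.7, 1.0), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:1000) {
    q <- sort(runif(2, -0.2, 1.2))
    bp <- bel_pl(random_mass(frame, i), q)
    expect_lte(bp["belief"], bp["plausibility"] + 1e-12)
  }
})

test_that("pignistic transform extracts sane point estimates", {
  frame <- dst_frame(c(0, 1), k = 10)
  onebin <- ghef:::mass_function(frame, c(rep(0, 4), 1, rep(0, 5)), 0)
  expect_equal(pignistic_predict(onebin), frame$centers[5])
  expect_equal(pignistic_predict(vacuous_mass(frame)), mean(frame$centers))
  for (i in 1:20) {
    est <- pignistic_predict(random_mass(frame, i))
    expect_true(est >= frame$edges[1] && est <= frame$edges[length(frame$edges)])
  }
})

test_that("agreeing sharp sources converge to the shared prediction as bins refine", {
  errs <- vapply(c(10, 40, 160), function(k) {
    frame <- dst_frame(c(0, 1), k = k)
    m1 <- build_mass_function(0.37, 0.01, 0.95, frame)
    m2 <- build_mass_function(0.37, 0.01, 0.95, frame)
    abs(pignistic_predict(dempster_combine(m1, m2)) - 0.37)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-2)
})

test_that("evidence-fused prediction respects reliability degeneracies", {
  ds <- std_fixture()
  sp <- split_train_test(ds, 0.2, seed = 2)
  m_gb <- train_learner(reference_config("gb"), sp$train)
  m_hgb <- train_learner(reference_config("hgb"), sp$train)
  frame <- dst_frame(sp$train$solubility, k = 20)
  # second model vacuous: fused estimate equals model 1's pignistic value
  fused <- dst_predict(list(m_gb, m_hgb), c(0.95, 0), c(0.1, 0.1), frame, sp$test)
  solo <- vapply(predict_learner(m_gb, sp$test), function(p) {
    pignistic_predict(build_mass_function(p, 0.1, 0.95, frame))
  }, numeric(1))
  expect_equal(fused$prediction, solo, tolerance = 1e-9)
  expect_true(all(fused$conflict >= 0 & fused$conflict < 1))
  # two equally reliable agreeing models stay near the shared bin
  fused2 <- dst_predict(list(m_gb, m_gb), c(0.9, 0.9), c(0.1, 0.1), frame, sp$test)
  binw <- diff(frame$edges[1:2])
  p_gb <- predict_learner(m_gb, sp$test)
  expect_true(all(abs(fused2$prediction - pmin(pmax(p_gb, frame$edges[1]),
                                               frame$edges[21])) < 3 * binw))
})

test_that("fused test error stays near the best base learner on the fixture", {
  ds <- std_fixture()
  sp <- split_train_test(ds, 0.2, seed = 2)
  m_gb <- train_learner(reference_config("gb"), sp$train)
  m_hgb <- train_learner(reference_config("hgb"), sp$train)
  oof <- ghef:::oof_predictions(list(reference_config("gb"),
                                     reference_config("hgb")),
                                sp$train, 5, seed = 2)
  val_rmse <- apply(oof$V, 2, function(p) rmse(oof$y, p))
  frame <- dst_frame(sp$train$solubility, k = 20)
  rel <- reliability_from_rmse(val_rmse, sd(sp$train$solubility))
  fused <- dst_predict(list(m_gb, m_hgb), rel, val_rmse, frame, sp$test)
  base_rmse <- c(rmse(sp$test$solubility, predict_learner(m_gb, sp$test)),
                 rmse(sp$test$solubility, predict_learner(m_hgb, sp$test)))
  binw <- diff(frame$edges[1:2])
  expect_lte(rmse(sp$test$solubility, fused$prediction),
             1.2 * min(base_rmse) + binw)
})
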