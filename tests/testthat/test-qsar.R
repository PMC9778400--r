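test_that("fit_mlr recovers exact and noisy linear relationships", {
  x <- matrix(1:5, 5, 1, dimnames = list(NULL, "x"))
  fit <- fit_mlr(x, 1 + 2 * (1:5))
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["x"]), 2, tolerance = 1e-10)

  fitc <- fit_mlr(x, rep(7, 5))
  expect_equal(unname(fitc$coefficients["x"]), 0, tolerance = 1e-10)
  expect_equal(fitc$intercept, 7, tolerance = 1e-10)

  set.seed(30)
  X <- matrix(stats::rnorm(90), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(a = 1.5, b = -2, c = 0.5)
  y <- 0.7 + drop(X %*% beta) + stats::rnorm(30, sd = 0.01)
  fitn <- fit_mlr(X, y)
  expect_equal(unname(fitn$coefficients), unname(beta), tolerance = 0.05)

  # OLS residuals orthogonal to design columns and the constant
  res <- attr(fitn, "fit")$residuals
  expect_lt(abs(sum(res)), 1e-8)
  expect_true(all(abs(crossprod(X, res)) < 1e-8))

  # error contracts
  expect_error(fit_mlr(cbind(a = 1:2), 1:2), "insufficient")
  Xs <- cbind(a = 1:6, b = 2 * (1:6))
  expect_error(fit_mlr(Xs, stats::rnorm(6)), "singular")
})

test_that("published equations evaluate exactly as printed", {
  m2 <- published_model_2d()
  zero <- c(MIC1 = 0, ATS4v = 0, AATS7m = 0, CIC3 = 0, minssCH2 = 0)
  expect_identical(unname(predict(m2, zero)), 4.12506)
  expect_equal(unname(predict(m2, replace(zero, "CIC3", 1))), 7.19121)
  # unit-descriptor evaluations return intercept + coefficient, every term
  for (nm in names(m2$coefficients)) {
    expect_equal(unname(predict(m2, replace(zero, nm, 1))),
                 4.12506 + m2$coefficients[[nm]])
  }
  m3 <- published_model_3d()
  expect_identical(m3$intercept, 8.97844)
  expect_identical(unname(m2$coefficients["minssCH2"]), -3.00189)
  expect_error(predict(m2, c(MIC1 = 1)), "missing descriptor")
})

test_that("train_test_split sizes and determinism", {
  ref <- reference_set()
  sp <- train_test_split(ref, 0.8, seed = 4)
  expect_equal(nrow(sp$train), 22L)
  expect_equal(nrow(sp$validation), 5L)
  expect_length(intersect(sp$train$id, sp$validation$id), 0L)
  expect_setequal(c(sp$train$id, sp$validation$id), ref$id)
  sp2 <- train_test_split(ref, 0.8, seed = 4)
  expect_identical(sp$train$id, sp2$train$id)
  sp10 <- train_test_split(data.frame(x = 1:10), 0.8, seed = 1)
  expect_equal(nrow(sp10$train), 8L)
  expect_error(train_test_split(data.frame(x = 1), 0.8, 1), "2 rows")
  expect_error(train_test_split(ref, 1.2, 1), "fraction")
})

test_that("loo_cv matches hand arithmetic and the hat-matrix shortcut", {
  # 3-point hand case: y = x fit through pairs
  X <- matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "x"))
  y <- c(0, 1, 4)
  # leave out each point, fit a line through the other two, predict it:
  # i=1: line through (1,1),(2,4): y = -2 + 3x -> pred(0) = -2, e = 2
  # i=2: line through (0,0),(2,4): y = 2x     -> pred(1) = 2,  e = -1
  # i=3: line through (0,0),(1,1): y = x      -> pred(2) = 2,  e = 2
  hand_press <- 2^2 + 1^2 + 2^2
  loo <- loo_cv(X, y)
  expect_equal(loo$press, hand_press, tolerance = 1e-10)
  expect_equal(loo$loo_predictions, c(-2, 2, 2), tolerance = 1e-10)

  # noise-free linear data: PRESS ~ 0, Q2 ~ 1
  Xp <- matrix(stats::rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  yp <- 2 + Xp %*% c(1, -1)
  expect_lt(loo_cv(Xp, drop(yp))$press, 1e-18)

  # pure noise: Q2 below 0.5 (typically negative)
  set.seed(77)
  Xn <- matrix(stats::rnorm(90), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  yn <- stats::rnorm(30)
  expect_lt(loo_cv(Xn, yn)$q2_loo, 0.5)

  # shortcut is numerically identical to brute force
  for (s in 1:5) {
    set.seed(s)
    Xr <- matrix(stats::rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    yr <- stats::rnorm(20)
    a <- loo_cv(Xr, yr); b <- press_shortcut(Xr, yr)
    expect_equal(a$press, b$press, tolerance = 1e-10)
    expect_equal(a$loo_predictions, b$loo_predictions, tolerance = 1e-10)
  }
})

test_that("PRESS >= RSS on 50 random OLS fits", {
  set.seed(123)
  for (rep in 1:50) {
    n <- sample(15:40, 1); p <- sample(1:4, 1)
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("v", seq_len(p))))
    y <- stats::rnorm(n)
    fit <- fit_mlr(X, y)
    rss <- sum(attr(fit, "fit")$residuals^2)
    expect_gte(press_shortcut(X, y)$press, rss - 1e-12)
  }
})

test_that("validation_report reproduces the printed metric relations", {
  # synthetic but self-consistent inputs
  set.seed(2)
  y <- stats::rnorm(22, 3.5, 0.7)
  yhat <- y + stats::rnorm(22, sd = 0.2)
  loo <- y + stats::rnorm(22, sd = 0.25)
  yv <- stats::rnorm(5, 3.5, 0.7); yvh <- yv + stats::rnorm(5, sd = 0.3)
  vr <- validation_report(y, yhat, loo, yv, yvh, p = 5)
  expect_equal(vr$sdec, sqrt(vr$rss / 22), tolerance = 1e-12)
  expect_equal(vr$sdep, sqrt(vr$press / 22), tolerance = 1e-12)
  expect_equal(vr$r2_adjusted,
               1 - (1 - vr$r2_fitting) * 21 / 16, tolerance = 1e-12)
  expect_equal(vr$mse, mean((yv - yvh)^2))
  expect_equal(vr$mae, mean(abs(yv - yvh)))
  expect_error(validation_report(rep(1, 5), rep(1, 5), rep(1, 5), p = 1),
               "zero training variance")
})

test_that("published residuals reproduce the printed residue columns", {
  expect_equal(residual_published("Apigenin-7-O-glucoside", "2d"), 1.174)
  expect_equal(residual_published("5281673", "3d"), -1.487)
  expect_equal(residual_published("65064", "2d"), 0.002)
  expect_error(residual_published("nosuch", "2d"), "unknown")
})

test_that("GA selection: exhaustive oracle at k=1, monotone trace, recovery", {
  d <- synth_linear_dataset(n = 40, p_total = 12, seed = 5)
  g1 <- ga_select(d$table, d$y, k = 1, population = 24, generations = 20,
                  seed = 3)
  exhaustive <- vapply(colnames(d$table$values), function(cn) {
    press_shortcut(d$table$values[, cn, drop = FALSE], d$y)$q2_loo
  }, 0)
  expect_identical(g1$subset, names(which.max(exhaustive)))
  expect_equal(g1$fitness, max(exhaustive), tolerance = 1e-12)
  expect_false(is.unsorted(g1$trace))

  # determinism
  g1b <- ga_select(d$table, d$y, k = 1, population = 24, generations = 20,
                   seed = 3)
  expect_identical(g1$subset, g1b$subset)
  expect_identical(g1$trace, g1b$trace)

  # planted 5-descriptor signal recovered
  d5 <- synth_linear_dataset(n = 60, p_total = 40, noise_sd = 0.1, seed = 21)
  r <- ga_select(d5$table, d5$y, k = 5, seed = 2)
  expect_setequal(r$subset, names(d5$truth$coefficients))

  expect_error(ga_select(d$table, d$y, k = 39, seed = 1), "k")
})

test_that("mlr model serialization round trips", {
  m <- published_model_2d()
  tf <- tempfile(fileext = ".json")
  write_mlr_model(m, tf)
  back <- read_mlr_model(tf)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$coefficients, m$coefficients)
})
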