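test_that("a one-rule system is ordinary linear regression", {
  set.seed(7)
  X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- 3 + 2 * X[, 1] - X[, 2] + rnorm(100, 0, 0.3)
  fcm <- fcm_cluster(X, c = 1, seed = 1)
  model <- init_fis_from_fcm(X, y, fcm)
  ols <- lm.fit(cbind(1, X), y)
  expect_lt(max(abs(evaluate_fis(model, X) - drop(cbind(1, X) %*% ols$coefficients))),
            1e-8)
})

test_that("single-rule evaluation equals the rule's linear consequent", {
  m <- single_rule_fis()
  x <- c(0.7, -1.3)
  expect_equal(evaluate_fis(m, x), 5 + 2 * 0.7 - 1 * (-1.3))
})

test_that("two symmetric rules average their consequents at the midpoint", {
  m <- single_rule_fis()
  m$rules <- list(list(center = c(-1, 0), sigma = c(1, 1), coef = c(10, 0, 0)),
                  list(center = c(1, 0), sigma = c(1, 1), coef = c(20, 0, 0)))
  expect_equal(evaluate_fis(m, c(0, 0)), 15)
})

test_that("batch evaluation equals the loop of single evaluations", {
  d <- ts2_data(n = 50, noise_sd = 0.1)
  fcm <- fcm_cluster(cbind(d$X, d$y), c = 2, seed = 2)
  model <- init_fis_from_fcm(d$X, d$y, fcm)
  batch <- evaluate_fis(model, d$X)
  single <- vapply(seq_len(50), function(i) evaluate_fis(model, d$X[i, ]),
                   numeric(1))
  expect_equal(batch, single)
  expect_error(evaluate_fis(model, c(1, 2)), "expects")
})

test_that("widths are strictly positive on any non-degenerate input", {
  for (s in 1:5) {
    d <- ts2_data(n = 80, noise_sd = 0.2, seed = s)
    model <- init_fis_from_fcm(d$X, d$y,
                               fcm_cluster(cbind(d$X, d$y), c = 3, seed = s))
    for (r in model$rules) expect_true(all(r$sigma > 0))
  }
})

test_that("zero epochs return the model unchanged", {
  d <- ts2_data(n = 60, noise_sd = 0.1)
  model <- init_fis_from_fcm(d$X, d$y, fcm_cluster(d$X, c = 2, seed = 1))
  expect_identical(train_hybrid(model, d$X, d$y, train_config(epochs = 0)),
                   model)
})

test_that("one least-squares pass is exact on a realizable linear target", {
  set.seed(9)
  X <- matrix(rnorm(300), 100, 3)
  y <- 2 - X[, 1] + 0.5 * X[, 2] + 3 * X[, 3]
  for (c in c(1, 3)) {
    model <- init_fis_from_fcm(X, y, fcm_cluster(X, c = c, seed = 1))
    model <- train_hybrid(model, X, y, train_config(epochs = 1))
    expect_lt(attr(model, "rmse_trace")[1], 1e-6)
  }
})

test_that("training RMSE across least-squares passes is non-increasing", {
  for (s in 1:5) {
    d <- ts2_data(n = 200, noise_sd = 0.5, seed = s)
    model <- init_fis_from_fcm(d$X, d$y,
                               fcm_cluster(cbind(d$X, d$y), c = 2, seed = s))
    model <- train_hybrid(model, d$X, d$y,
                          train_config(epochs = 15, seed = s))
    expect_true(all(diff(attr(model, "rmse_trace")) <= 1e-9))
  }
})

test_that("a 2-regime piecewise-linear function is recovered", {
  d <- ts2_data(n = 600, noise_sd = 0)
  model <- anfis_fcm(d$X, d$y, n_rules = 2, cfg = train_config(epochs = 40))
  expect_gte(cor(evaluate_fis(model, d$X), d$y), 0.99)
})

test_that("a known 2-rule TS system is recovered on held-out points", {
  d <- ts2_data(n = 1000, noise_sd = 0.01, seed = 13)
  tr <- 1:700; te <- 701:1000
  model <- anfis_fcm(d$X[tr, , drop = FALSE], d$y[tr], n_rules = 2,
                     cfg = train_config(epochs = 40))
  truth_te <- evaluate_fis(d$truth, d$X[te, , drop = FALSE])
  expect_gte(cor(evaluate_fis(model, d$X[te, , drop = FALSE]), truth_te), 0.99)
})

test_that("training is equivariant to affine input rescaling", {
  d <- ts2_data(n = 300, noise_sd = 0.2, seed = 5)
  cfg <- train_config(epochs = 10, seed = 2)
  m_raw <- anfis_fcm(d$X, d$y, n_rules = 2, cfg = cfg, normalize = TRUE)
  X2 <- d$X * 37 + 11
  colnames(X2) <- "x"
  m_scaled <- anfis_fcm(X2, d$y, n_rules = 2, cfg = cfg, normalize = TRUE)
  p1 <- evaluate_fis(m_raw, d$X)
  p2 <- evaluate_fis(m_scaled, X2)
  expect_lt(max(abs(p1 - p2)) / sd(d$y), 1e-6)
})

test_that("the JSON rule base round-trips bit-for-bit", {
  d <- ts2_data(n = 200, noise_sd = 0.3, seed = 8)
  model <- anfis_fcm(d$X, d$y, n_rules = 3, cfg = train_config(epochs = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_fis(model, path)
  back <- read_fis(path)
  Xnew <- matrix(runif(500, -4, 4), ncol = 1, dimnames = list(NULL, "x"))
  expect_identical(evaluate_fis(back, Xnew), evaluate_fis(model, Xnew))
})
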