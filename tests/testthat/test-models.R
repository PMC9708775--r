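# shared noiseless linear toy with positive targets
set.seed(6)
toy_X <- matrix(rnorm(600), 200, 3)
toy_y <- drop(toy_X %*% c(2, -1, 0.5)) + 20

test_that("both trainers drive the noiseless linear toy near zero error", {
  m_lm <- ffnn_train(toy_X, toy_y,
                     ffnn_spec(5, "levenberg_marquardt", max_epochs = 150,
                               seed = 4), val_fraction = 0)
  m_scg <- ffnn_train(toy_X, toy_y,
                      ffnn_spec(5, "scaled_conjugate_gradient",
                                max_epochs = 3000, seed = 4),
                      val_fraction = 0)
  rmse <- function(m) sqrt(mean((predict(m, toy_X) - toy_y)^2))
  r_lm <- rmse(m_lm)
  r_scg <- rmse(m_scg)
  expect_lt(r_lm, 1e-3 * sd(toy_y))
  expect_lt(r_scg, 1e-3 * sd(toy_y))
  # trainer agreement, with both floored at the noise-free resolution limit
  floor_ <- 1e-3 * sd(toy_y)
  expect_lt(abs(max(r_lm, floor_) - max(r_scg, floor_)),
            0.1 * max(r_lm, r_scg, floor_))
})

test_that("LM accepted steps never increase the SSE and runs are bitwise reproducible", {
  spec <- ffnn_spec(6, "levenberg_marquardt", max_epochs = 60, seed = 9)
  set.seed(2)
  X <- matrix(rnorm(300), 100, 3)
  y <- abs(drop(X %*% c(1, 2, -1))) + 5 + rnorm(100, 0, 0.3)
  m1 <- ffnn_train(X, y, spec, val_fraction = 0)
  expect_true(all(diff(m1$history$sse_trace) <= 1e-10))
  m2 <- ffnn_train(X, y, spec, val_fraction = 0)
  expect_identical(m1$theta, m2$theta)
})

test_that("constant targets are fit exactly and predictions stay non-negative", {
  set.seed(3)
  X <- matrix(rnorm(120), 40, 3)
  mc <- ffnn_train(X, rep(3, 40), ffnn_spec(5, seed = 1), val_fraction = 0)
  expect_lt(max(abs(predict(mc, X) - 3)), 1e-6)
  # a target near zero can never be predicted negative
  my <- ffnn_train(X, abs(rnorm(40, 0.1, 0.2)), ffnn_spec(5, seed = 1),
                   val_fraction = 0)
  expect_true(all(predict(my, X) >= 0))
  expect_error(ffnn_train(X, c(rep(1, 39), NA), ffnn_spec(5)), "non-finite")
  expect_error(ffnn_spec(n_hidden = 0), "n_hidden")
})

test_that("model save/load round-trips predictions bitwise for every kind", {
  set.seed(5)
  X <- matrix(rnorm(200), 50, 4)
  y <- abs(drop(X %*% c(1, 0, 2, -1))) + 10
  models <- list(
    ffnn = ffnn_train(X, y, ffnn_spec(5, max_epochs = 30, seed = 2),
                      val_fraction = 0),
    linear = baseline_regressors(X, y, "linear"),
    svm = baseline_regressors(X, y, "svm"),
    pls = pls_train(X, y, 3)
  )
  for (nm in names(models)) {
    f <- withr::local_tempfile(fileext = ".json")
    model_save(models[[nm]], f)
    back <- model_load(f)
    expect_identical(predict(back, X), predict(models[[nm]], X))
  }
})

test_that("prediction contracts: dimension check and extrapolation warning", {
  set.seed(8)
  X <- matrix(runif(60), 20, 3)
  m <- ffnn_train(X, rowSums(X) + 5, ffnn_spec(5, max_epochs = 20, seed = 1),
                  val_fraction = 0)
  expect_error(predict(m, X[, 1:2]), "feature count")
  expect_warning(out <- predict(m, X + 10), "extrapolating")
  expect_true(all(is.finite(out)))
})

test_that("hidden-size search returns the argmin with a parsimony tie-break", {
  expect_error(ffnn_hidden_search(toy_X, toy_y, hidden = integer(0)), "empty")
  one <- suppressWarnings(
    ffnn_hidden_search(toy_X[1:60, ], toy_y[1:60], hidden = 7, folds = 2,
                       max_epochs = 10, seed = 1))
  expect_equal(one$n_hidden, 7L)
  sub <- suppressWarnings(
    ffnn_hidden_search(toy_X[1:90, ], toy_y[1:90], hidden = c(5, 8),
                       folds = 2, max_epochs = 25, seed = 1))
  tab <- attr(sub, "search")
  expect_equal(sub$n_hidden, tab$n_hidden[which.min(tab$rmse_cv)])
  expect_true(all(is.finite(tab$rmse_cv)))
})

test_that("linear baseline is exact on linear data and ridge-falls-back when p > n", {
  set.seed(2)
  X <- matrix(rnorm(300), 100, 3)
  y <- drop(X %*% c(1, 2, 3)) + 30
  m <- baseline_regressors(X, y, "linear")
  expect_lt(sqrt(mean((predict(m, X) - y)^2)), 1e-8)
  expect_warning(
    baseline_regressors(matrix(rnorm(50), 5, 10), abs(rnorm(5)) + 1,
                        "linear"),
    "ridge")
})

test_that("svm baseline fits and both comparison models produce finite CV entries", {
  set.seed(13)
  X <- matrix(runif(400), 100, 4)
  y <- 50 + 30 * sin(3 * X[, 1]) + 10 * X[, 2] + rnorm(100)
  for (kind in c("svm", "linear")) {
    cv <- suppressWarnings(kfold_rmsecv(
      X, y, function(Xtr, ytr) baseline_regressors(Xtr, ytr, kind),
      k = 3, seed = 2))
    expect_true(is.finite(cv$rmse_cv))
    expect_true(is.finite(cv$sd))
  }
})

test_that("PLS at full rank reproduces least squares", {
  set.seed(4)
  X <- matrix(rnorm(300), 100, 3)
  y <- drop(X %*% c(2, -1, 1)) + 25
  m <- pls_train(X, y, ncomp = 3)
  expect_lt(sqrt(mean((predict(m, X) - y)^2)), 1e-6)
})

test_that("ipls with one interval equals whole-spectrum PLS and localizes signal", {
  set.seed(5)
  wn <- seq(200, 1800, length.out = 40)
  X <- matrix(rnorm(120 * 40), 120, 40)
  # only features inside the 3rd of 10 intervals carry signal
  in3 <- wn >= 520 & wn < 680
  y <- drop(X[, in3, drop = FALSE] %*% rep(3, sum(in3))) + 100
  one <- suppressWarnings(ipls(X, y, wn, n_intervals = 1,
                               max_components = 3, folds = 3, seed = 1))
  whole <- suppressWarnings(kfold_rmsecv(
    X, y, function(a, b) pls_train(a, b, one$table$ncomp[1]),
    k = 3, seed = 1))
  expect_equal(one$table$pls_rmse_cv[1], whole$rmse_cv)

  ten <- suppressWarnings(ipls(X, y, wn, n_intervals = 10,
                               max_components = 3, folds = 3, seed = 1))
  expect_equal(ten$best_interval, 3L)
})

test_that("classifier is perfect on separable clusters and near chance on shuffled labels", {
  set.seed(4)
  Xc <- rbind(matrix(rnorm(60, 0, 0.3), 20, 3),
              matrix(rnorm(60, 3, 0.3), 20, 3),
              matrix(rnorm(60, -3, 0.3), 20, 3))
  lab <- rep(c("healthy", "prediabetes", "t2d"), each = 20)
  cl <- ffnn_classify(Xc, lab,
                      spec = ffnn_spec(6, "scaled_conjugate_gradient",
                                       max_epochs = 100),
                      runs = 3, seed = 2)
  expect_equal(cl$mean_accuracy, 100)
  expect_equal(cl$sd_accuracy, 0)

  set.seed(99)
  lab_shuf <- sample(lab)
  cl2 <- ffnn_classify(Xc, lab_shuf,
                       spec = ffnn_spec(4, "scaled_conjugate_gradient",
                                        max_epochs = 40),
                       runs = 5, seed = 3)
  # majority-class fraction is 1/3; Monte-Carlo tolerance is generous
  expect_lt(cl2$mean_accuracy, 60)

  one_run <- ffnn_classify(Xc, lab,
                           spec = ffnn_spec(6, "scaled_conjugate_gradient",
                                            max_epochs = 100),
                           runs = 1, seed = 2)
  expect_equal(one_run$mean_accuracy, one_run$per_run$accuracy[1])
  expect_equal(one_run$sd_accuracy, 0)
})
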