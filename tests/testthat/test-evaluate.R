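test_that("3-fold partition of 414 samples gives the 276/138 arithmetic", {
  set.seed(1)
  X <- matrix(rnorm(414 * 2), 414, 2)
  y <- abs(rnorm(414)) + 5
  cv <- suppressWarnings(kfold_rmsecv(X, y, fit_mean_model, k = 3, seed = 7))
  sizes <- as.integer(table(cv$fold_assignment))
  expect_equal(sizes, c(138L, 138L, 138L))
  expect_equal(414L - sizes, c(276L, 276L, 276L))
  expect_error(kfold_rmsecv(X, y, fit_mean_model, k = 1), "k must be")
})

test_that("an exact oracle model yields zero RMSE-CV; the mean model approaches sigma", {
  set.seed(2)
  X <- matrix(rnorm(900), 300, 3)
  y <- abs(drop(X %*% c(1, 2, 3))) + 2
  cv0 <- kfold_rmsecv(X, y, fit_oracle_model(X, y), k = 3, seed = 5)
  expect_equal(cv0$rmse_cv, 0)
  expect_equal(cv0$sd, 0)
  expect_equal(cv0$predictions, y)

  sigma <- 4
  y2 <- rnorm(3000, 100, sigma)
  X2 <- matrix(rnorm(3000), ncol = 1)
  cv <- suppressWarnings(kfold_rmsecv(X2, y2, fit_mean_model, k = 3, seed = 5))
  expect_equal(cv$rmse_cv, sigma, tolerance = 0.05)
})

test_that("cross-validation is reproducible and grouped folds keep subjects together", {
  set.seed(3)
  X <- matrix(rnorm(120), 60, 2)
  y <- abs(rnorm(60)) + 1
  g <- rep(sprintf("S%02d", 1:12), each = 5)
  a <- suppressWarnings(kfold_rmsecv(X, y, fit_mean_model, k = 3, seed = 4,
                                     groups = g))
  b <- suppressWarnings(kfold_rmsecv(X, y, fit_mean_model, k = 3, seed = 4,
                                     groups = g))
  expect_identical(a$fold_rmse, b$fold_rmse)
  expect_true(all(tapply(a$fold_assignment, g,
                         function(f) length(unique(f))) == 1))
})

test_that("clarke zones partition the lattice and honor the canonical regions", {
  grid <- expand.grid(r = seq_len(450), p = seq_len(450))
  z <- clarke_zone(grid$r, grid$p)
  expect_false(anyNA(z))
  expect_true(all(z %in% c("A", "B", "C", "D", "E")))
  expect_true(all(clarke_zone(seq_len(450), seq_len(450)) == "A"))
  expect_identical(clarke_zone(100, 100), "A")
  expect_identical(clarke_zone(50, 200), "E")
  expect_identical(clarke_zone(250, 100), "D")
  expect_error(clarke_zone(0, 100), "positive")
  expect_error(clarke_zone(100, -5), ">= 0")
})

test_that("clarke summary percentages count zones and sum to 100", {
  all_a <- clarke_summary(c(100, 200, 300), c(100, 200, 300))
  expect_equal(unname(all_a$percentages["A"]), 100)
  mix <- clarke_summary(c(100, 50, 250), c(100, 200, 100))
  expect_equal(unname(mix$percentages[c("A", "E", "D")]),
               rep(33.33, 3))
  for (seed in 1:3) {
    set.seed(seed)
    cs <- clarke_summary(runif(97, 20, 420), runif(97, 0, 420))
    expect_lt(abs(sum(cs$percentages) - 100), 0.011)
  }
  expect_error(clarke_summary(numeric(0), numeric(0)), "at least one")
})

test_that("HbA1c cut-offs map to diagnostic classes with the ADA boundary policy", {
  expect_identical(class_from_hba1c(5.2), "healthy")
  expect_identical(class_from_hba1c(6.0), "prediabetes")
  expect_identical(class_from_hba1c(14.0), "t2d")
  expect_identical(class_from_hba1c(c(5.69, 5.7, 6.49, 6.5)),
                   c("healthy", "prediabetes", "prediabetes", "t2d"))
  expect_error(class_from_hba1c(0), "positive")
})

test_that("dx metrics match hand-computed confusion arithmetic", {
  tru <- c(rep("healthy", 2), rep("prediabetes", 2), rep("t2d", 3))
  prd <- c("healthy", "healthy", "healthy", "prediabetes",
           "t2d", "t2d", "t2d")
  m <- dx_metrics(tru, prd)
  expect_equal(unname(m$sensitivity["healthy"]), 100)
  expect_equal(unname(m$sensitivity["prediabetes"]), 50)
  expect_equal(unname(m$specificity["healthy"]), 80)
  expect_equal(m$accuracy, 100 * 6 / 7)

  perfect <- dx_metrics(tru, tru)
  expect_true(all(perfect$sensitivity == 100))
  expect_true(all(perfect$specificity == 100))
  expect_equal(perfect$accuracy, 100)

  all_t2d <- dx_metrics(tru, rep("t2d", 7))
  expect_equal(unname(all_t2d$sensitivity["t2d"]), 100)
  expect_equal(unname(all_t2d$specificity["t2d"]), 0)
  expect_error(dx_metrics(tru, prd[-1]), "equal length")
  # absent class: undefined, not zero
  m2 <- dx_metrics(c("t2d", "t2d"), c("t2d", "t2d"))
  expect_true(is.na(m2$sensitivity["healthy"]))
})

test_that("dx metrics permute consistently under class relabeling", {
  set.seed(8)
  tru <- sample(DX_CLASSES, 60, replace = TRUE)
  prd <- sample(DX_CLASSES, 60, replace = TRUE)
  m <- dx_metrics(tru, prd)
  perm <- c(healthy = "t2d", prediabetes = "healthy", t2d = "prediabetes")
  m2 <- dx_metrics(unname(perm[tru]), unname(perm[prd]))
  expect_equal(unname(m2$sensitivity[unname(perm)]),
               unname(m$sensitivity[names(perm)]))
  expect_equal(m2$accuracy, m$accuracy)
})

test_that("regression-derived diagnosis composes the cut-offs with the metrics", {
  hba1c <- c(5.3, 6.0, 7.2, 9.0, 5.8)
  tru <- class_from_hba1c(hba1c)
  same <- regression_to_dx(hba1c, tru)
  expect_equal(same$accuracy, 100)
  shifted <- regression_to_dx(hba1c + 1.0, tru)
  expect_lt(shifted$accuracy, 100)
  expect_true(all(is.na(shifted$sensitivity) |
                    (shifted$sensitivity >= 0 & shifted$sensitivity <= 100)))
})
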