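linear_design <- function(n = 50, seed = 42) {
  set.seed(seed)
  x <- matrix(runif(n), n, 1, dimnames = list(NULL, "x"))
  list(x = x, y = 2 * x[, 1])
}

test_that("the hold-out split is sized, disjoint, exhaustive and seeded", {
  g <- generate_samples(generator_config(seed = 2))
  parts <- split_train_validate(g, seed = 9)
  expect_equal(nrow(parts$train), 42)
  expect_equal(nrow(parts$validate), 18)
  key <- function(d) paste(d$sample_id, d$season, d$replicate)
  expect_length(intersect(key(parts$train), key(parts$validate)), 0)
  expect_setequal(c(key(parts$train), key(parts$validate)), key(g))
  again <- split_train_validate(g, seed = 9)
  expect_identical(parts$train, again$train)
  expect_error(split_train_validate(g, fraction = 1.0))
  expect_error(split_train_validate(g[1:3, ]))
})

test_that("all three regressors learn an exactly linear response", {
  d <- linear_design()
  tr <- 1:35; va <- 36:50
  for (alg in c("svr", "ann")) {
    fit <- train_model(model_config(alg, seed = 7),
                       d$x[tr, , drop = FALSE], d$y[tr])
    mae <- mean(abs(predict(fit, d$x[va, , drop = FALSE]) - d$y[va]))
    expect_lt(mae, 0.05 * sd(d$y), label = alg)
  }
  # the forest interpolates more coarsely but still tracks the trend
  rf <- train_model(model_config("random_forest", seed = 7),
                    d$x[tr, , drop = FALSE], d$y[tr])
  expect_lt(mean(abs(predict(rf, d$x[va, , drop = FALSE]) - d$y[va])),
            0.2 * sd(d$y))
})

test_that("a constant target is reproduced by every algorithm", {
  d <- linear_design(30)
  yc <- rep(3.5, 20)
  for (alg in c("random_forest", "svr", "ann")) {
    fit <- suppressWarnings(train_model(model_config(alg, seed = 7),
                                        d$x[1:20, , drop = FALSE], yc))
    pred <- predict(fit, d$x[21:30, , drop = FALSE])
    tol <- if (alg == "random_forest") 0 else 1e-6
    expect_lte(max(abs(pred - 3.5)), tol, label = alg)
  }
})

test_that("fits are deterministic given the config seed and reject NaN", {
  d <- linear_design()
  for (alg in c("random_forest", "svr", "ann")) {
    f1 <- train_model(model_config(alg, seed = 3), d$x, d$y)
    f2 <- train_model(model_config(alg, seed = 3), d$x, d$y)
    expect_identical(predict(f1, d$x), predict(f2, d$x), label = alg)
  }
  bad <- d$x; bad[1] <- NaN
  expect_error(train_model(model_config("svr"), bad, d$y), "finite")
  expect_error(model_config("boosting"))
  expect_error(model_config("svr", cost = -1))
})

test_that("the quasi-Newton optimizer is a selectable alternative", {
  d <- linear_design()
  cfg <- model_config("ann", optimizer = "quasi_newton", seed = 5)
  fit <- train_model(cfg, d$x, d$y)
  expect_lt(mean(abs(predict(fit, d$x) - d$y)), 0.05 * sd(d$y))
})

test_that("error metrics match hand arithmetic and their identities", {
  m <- evaluate(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m$mae, 2 / 3, tolerance = 1e-12)
  expect_equal(m$rmse, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(m$mape_percent, 100 / 3, tolerance = 1e-12)
  expect_equal(m$r_squared, 0, tolerance = 1e-12)

  perfect <- evaluate(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r_squared, 1)

  # predicting the mean gives R^2 = 0 by definition
  a <- c(4, 8, 12, 16)
  expect_equal(evaluate(a, rep(mean(a), 4))$r_squared, 0)

  expect_warning(z <- evaluate(c(1, 2), c(0, 2)), "excluded")
  expect_equal(z$n_mape_excluded, 1)
  expect_equal(z$mape_percent, 0)
  expect_error(evaluate(1:3, 1:2))
})

test_that("k-fold validation partitions correctly and ignores row order", {
  g <- generate_samples(generator_config(seed = 4, censor_stations = list()))
  w <- g[g$season == "winter", ]
  cfg <- model_config("random_forest", seed = 1)
  rep5 <- suppressWarnings(kfold_validate(w, "cd", cfg, k = 5, seed = 8))
  expect_equal(nrow(rep5), 5)
  folds <- attr(rep5, "fold_assignments")
  expect_equal(sort(as.integer(table(folds))), rep(6L, 5))
  expect_length(folds, nrow(w))

  shuffled <- w[sample(nrow(w)), ]
  rep5b <- suppressWarnings(kfold_validate(shuffled, "cd", cfg, k = 5,
                                           seed = 8))
  expect_identical(attr(rep5b, "fold_assignments"), folds)
  expect_equal(rep5b$mae, rep5$mae, tolerance = 1e-12)

  # leave-one-out boundary: every fold holds exactly one record
  loo <- suppressWarnings(kfold_validate(w[1:8, ], "cd", cfg, k = 8, seed = 8))
  expect_equal(nrow(loo), 8)
  expect_true(all(loo$n == 1))
  expect_error(kfold_validate(w[1:4, ], "cd", cfg, k = 5))
  expect_error(kfold_validate(w, "cd", cfg, k = 1))

  gl <- glance(rep5)
  expect_equal(gl$mae_mean, mean(rep5$mae))
})

test_that("the comparison harness produces a tidy per-metal report", {
  g <- generate_samples(generator_config(seed = 6))
  rep <- suppressWarnings(
    compare_models(g, targets = c("cd", "pb"),
                   algorithms = c("random_forest", "svr"), k = 3, seed = 2)
  )
  expect_equal(nrow(rep), 2 * 2 * 2)   # seasons x metals x models
  expect_setequal(unique(rep$model), c("random_forest", "svr"))
  expect_true(all(rep$mae >= 0))
  expect_true(all(rep$rmse >= 0))
  expect_true(all(rep$r_squared <= 1))
  expect_true(all(rep$n_train + rep$n_validate == 30))
})

test_that("tidy and glance summarise fitted models", {
  d <- linear_design()
  fit <- train_model(model_config("svr", seed = 1), d$x, d$y)
  td <- tidy(fit)
  expect_setequal(td$term, c("epsilon", "gamma", "cost"))
  expect_equal(td$value[td$term == "cost"], 200)
  gl <- glance(fit)
  expect_equal(gl$n_train, 50)
  expect_true(gl$converged)
})

test_that("model configurations round-trip through YAML", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  cfgs <- list(model_config("ann", seed = 3), model_config("svr"))
  write_model_yaml(cfgs, yml)
  back <- read_model_yaml(yml)
  expect_equal(back[[1]]$hidden_neurons, 9L)
  expect_equal(back[[2]]$epsilon, 0.015)
  expect_identical(lapply(back, unclass), lapply(cfgs, unclass))
})
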