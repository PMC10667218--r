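#' Regression algorithm configuration
#'
#' One of the three regressors compared by the harness, with tuned
#' defaults: random forest with 15 trees; epsilon-insensitive RBF-kernel
#' support vector regression with epsilon 0.015, gamma 1.2 and cost 200;
#' or a three-layer (single hidden layer) perceptron with 9 sigmoid hidden
#' neurons trained for up to 1000 epochs. The perceptron's default
#' optimizer is Levenberg-Marquardt (a damped Gauss-Newton loop on the
#' sum-of-squares objective, with the learning rate as initial damping);
#' `optimizer = "quasi_newton"` selects BFGS training via \pkg{nnet}
#' instead.
#'
#' @param algorithm `"random_forest"`, `"svr"` or `"ann"`.
#' @param n_trees Random forest: number of trees.
#' @param epsilon,gamma,cost SVR: insensitivity tube width, RBF kernel
#'   width, and soft-margin cost.
#' @param hidden_neurons,epochs,learning_rate,optimizer ANN: hidden-layer
#'   width, maximum training iterations, initial damping / learning rate,
#'   and `"levenberg_marquardt"` or `"quasi_newton"`.
#' @param seed Integer seed controlling every stochastic element of the
#'   fit.
#' @return A list of class `model_config`.
#' @export
model_config <- function(algorithm = c("random_forest", "svr", "ann"),
                         n_trees = 15,
                         epsilon = 0.015, gamma = 1.2, cost = 200,
                         hidden_neurons = 9, epochs = 1000,
                         learning_rate = 0.01,
                         optimizer = c("levenberg_marquardt", "quasi_newton"),
                         seed = 1L) {
  algorithm <- match.arg(algorithm)
  optimizer <- match.arg(optimizer)
  hyper <- c(n_trees, epsilon, gamma, cost, hidden_neurons, epochs,
             learning_rate)
  if (any(!is.finite(hyper)) || any(hyper <= 0)) {
    abort("all hyperparameters must be strictly positive.")
  }
  structure(
    list(algorithm = algorithm, n_trees = as.integer(n_trees),
         epsilon = epsilon, gamma = gamma, cost = cost,
         hidden_neurons = as.integer(hidden_neurons),
         epochs = as.integer(epochs), learning_rate = learning_rate,
         optimizer = optimizer, seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Read / write model configurations as YAML
#' @param path File path.
#' @return A list of `model_config` objects, or `path` invisibly.
#' @export
read_model_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(x) do.call(model_config, x))
}

#' @rdname read_model_yaml
#' @param configs A list of `model_config` objects.
#' @export
write_model_yaml <- function(configs, path) {
  yaml::write_yaml(lapply(configs, unclass), path)
  invisible(path)
}

canonical_order <- function(data) {
  keys <- intersect(c("sample_id", "river", "season", "replicate", "variant"),
                    names(data))
  if (!length(keys)) return(data)
  data[do.call(order, data[keys]), , drop = FALSE]
}

#' Split records into training and validation sets
#'
#' A seeded shuffle after canonical ordering by sample identifiers, so the
#' partition does not depend on incoming row order. The training set gets
#' `round(fraction * n)` rows and the validation set the remainder; the
#' two are disjoint and exhaustive.
#'
#' @param data Data frame of records (>= 4 rows).
#' @param fraction Training fraction in (0, 1); default 0.70.
#' @param seed Integer seed.
#' @return A list with elements `train` and `validate`.
#' @export
split_train_validate <- function(data, fraction = 0.70, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
  n <- nrow(data)
  if (n < 4) abort("need at least 4 records to split.")
  data <- canonical_order(data)
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- max(1L, min(n - 1L, round(fraction * n)))
  list(train = data[sort(idx[seq_len(n_train)]), , drop = FALSE],
       validate = data[sort(idx[-seq_len(n_train)]), , drop = FALSE])
}

# ---- feature construction --------------------------------------------------

#' Design matrix for per-metal prediction
#'
#' Default regression layout: the target metal's concentration is
#' predicted from the remaining four metals plus a season indicator and
#' the station coordinates (spatial prediction across the study area).
#'
#' @param data Sample tibble.
#' @param target Metal code to predict.
#' @param features Optional explicit feature column names overriding the
#'   default layout.
#' @return List with `x` (numeric matrix) and `y` (numeric vector).
#' @export
build_design <- function(data, target, features = NULL) {
  target <- match.arg(tolower(target), METALS)
  ycol <- paste0(target, "_mg_l")
  if (is.null(features)) {
    features <- setdiff(conc_cols(), ycol)
    if ("lon" %in% names(data)) features <- c(features, "lon", "lat")
  }
  x <- as.matrix(data[, intersect(features, names(data)), drop = FALSE])
  if ("season" %in% names(data) && length(unique(data$season)) > 1) {
    lev <- sort(unique(data$season))
    for (s in lev[-1]) {
      x <- cbind(x, as.numeric(data$season == s))
      colnames(x)[ncol(x)] <- paste0("season_", s)
    }
  }
  storage.mode(x) <- "double"
  list(x = x, y = as.numeric(data[[ycol]]))
}

# ---- training --------------------------------------------------------------

#' Train one configured regressor
#'
#' Fits the configured algorithm to a numeric feature matrix and target.
#' Features are z-score standardized (statistics estimated on the
#' training data only) for the SVR and the neural network; the random
#' forest sees raw features. Fits are deterministic given
#' `config$seed`. If the neural network's optimizer does not converge
#' within the epoch budget, a warning is raised and the best weights seen
#' are kept.
#'
#' @param config A [model_config()].
#' @param features Numeric matrix or data frame of predictors.
#' @param target Numeric response vector.
#' @return A fitted object of class `hm_model`, usable with
#'   [predict.hm_model()], [tidy()] and [glance()].
#' @export
train_model <- function(config, features, target) {
  stopifnot(inherits(config, "model_config"))
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  y <- as.numeric(target)
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    abort("features and target must be finite and free of missing values.")
  }
  if (nrow(x) < 2) abort("need at least 2 training rows.")
  scaled <- config$algorithm %in% c("svr", "ann")
  ctr <- if (scaled) colMeans(x) else rep(0, ncol(x))
  scl <- if (scaled) apply(x, 2, sd) else rep(1, ncol(x))
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  set.seed(config$seed)
  converged <- TRUE
  fit <- switch(
    config$algorithm,
    random_forest = randomForest::randomForest(x, y, ntree = config$n_trees),
    svr = {
      # when the whole target range fits inside the epsilon tube the SVR
      # optimum has no support vectors (w = 0) and f(x) is the feasible
      # constant; libsvm reports "Model is empty" there, so return that
      # constant solution directly
      if (diff(range(y)) <= 2 * config$epsilon) {
        structure(list(constant = mean(range(y))),
                  class = "constant_predictor")
      } else {
        e1071::svm(xs, y, type = "eps-regression", kernel = "radial",
                   gamma = config$gamma, cost = config$cost,
                   epsilon = config$epsilon, scale = FALSE)
      }
    },
    ann = {
      if (config$optimizer == "levenberg_marquardt") {
        f <- fit_mlp_lm(xs, y, hidden = config$hidden_neurons,
                        max_iter = config$epochs,
                        lambda0 = config$learning_rate)
        converged <- f$converged
        f
      } else {
        nnet::nnet(xs, y, size = config$hidden_neurons, linout = TRUE,
                   maxit = config$epochs, decay = 0, trace = FALSE)
      }
    }
  )
  if (!converged) {
    warn("neural network did not converge within the epoch budget; best-so-far weights returned.")
  }
  structure(
    list(config = config, fit = fit, center = ctr, scale = scl,
         feature_names = colnames(x), n_train = nrow(x),
         converged = converged),
    class = "hm_model"
  )
}

#' @export
predict.hm_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  cfg <- object$config
  switch(
    cfg$algorithm,
    random_forest = as.numeric(predict(object$fit, x)),
    svr = if (inherits(object$fit, "constant_predictor")) {
      rep(object$fit$constant, nrow(xs))
    } else {
      as.numeric(predict(object$fit, xs))
    },
    ann = if (cfg$optimizer == "levenberg_marquardt") {
      as.numeric(predict_mlp(object$fit, xs))
    } else {
      as.numeric(predict(object$fit, xs))
    }
  )
}

#' @export
print.hm_model <- function(x, ...) {
  cat("<hm_model>", x$config$algorithm,
      "| features:", length(x$feature_names),
      "| n_train:", x$n_train, "\n")
  invisible(x)
}

#' @export
tidy.hm_model <- function(x, ...) {
  cfg <- x$config
  params <- switch(
    cfg$algorithm,
    random_forest = tibble(term = "n_trees", value = cfg$n_trees),
    svr = tibble(term = c("epsilon", "gamma", "cost"),
                 value = c(cfg$epsilon, cfg$gamma, cfg$cost)),
    ann = tibble(term = c("hidden_neurons", "epochs", "learning_rate"),
                 value = c(cfg$hidden_neurons, cfg$epochs, cfg$learning_rate))
  )
  params$algorithm <- cfg$algorithm
  params[, c("algorithm", "term", "value")]
}

#' @export
glance.hm_model <- function(x, ...) {
  tibble(algorithm = x$config$algorithm, n_train = x$n_train,
         n_features = length(x$feature_names), seed = x$config$seed,
         converged = x$converged)
}

# ---- Levenberg-Marquardt MLP ----------------------------------------------

# Single-hidden-layer perceptron, sigmoid hidden units, linear output,
# trained by Levenberg-Marquardt (damped Gauss-Newton on the residuals).
# Parameters: hidden weights W (h x p), hidden biases ch (h), output
# weights v (h), output bias b. Output weights start at zero and the
# output bias at mean(y), so the initial model is the training mean.
fit_mlp_lm <- function(x, y, hidden = 9, max_iter = 1000, lambda0 = 0.01,
                       tol = 1e-10) {
  n <- nrow(x); p <- ncol(x); h <- hidden
  W <- matrix(runif(h * p, -0.7, 0.7) / sqrt(p), h, p)
  ch <- runif(h, -0.1, 0.1)
  v <- rep(0, h)
  b <- mean(y)
  pack <- function(W, ch, v, b) c(b, v, ch, as.numeric(W))
  unpack <- function(th) {
    list(b = th[1], v = th[2:(1 + h)], ch = th[(2 + h):(1 + 2 * h)],
         W = matrix(th[-seq_len(1 + 2 * h)], h, p))
  }
  fwd <- function(th) {
    pr <- unpack(th)
    a <- x %*% t(pr$W) + matrix(pr$ch, n, h, byrow = TRUE)
    hmat <- 1 / (1 + exp(-a))
    list(pred = as.numeric(hmat %*% pr$v + pr$b), hmat = hmat, pr = pr)
  }
  jac <- function(fw) {
    hmat <- fw$hmat; v <- fw$pr$v
    dh <- hmat * (1 - hmat)
    J <- matrix(0, n, 1 + 2 * h + h * p)
    J[, 1] <- 1
    J[, 2:(1 + h)] <- hmat
    J[, (2 + h):(1 + 2 * h)] <- dh * matrix(v, n, h, byrow = TRUE)
    for (k in seq_len(p)) {
      J[, (1 + 2 * h + (k - 1) * h + 1):(1 + 2 * h + k * h)] <-
        dh * matrix(v, n, h, byrow = TRUE) * x[, k]
    }
    J
  }
  th <- pack(W, ch, v, b)
  fw <- fwd(th)
  sse <- sum((y - fw$pred)^2)
  best <- list(theta = th, sse = sse)
  lambda <- lambda0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- y - fw$pred
    J <- jac(fw)
    g <- crossprod(J, r)
    if (max(abs(g)) < 1e-8 || sse < tol) { converged <- TRUE; break }
    A <- crossprod(J)
    step <- tryCatch(
      solve(A + lambda * diag(diag(A) + 1e-8), g),
      error = function(e) NULL
    )
    if (is.null(step)) { lambda <- lambda * 10; next }
    th_new <- th + as.numeric(step)
    fw_new <- fwd(th_new)
    sse_new <- sum((y - fw_new$pred)^2)
    if (is.finite(sse_new) && sse_new < sse) {
      th <- th_new; fw <- fw_new
      if (sse - sse_new < tol * (1 + sse)) {
        sse <- sse_new
        converged <- TRUE
        break
      }
      sse <- sse_new
      lambda <- max(lambda / 10, 1e-12)
      if (sse < best$sse) best <- list(theta = th, sse = sse)
    } else {
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
  }
  if (sse <= best$sse) best <- list(theta = th, sse = sse)
  pr <- unpack(best$theta)
  structure(list(W = pr$W, ch = pr$ch, v = pr$v, b = pr$b,
                 sse = best$sse, converged = converged, hidden = h),
            class = "mlp_lm")
}

predict_mlp <- function(object, x) {
  a <- x %*% t(object$W) +
    matrix(object$ch, nrow(x), object$hidden, byrow = TRUE)
  hmat <- 1 / (1 + exp(-a))
  as.numeric(hmat %*% object$v + object$b)
}

# ---- metrics ---------------------------------------------------------------

#' Error metrics for a prediction vector
#'
#' Computes root mean square error, mean absolute error, mean absolute
#' percentage error and the coefficient of determination:
#' `RMSE = sqrt(mean((a - p)^2))`, `MAE = mean(|p - a|)`,
#' `MAPE = 100 * mean(|a - p| / |p|)` (note the denominator is the
#' predicted value), `R^2 = 1 - SSres / SStot`. Elements with a predicted
#' value of exactly zero are excluded from the MAPE (counted in
#' `n_mape_excluded`, with a warning) since the ratio is undefined there —
#' zeros do occur with censored data under the zero-substitution policy.
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @return One-row tibble: `mae`, `rmse`, `mape_percent`, `r_squared`,
#'   `n`, `n_mape_excluded`.
#' @export
evaluate <- function(actual, predicted) {
  if (length(actual) != length(predicted) || !length(actual)) {
    abort("`actual` and `predicted` must be equal-length, non-empty vectors.")
  }
  err <- actual - predicted
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  nz <- predicted != 0
  if (!all(nz)) {
    warn(paste0(sum(!nz), " element(s) with predicted value 0 excluded from MAPE."))
  }
  mape <- if (any(nz)) 100 * mean(abs(err[nz] / predicted[nz])) else NA_real_
  sstot <- sum((actual - mean(actual))^2)
  ssres <- sum(err^2)
  r2 <- if (sstot > 0) 1 - ssres / sstot else if (ssres == 0) 1 else NA_real_
  tibble(mae = mae, rmse = rmse, mape_percent = mape, r_squared = r2,
         n = length(actual), n_mape_excluded = sum(!nz))
}

#' k-fold cross-validation of one configured regressor
#'
#' Records are canonically ordered by sample identifiers and assigned to
#' `k` disjoint, exhaustive folds by a seeded shuffle (so fold membership
#' is invariant to incoming row order); each fold in turn is held out,
#' the model retrained on the rest, and [evaluate()] applied.
#'
#' @param data Sample tibble.
#' @param target Metal code to predict.
#' @param config A [model_config()].
#' @param k Number of folds (>= 2, <= n); default 5.
#' @param seed Integer seed for the fold assignment.
#' @param features Optional feature columns passed to [build_design()].
#' @return A tibble of class `kfold_report` with one row per fold; fold
#'   assignments are attached as attribute `fold_assignments` (named by
#'   row key) and `glance()` gives the mean and sd of each metric.
#' @export
kfold_validate <- function(data, target, config, k = 5, seed = 1L,
                           features = NULL) {
  if (k < 2) abort("`k` must be >= 2.")
  n <- nrow(data)
  if (k > n) abort("`k` cannot exceed the number of records.")
  data <- canonical_order(data)
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  design <- build_design(data, target, features)
  res <- purrr::map_dfr(seq_len(k), function(f) {
    hold <- fold == f
    fit <- train_model(config, design$x[!hold, , drop = FALSE],
                       design$y[!hold])
    pred <- predict(fit, design$x[hold, , drop = FALSE])
    m <- evaluate(design$y[hold], pred)
    m$fold <- f
    m
  })
  keys <- if (all(c("sample_id", "season") %in% names(data))) {
    paste(data$sample_id, data$season,
          if ("replicate" %in% names(data)) data$replicate else 1L,
          sep = "|")
  } else {
    as.character(seq_len(n))
  }
  attr(res, "fold_assignments") <- setNames(fold, keys)
  attr(res, "target") <- target
  class(res) <- c("kfold_report", class(res))
  res
}

#' @export
glance.kfold_report <- function(x, ...) {
  tibble(
    k = nrow(x),
    mae_mean = mean(x$mae), mae_sd = sd(x$mae),
    rmse_mean = mean(x$rmse), rmse_sd = sd(x$rmse),
    mape_mean = mean(x$mape_percent, na.rm = TRUE),
    mape_sd = sd(x$mape_percent, na.rm = TRUE),
    r_squared_mean = mean(x$r_squared, na.rm = TRUE),
    r_squared_sd = sd(x$r_squared, na.rm = TRUE)
  )
}

#' Compare the three regressors across metals and seasons
#'
#' For every requested metal, season and algorithm: a seeded 70/30
#' train/validation split scored with [evaluate()], plus (optionally)
#' k-fold cross-validated metric means. This is the tabular model
#' comparison the package's modelling layer produces.
#'
#' @param data Sample tibble.
#' @param targets Metal codes to predict (default all five).
#' @param algorithms Algorithms to compare.
#' @param by_season Fit per season (default) or pool seasons.
#' @param fraction Training fraction for the hold-out split.
#' @param k Folds for cross-validation; `NULL` skips it.
#' @param seed Integer seed.
#' @return A tidy tibble: one row per metal x season x model with hold-out
#'   and (if requested) cross-validated metrics.
#' @export
compare_models <- function(data, targets = METALS,
                           algorithms = c("random_forest", "svr", "ann"),
                           by_season = TRUE, fraction = 0.7, k = 5,
                           seed = 1L) {
  assert_sample_frame(data)
  groups <- if (by_season && "season" %in% names(data)) {
    split(data, data$season)
  } else {
    list(all = data)
  }
  grid <- tidyr::expand_grid(season = names(groups), metal = targets,
                             model = algorithms)
  purrr::pmap_dfr(grid, function(season, metal, model) {
    d <- groups[[season]]
    cfg <- model_config(model, seed = seed)
    parts <- split_train_validate(d, fraction, seed = seed)
    tr <- build_design(parts$train, metal)
    va <- build_design(parts$validate, metal)
    fit <- train_model(cfg, tr$x, tr$y)
    m <- evaluate(va$y, predict(fit, va$x))
    out <- dplyr::bind_cols(
      tibble(metal = metal, season = season, model = model,
             n_train = nrow(tr$x), n_validate = nrow(va$x)),
      m[, c("mae", "rmse", "mape_percent", "r_squared")]
    )
    if (!is.null(k)) {
      cv <- glance(kfold_validate(d, metal, cfg, k = k, seed = seed))
      out$cv_k <- cv$k
      out$cv_mae_mean <- cv$mae_mean
      out$cv_rmse_mean <- cv$rmse_mean
      out$cv_r_squared_mean <- cv$r_squared_mean
    }
    out
  })
}

#' Export a model-comparison table as tidy CSV
#' @param report Output of [compare_models()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  readr::write_csv(report, path)
  invisible(path)
}

#' Observed-versus-predicted scatter for a fitted model
#'
#' @param fit An `hm_model`.
#' @param features,actual Validation features and observed values.
#' @param ... Unused.
#' @return A ggplot object with the y = x reference line.
#' @export
plot_observed_predicted <- function(fit, features, actual, ...) {
  d <- tibble(observed = actual, predicted = predict(fit, features))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(title = paste("Observed vs predicted -",
                                fit$config$algorithm))
}
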