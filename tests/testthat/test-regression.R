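test_that("noise-free single-effect response is recovered exactly", {
  withr::with_seed(31, {
    n <- 9
    X <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("x", 1:6)))
    y <- 2 * X[, "x3"] + 1
    # lm warns about the essentially perfect fit; that is the point here
    fit <- suppressWarnings(stepwise_fit(X, y))
    expect_equal(fit$selected, "x3")
    expect_equal(fit$intercept, 1, tolerance = 1e-8)
    expect_equal(unname(fit$coefficients), 2, tolerance = 1e-8)
    expect_true(fit$valid)
  })
})

test_that("stepwise never saturates: at most n - 2 terms", {
  withr::with_seed(32, {
    for (i in 1:10) {
      n <- 9
      X <- matrix(rnorm(n * 13), n, 13,
                  dimnames = list(NULL, paste0("x", 1:13)))
      y <- X %*% rnorm(13) # strong signal everywhere
      fit <- stepwise_fit(X, as.numeric(y))
      expect_lte(length(fit$selected), n - 2)
    }
  })
})

test_that("OLS residuals are orthogonal to the selected columns", {
  withr::with_seed(33, {
    n <- 12
    X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("x", 1:5)))
    y <- X[, 1] - 0.5 * X[, 4] + rnorm(n, sd = 0.1)
    fit <- stepwise_fit(X, y)
    if (length(fit$selected)) {
      res <- y - predict(fit$fit)
      for (v in fit$selected) {
        expect_lt(abs(sum(res * X[, v])), 1e-10)
      }
    }
  })
})

test_that("null responses rarely admit a valid model at the 0.05 gate", {
  # type-I simulation on independent predictors
  withr::with_seed(34, {
    n_valid <- 0
    for (i in 1:60) {
      X <- matrix(rnorm(9 * 5), 9, 5, dimnames = list(NULL, paste0("x", 1:5)))
      y <- rnorm(9)
      fit <- stepwise_fit(X, y)
      n_valid <- n_valid + fit$valid
    }
    # best-of-5 selection inflates the nominal 5%; stays well under 40%
    expect_lt(n_valid / 60, 0.4)
  })
})

test_that("relative importance matches closed-form r-squared ratios", {
  withr::with_seed(35, {
    n <- 400
    y <- rnorm(n)
    e1 <- rnorm(n); e2 <- rnorm(n)
    r <- 0.6
    # construct predictors with known population correlation r and r/sqrt(2)
    x1 <- r * y + sqrt(1 - r^2) * e1
    r2 <- r / sqrt(2)
    x2 <- r2 * y + sqrt(1 - r2^2) * e2
    imp <- relative_importance(cbind(a = x1, b = x2), y)
    ratio <- imp$importance[imp$component == "a"] /
      imp$importance[imp$component == "b"]
    expect_equal(ratio, 2, tolerance = 0.35)
    expect_equal(sum(imp$importance), 1, tolerance = 1e-10)
  })
  # exact version: plug sample correlations into the definition
  withr::with_seed(36, {
    X <- matrix(rnorm(9 * 4), 9, 4, dimnames = list(NULL, paste0("x", 1:4)))
    y <- rnorm(9)
    imp <- relative_importance(X, y)
    direct <- cor(X, y)^2
    expect_equal(imp$importance, as.numeric(direct / sum(direct)),
                 tolerance = 1e-12)
  })
})

test_that("importance is invariant to affine predictor rescaling", {
  withr::with_seed(37, {
    X <- matrix(rnorm(10 * 3), 10, 3, dimnames = list(NULL, paste0("x", 1:3)))
    y <- rnorm(10)
    a <- relative_importance(X, y)
    Xs <- sweep(sweep(X, 2, c(2, -3, 0.5), `*`), 2, c(1, 0, -7), `+`)
    b <- relative_importance(Xs, y)
    expect_equal(a$importance, b$importance, tolerance = 1e-10)
  })
})

test_that("perfectly correlated predictor takes all the weight; identical predictors share", {
  withr::with_seed(38, {
    y <- rnorm(12)
    X <- cbind(a = y, b = rnorm(12), c = rnorm(12))
    imp <- relative_importance(X, y)
    expect_gt(imp$importance[imp$component == "a"], 0.8)
    Xeq <- cbind(a = X[, 2], b = X[, 2], c = X[, 2])
    impeq <- relative_importance(Xeq, y)
    expect_equal(impeq$importance, rep(1 / 3, 3), tolerance = 1e-12)
  })
})

test_that("constant predictors get zero importance with a warning", {
  withr::with_seed(39, {
    X <- cbind(a = rnorm(8), b = rep(2, 8))
    y <- rnorm(8)
    expect_warning(imp <- relative_importance(X, y), "constant")
    expect_equal(imp$importance[imp$component == "b"], 0)
  })
})

test_that("mlr_relevance routes between signed coefficients and importance", {
  withr::with_seed(40, {
    n <- 9
    sample_id <- paste0("S", 1:n)
    X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("P", 1:5)))
    fp <- dplyr::bind_cols(tibble::tibble(sample_id = sample_id),
                           tibble::as_tibble(X))
    scores <- tibble::tibble(
      sample_id = sample_id,
      F1 = 3 * X[, "P2"] + rnorm(n, sd = 0.01), # strong single effect
      F2 = rnorm(n) # pure noise
    )
    rel <- mlr_relevance(scores, fp)
    paths <- attr(rel, "paths")
    expect_equal(unname(paths["F1"]), "coefficients")
    f1 <- rel[rel$factor == "F1", ]
    expect_gt(f1$signed[f1$component == "P2"], 0)
    expect_true(all(f1$score[f1$component != "P2"] == 0) ||
                  sum(f1$score > 0) <= 3)
    if (paths["F2"] == "importance") {
      f2 <- rel[rel$factor == "F2", ]
      expect_equal(sum(f2$score), 1, tolerance = 1e-10)
      expect_true(all(is.na(f2$signed)))
    }
  })
})

test_that("glance and tidy report the fitted stepwise model", {
  withr::with_seed(41, {
    X <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(NULL, paste0("x", 1:4)))
    y <- 1.5 * X[, 2] + rnorm(10, sd = 0.05)
    fit <- stepwise_fit(X, y)
    gl <- glance(fit)
    expect_true(gl$valid)
    expect_gt(gl$r2, 0.9)
    td <- tidy(fit)
    expect_true("x2" %in% td$component)
  })
})
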