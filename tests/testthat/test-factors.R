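block_data <- function(n = 12, seed = 3) {
  # two blocks of perfectly correlated columns; b orthogonalized against a so
  # the blocks are exactly uncorrelated and separate cleanly
  withr::with_seed(seed, {
    a <- rnorm(n)
    b <- residuals(lm(rnorm(n) ~ a))
    tibble::tibble(sample_id = paste0("S", 1:n),
                   A1 = a, A2 = 2 * a + 1, A3 = -a,
                   B1 = b, B2 = 3 * b - 2)
  })
}

test_that("two perfect blocks give 100% variance and one factor per block", {
  fm <- fit_factors(block_data(), n_factors = 2)
  expect_equal(fm$cumulative_variance_pct, 100, tolerance = 1e-8)
  L <- abs(fm$loadings)
  # each factor loads ~1 on exactly one block
  blockA <- c("A1", "A2", "A3"); blockB <- c("B1", "B2")
  fA <- which.max(L["A1", ])
  expect_true(all(L[blockA, fA] > 0.99))
  expect_true(all(L[blockB, fA] < 0.05))
  expect_true(all(L[blockB, -fA] > 0.99))
})

test_that("cumulative variance equals the independent eigenvalue ratio", {
  withr::with_seed(8, {
    n <- 10; p <- 6
    x <- tibble::tibble(sample_id = paste0("S", 1:n))
    for (j in 1:p) x[[paste0("V", j)]] <- rnorm(n)
    for (m in c(2, 4, p)) {
      fm <- fit_factors(x, n_factors = m)
      ev <- eigen(cor(as.matrix(x[, -1])), symmetric = TRUE,
                  only.values = TRUE)$values
      expect_equal(fm$cumulative_variance_pct, 100 * sum(ev[1:m]) / p,
                   tolerance = 1e-10)
    }
    expect_equal(fit_factors(x, n_factors = p)$cumulative_variance_pct, 100,
                 tolerance = 1e-8)
  })
})

test_that("varimax rotation is orthogonal and preserves communalities", {
  withr::with_seed(21, {
    x <- tibble::tibble(sample_id = paste0("S", 1:9))
    base <- matrix(rnorm(9 * 2), 9, 2)
    for (j in 1:7) {
      x[[paste0("V", j)]] <- base %*% rnorm(2) + rnorm(9, sd = 0.3)
    }
    fm <- fit_factors(x, n_factors = 3)
    R <- fm$rotation
    expect_equal(crossprod(R), diag(3), tolerance = 1e-10, ignore_attr = TRUE)
    # communalities equal those of the unrotated principal loadings
    ev <- eigen(cor(as.matrix(x[, -1])), symmetric = TRUE)
    L0 <- ev$vectors[, 1:3] %*% diag(sqrt(ev$values[1:3]))
    expect_equal(unname(fm$communalities), unname(rowSums(L0^2)),
                 tolerance = 1e-10)
  })
})

test_that("factor scores are centered and reproduce standardized data at m = p", {
  withr::with_seed(5, {
    n <- 11; p <- 4
    x <- tibble::tibble(sample_id = paste0("S", 1:n))
    for (j in 1:p) x[[paste0("V", j)]] <- rnorm(n)
    fm <- fit_factors(x, n_factors = p)
    S <- as.matrix(fm$scores[, -1])
    expect_equal(colMeans(S), rep(0, p), tolerance = 1e-10, ignore_attr = TRUE)
    Z <- scale(as.matrix(x[, -1]))
    expect_equal(S %*% t(fm$loadings), Z, tolerance = 1e-8, ignore_attr = TRUE)
  })
})

test_that("sign convention makes each factor's dominant loading positive", {
  withr::with_seed(13, {
    x <- block_data(n = 15, seed = 13)
    fm <- fit_factors(x, n_factors = 2)
    for (j in 1:2) {
      col <- fm$loadings[, j]
      expect_gt(col[which.max(abs(col))], 0)
    }
  })
})

test_that("factor count beyond the matrix rank is rejected", {
  x <- block_data()
  # 5 columns but rank 2
  expect_error(fit_factors(x, n_factors = 4), "rank")
})

test_that("factors are labeled by their dominant index group", {
  loadings <- matrix(0, 10, 2,
                     dimnames = list(names(default_index_groups()),
                                     c("F1", "F2")))
  loadings[c("WBV5", "WBV50", "WBV200", "PV"), 1] <- 0.9
  loadings["MPAR", 2] <- 0.99
  model <- structure(list(loadings = loadings), class = "factor_model")
  model <- label_factors(model)
  expect_equal(model$labels$F1, "blood viscosity")
  expect_equal(model$labels$F2, "platelet aggregation")
})

test_that("loading ties attach both labels with a warning", {
  loadings <- matrix(0, 10, 1,
                     dimnames = list(names(default_index_groups()), "F1"))
  loadings[c("PV", "MPAR"), 1] <- 0.8
  model <- structure(list(loadings = loadings), class = "factor_model")
  expect_warning(model <- label_factors(model), "tie")
  expect_match(model$labels$F1, "&")
})

test_that("tidy and glance expose loadings and fit summary", {
  fm <- fit_factors(block_data(), n_factors = 2)
  td <- tidy(fm)
  expect_setequal(names(td), c("index", "factor", "loading", "communality"))
  expect_equal(nrow(td), 10)
  gl <- glance(fm)
  expect_equal(gl$n_factors, 2)
  expect_equal(gl$cumulative_variance_pct, 100, tolerance = 1e-8)
})
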