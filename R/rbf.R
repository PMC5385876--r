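#' Fit a radial basis function network
#'
#' A compact Gaussian RBF network for a factor-score response on standardized
#' component inputs: hidden-unit centers are chosen by seeded k-means, each
#' center's width is its distance to the nearest other center divided by
#' \eqn{\sqrt{2}} (floored at a small epsilon), hidden activations are
#' \eqn{\exp(-\lVert x - c \rVert^2 / (2 w^2))}, and output weights (with
#' bias) are solved by least squares. With as many hidden units as distinct
#' samples the network interpolates the training data exactly.
#'
#' @param x Predictor tibble/matrix (components); standardized internally.
#' @param y Numeric response (factor scores).
#' @param n_hidden Number of hidden units, between 1 and the number of
#'   samples. The default 3 keeps the least-squares solve comfortably
#'   overdetermined for a nine-sample study.
#' @param seed Integer seed for the k-means initialization; the same seed
#'   reproduces the model exactly.
#' @return An `rbf_model`: `centers`, `widths`, `weights` (bias first),
#'   `train_rmse`, `seed`, plus the input scaling.
#' @export
fit_rbf <- function(x, y, n_hidden = 3, seed = 1L) {
  xm <- predictor_matrix(x)
  n <- nrow(xm)
  if (length(y) != n) abort("`y` length does not match predictor rows")
  if (!is_count(n_hidden) || n_hidden > n) {
    abort("`n_hidden` must be a positive integer <= number of samples")
  }
  ctr <- attr(sc <- scale(xm), "scaled:center")
  scl <- attr(sc, "scaled:scale")
  scl[scl == 0] <- 1
  z <- sweep(sweep(xm, 2, ctr), 2, scl, `/`)
  centers <- withr::with_seed(seed, {
    if (n_hidden == n) {
      z
    } else {
      km <- kmeans(z, centers = n_hidden, nstart = 10, iter.max = 100)
      km$centers
    }
  })
  widths <- center_widths(centers)
  H <- rbf_activations(z, centers, widths)
  A <- cbind(1, H)
  # minimum-norm least squares: robust to the square/underdetermined case
  # (n_hidden = n gives n equations, n + 1 unknowns but an exact interpolant)
  w <- as.numeric(MASS::ginv(A) %*% y)
  pred <- as.numeric(A %*% w)
  structure(list(
    centers = centers, widths = widths, weights = w,
    train_rmse = sqrt(mean((y - pred)^2)),
    seed = as.integer(seed),
    scaling = list(center = ctr, scale = scl),
    n_hidden = as.integer(n_hidden)
  ), class = "rbf_model")
}

center_widths <- function(centers, eps = 1e-6) {
  h <- nrow(centers)
  if (h == 1) return(max(sqrt(sum(centers^2)), 1)) # lone center: unit-order width
  d <- as.matrix(stats::dist(centers))
  diag(d) <- Inf
  pmax(apply(d, 1, min) / sqrt(2), eps)
}

rbf_activations <- function(z, centers, widths) {
  h <- nrow(centers)
  H <- matrix(0, nrow(z), h)
  for (j in seq_len(h)) {
    d2 <- rowSums(sweep(z, 2, centers[j, ])^2)
    H[, j] <- exp(-d2 / (2 * widths[j]^2))
  }
  H
}

#' @export
predict.rbf_model <- function(object, newdata, ...) {
  xm <- predictor_matrix(newdata)
  z <- sweep(sweep(xm, 2, object$scaling$center), 2, object$scaling$scale, `/`)
  H <- rbf_activations(z, object$centers, object$widths)
  as.numeric(cbind(1, H) %*% object$weights)
}

#' @export
print.rbf_model <- function(x, ...) {
  cat(sprintf("RBF network: %d hidden units, %d inputs, train RMSE %.4g (seed %d)\n",
              x$n_hidden, ncol(x$centers), x$train_rmse, x$seed))
  invisible(x)
}

#' Permutation importance of RBF network inputs
#'
#' Contribution of each input component measured as the mean increase in
#' squared prediction error when that column is randomly permuted, averaged
#' over `n_perm` seeded permutations; negative increases are clipped to zero
#' and the vector is normalized to sum one. A flat model (zero total
#' importance) yields a uniform vector with a warning.
#'
#' @param model A fitted `rbf_model`.
#' @param x The training predictors.
#' @param y The training response.
#' @param n_perm Number of permutations per column.
#' @param seed Integer seed for the permutations.
#' @return Tibble `component`, `importance` (nonnegative, sums to 1).
#' @export
rbf_importance <- function(model, x, y, n_perm = 20, seed = 1L) {
  stopifnot(inherits(model, "rbf_model"))
  xm <- predictor_matrix(x)
  base_mse <- mean((y - predict(model, xm))^2)
  inc <- withr::with_seed(seed, {
    vapply(colnames(xm), function(v) {
      deltas <- vapply(seq_len(n_perm), function(r) {
        xp <- xm
        xp[, v] <- xp[sample(nrow(xp)), v]
        mean((y - predict(model, xp))^2) - base_mse
      }, numeric(1))
      mean(deltas)
    }, numeric(1))
  })
  inc <- pmax(inc, 0)
  tot <- sum(inc)
  w <- if (tot > 0) {
    inc / tot
  } else {
    warn("flat RBF model: uniform importance")
    rep(1 / length(inc), length(inc))
  }
  tibble::tibble(component = colnames(xm), importance = unname(w))
}

#' Per-factor RBF network relevance of components
#'
#' Fits one RBF network per factor on the nondimensionalized component matrix
#' and extracts permutation importances — the seedable surrogate for reading
#' per-input contributions out of a trained network.
#'
#' @param scores Factor-score tibble (`sample_id`, F1..Fm).
#' @param fingerprints Nondimensionalized fingerprint tibble, same samples in
#'   the same order.
#' @param n_hidden Hidden units per network.
#' @param n_perm Permutations per input column.
#' @param seed Base seed; factor j uses `seed + j` for both fit and
#'   permutations so every number is reproducible.
#' @return A `method_relevance` tibble: `method` ("rbf"), `factor`,
#'   `component`, `score` (importance), `signed` (NA), with fitted models in
#'   attribute `details`.
#' @export
rbf_relevance <- function(scores, fingerprints, n_hidden = 3, n_perm = 20,
                          seed = 1L) {
  if (!identical(as.character(scores[[1]]), as.character(fingerprints[[1]]))) {
    abort("sample ids of `scores` and `fingerprints` differ (order matters)")
  }
  fm <- wide_to_matrix(fingerprints)
  sm <- wide_to_matrix(scores)
  details <- list()
  rows <- purrr::map_dfr(seq_len(ncol(sm)), function(j) {
    f <- colnames(sm)[j]
    model <- fit_rbf(fm, sm[, f], n_hidden = n_hidden, seed = seed + j)
    details[[f]] <<- model
    imp <- rbf_importance(model, fm, sm[, f], n_perm = n_perm, seed = seed + j)
    tibble::tibble(method = "rbf", factor = f, component = imp$component,
                   score = imp$importance, signed = NA_real_)
  })
  new_method_relevance(rows, sign_available = FALSE, details = details)
}
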