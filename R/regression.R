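#' Gated stepwise multiple linear regression
#'
#' Classic forward-backward stepwise selection for a factor-score response on
#' component peak-area predictors: at each step the candidate with the
#' smallest partial-F p-value enters if it passes `entry_alpha`, then any
#' included term whose partial-F p-value has risen to `removal_alpha` or above
#' is removed, iterating to a fixpoint. The final model is an ordinary least
#' squares fit; its overall F-test p-value gates whether the signed
#' coefficients may be interpreted at all (`valid`).
#'
#' The selected set is capped at `n - 2` terms so the fit never saturates
#' (13 candidate components vs 9 samples), and a condition-number guard drops
#' the latest entrant if the selected set turns collinear.
#'
#' @param x Predictor tibble/matrix (numeric columns = components); an id
#'   first column in a tibble is dropped automatically.
#' @param y Numeric response (factor scores).
#' @param entry_alpha,removal_alpha Entry and removal thresholds
#'   (`entry_alpha <= removal_alpha`).
#' @return A `stepwise_model`: `selected`, `intercept`, `coefficients`,
#'   `std_coefficients`, `overall_p`, `r2`, `adj_r2`, `valid`, `fit` (the
#'   `lm`, or NULL when nothing entered).
#' @export
stepwise_fit <- function(x, y, entry_alpha = 0.05, removal_alpha = 0.10) {
  xm <- predictor_matrix(x)
  n <- nrow(xm)
  if (length(y) != n) abort("`y` length does not match predictor rows")
  if (n < 4) abort("need at least 4 samples for stepwise selection")
  if (entry_alpha > removal_alpha) abort("`entry_alpha` must be <= `removal_alpha`")
  max_terms <- n - 2L
  selected <- character(0)
  repeat {
    changed <- FALSE
    # forward: best candidate by partial-F p-value
    if (length(selected) < max_terms) {
      cand <- setdiff(colnames(xm), selected)
      cand <- cand[apply(xm[, cand, drop = FALSE], 2, sd) > 0]
      if (length(cand)) {
        pvals <- vapply(cand, function(v) {
          partial_f_p(xm[, c(selected, v), drop = FALSE], y, v)
        }, numeric(1))
        best <- which.min(pvals)
        if (is.finite(pvals[best]) && pvals[best] <= entry_alpha) {
          entrant <- cand[best]
          trial <- c(selected, entrant)
          if (condition_ok(xm[, trial, drop = FALSE])) {
            selected <- trial
            changed <- TRUE
          } else {
            warn(sprintf("dropping collinear entrant '%s'", entrant))
            xm <- xm[, setdiff(colnames(xm), entrant), drop = FALSE]
          }
        }
      }
    }
    # backward: remove any term whose partial-F p rose past removal_alpha
    if (length(selected) > 1) {
      pvals <- vapply(selected, function(v) {
        partial_f_p(xm[, selected, drop = FALSE], y, v)
      }, numeric(1))
      worst <- which.max(pvals)
      if (pvals[worst] >= removal_alpha) {
        selected <- selected[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (!length(selected)) {
    return(structure(list(
      selected = character(0), intercept = mean(y),
      coefficients = numeric(0), std_coefficients = numeric(0),
      overall_p = NA_real_, r2 = 0, adj_r2 = 0, valid = FALSE, fit = NULL
    ), class = "stepwise_model"))
  }
  df <- data.frame(y = y, xm[, selected, drop = FALSE], check.names = FALSE)
  fit <- lm(y ~ ., data = df)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  overall_p <- unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  b <- coef(fit)[-1]
  std_b <- b * apply(xm[, selected, drop = FALSE], 2, sd) / sd(y)
  structure(list(
    selected = selected,
    intercept = unname(coef(fit)[1]),
    coefficients = setNames(unname(b), selected),
    std_coefficients = setNames(unname(std_b), selected),
    overall_p = overall_p,
    r2 = sm$r.squared,
    adj_r2 = sm$adj.r.squared,
    valid = is.finite(overall_p) && overall_p < 0.05,
    fit = fit
  ), class = "stepwise_model")
}

predictor_matrix <- function(x) {
  xm <- if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    as.matrix(x[num])
  } else {
    as.matrix(x)
  }
  if (is.null(colnames(xm))) colnames(xm) <- component_labels(ncol(xm))
  xm
}

# p-value of the partial F test for term `v` in the model containing `cols`
partial_f_p <- function(cols, y, v) {
  df_full <- data.frame(y = y, cols, check.names = FALSE)
  fit_full <- lm(y ~ ., data = df_full)
  tt <- summary(fit_full)$coefficients
  if (!v %in% rownames(tt)) return(Inf) # aliased: perfectly collinear
  tt[v, "Pr(>|t|)"]
}

condition_ok <- function(cols, kappa_max = 1e8) {
  s <- svd(scale(cols), nu = 0, nv = 0)$d
  s[length(s)] > 0 && (s[1] / s[length(s)]) < kappa_max
}

#' @export
print.stepwise_model <- function(x, ...) {
  if (!length(x$selected)) {
    cat("Stepwise model: no term entered (valid = FALSE)\n")
  } else {
    cat(sprintf("Stepwise model: %s (overall p = %.4g, R2 = %.3f, valid = %s)\n",
                paste(x$selected, collapse = " + "), x$overall_p, x$r2, x$valid))
  }
  invisible(x)
}

#' @export
tidy.stepwise_model <- function(x, ...) {
  tibble::tibble(
    component = x$selected,
    estimate = unname(x$coefficients),
    std_estimate = unname(x$std_coefficients)
  )
}

#' @export
glance.stepwise_model <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected),
    overall_p = x$overall_p,
    r2 = x$r2, adj_r2 = x$adj_r2, valid = x$valid
  )
}

#' Relative importance of predictors by squared marginal correlation
#'
#' The deterministic fallback used when no valid regression can be gated in:
#' each component's importance is its squared Pearson correlation with the
#' response, normalized so the weights sum to one. Constant predictors get
#' importance zero with a warning. Invariant to affine rescaling of any
#' predictor.
#'
#' @inheritParams stepwise_fit
#' @return Tibble `component`, `importance` (nonnegative, sums to 1).
#' @export
relative_importance <- function(x, y) {
  xm <- predictor_matrix(x)
  if (nrow(xm) < 3) abort("need at least 3 samples")
  r2 <- vapply(colnames(xm), function(v) {
    if (sd(xm[, v]) == 0) {
      warn(sprintf("constant predictor '%s': importance 0", v))
      return(0)
    }
    cor(xm[, v], y)^2
  }, numeric(1))
  tot <- sum(r2)
  w <- if (tot > 0) r2 / tot else rep(1 / length(r2), length(r2))
  tibble::tibble(component = colnames(xm), importance = unname(w))
}

#' Per-factor regression relevance of components
#'
#' For each factor: fit the gated stepwise regression of its scores on the
#' component matrix. If a valid model is established (overall p below
#' `gate_alpha`) the standardized coefficients carry the relevance, signed;
#' components not selected score zero. Otherwise the unsigned
#' [relative_importance()] fallback is used. The method tag per factor is
#' recorded so the consensus stage knows when signs are available.
#'
#' @param scores Factor-score tibble (`sample_id`, F1..Fm).
#' @param fingerprints Nondimensionalized fingerprint tibble, same samples in
#'   the same order.
#' @param gate_alpha Overall-p gate below which coefficients are interpreted.
#' @param entry_alpha,removal_alpha Stepwise thresholds.
#' @return A `method_relevance` tibble: `method` ("mlr"), `factor`,
#'   `component`, `score` (|standardized beta| or importance), `signed`
#'   (signed beta, or NA on the importance path), with per-factor models in
#'   attribute `details` and per-factor path in attribute `paths`.
#' @export
mlr_relevance <- function(scores, fingerprints, gate_alpha = 0.05,
                          entry_alpha = 0.05, removal_alpha = 0.10) {
  if (!identical(as.character(scores[[1]]), as.character(fingerprints[[1]]))) {
    abort("sample ids of `scores` and `fingerprints` differ (order matters)")
  }
  fm <- wide_to_matrix(fingerprints)
  sm <- wide_to_matrix(scores)
  comps <- colnames(fm)
  details <- list()
  paths <- character(0)
  rows <- purrr::map_dfr(colnames(sm), function(f) {
    model <- stepwise_fit(fm, sm[, f], entry_alpha, removal_alpha)
    details[[f]] <<- model
    if (model$valid && model$overall_p < gate_alpha) {
      paths[f] <<- "coefficients"
      beta <- setNames(rep(0, length(comps)), comps)
      beta[model$selected] <- model$std_coefficients
      tibble::tibble(method = "mlr", factor = f, component = comps,
                     score = abs(unname(beta)), signed = unname(beta))
    } else {
      paths[f] <<- "importance"
      imp <- relative_importance(fm, sm[, f])
      tibble::tibble(method = "mlr", factor = f, component = imp$component,
                     score = imp$importance, signed = NA_real_)
    }
  })
  out <- new_method_relevance(rows, sign_available = TRUE, details = details)
  attr(out, "paths") <- paths
  out
}
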