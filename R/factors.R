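#' Reduce correlated pharmacological indices to bioactivity factors
#'
#' Principal-component extraction from the correlation matrix of the oriented,
#' nondimensionalized index table, followed by varimax rotation with Kaiser
#' normalization and regression (Thomson) factor scores — the classic recipe
#' for collapsing an intercorrelated hemorheology/coagulation panel into a
#' handful of independent bioactivity factors that then serve as reference
#' series for relevance analysis.
#'
#' Unrotated loadings are eigenvectors scaled by the square roots of their
#' eigenvalues; the reported cumulative variance is
#' \eqn{100 \sum_{j \le m} \lambda_j / p} and is invariant under rotation.
#' Each rotated factor is sign-flipped so its largest-magnitude loading is
#' positive (score signs are otherwise arbitrary). With fewer samples than
#' indices the correlation matrix is singular, so regression scores use the
#' Moore-Penrose pseudoinverse.
#'
#' @param x Wide tibble of samples by indices (first column = sample ids),
#'   typically the reference-group rows of a nondimensionalized table.
#' @param n_factors Number of factors m to extract (<= rank of the
#'   correlation matrix).
#' @return A `factor_model`: `correlation`, `eigenvalues`, `loadings`
#'   (p x m, rotated), `rotation` (m x m orthogonal), `communalities`,
#'   `scores` (tibble `sample_id`, F1..Fm), `cumulative_variance_pct`,
#'   `labels` (NULL until [label_factors()]).
#' @export
fit_factors <- function(x, n_factors = 5) {
  m <- wide_to_matrix(x)
  n <- nrow(m)
  p <- ncol(m)
  if (!is_count(n_factors) || n_factors > p) {
    abort("`n_factors` must be a positive integer <= number of indices")
  }
  if (n < n_factors + 1) abort("need at least n_factors + 1 samples")
  R <- cor(m)
  eig <- eigen(R, symmetric = TRUE)
  evals <- pmax(eig$values, 0)
  rk <- sum(evals > 1e-10)
  if (n_factors > rk) {
    abort(sprintf("correlation matrix has rank %d < n_factors = %d", rk, n_factors))
  }
  L <- eig$vectors[, seq_len(n_factors), drop = FALSE] %*%
    diag(sqrt(evals[seq_len(n_factors)]), n_factors)
  if (n_factors > 1) {
    vm <- stats::varimax(L, normalize = TRUE)
    Lr <- unclass(vm$loadings)
    rot <- vm$rotmat
  } else {
    Lr <- L
    rot <- diag(1)
  }
  # sign convention: largest |loading| of each factor is positive
  flip <- vapply(seq_len(n_factors), function(j) {
    sign(Lr[which.max(abs(Lr[, j])), j])
  }, numeric(1))
  flip[flip == 0] <- 1
  Lr <- sweep(Lr, 2, flip, `*`)
  rot <- sweep(rot, 2, flip, `*`)
  dimnames(Lr) <- list(colnames(m), paste0("F", seq_len(n_factors)))
  # regression (Thomson) scores on standardized data; pseudoinverse because
  # with n <= p the correlation matrix is rank-deficient
  Z <- scale(m)
  S <- Z %*% MASS::ginv(R) %*% Lr
  colnames(S) <- colnames(Lr)
  scores <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                             tibble::as_tibble(S))
  structure(list(
    correlation = R,
    eigenvalues = evals,
    loadings = Lr,
    rotation = rot,
    communalities = rowSums(Lr^2),
    scores = scores,
    cumulative_variance_pct = 100 * sum(evals[seq_len(n_factors)]) / p,
    n_factors = n_factors,
    n_samples = n,
    labels = NULL
  ), class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("Factor model: %d factors from %d indices over %d samples\n",
              x$n_factors, nrow(x$loadings), x$n_samples))
  cat(sprintf("Cumulative variance: %.2f%%\n", x$cumulative_variance_pct))
  if (!is.null(x$labels)) {
    for (f in names(x$labels)) cat(sprintf("  %s: %s\n", f, x$labels[[f]]))
  }
  invisible(x)
}

#' Default clinical grouping of the ten-index panel
#'
#' Maps each index to the aspect of the vascular system it measures, used by
#' [label_factors()] to give extracted factors a clinical reading.
#'
#' @return Named character vector index -> group label.
#' @export
default_index_groups <- function() {
  c(WBV5 = "blood viscosity", WBV50 = "blood viscosity",
    WBV200 = "blood viscosity", PV = "blood viscosity",
    EAI = "RBC aggregation", RCEI = "RBC aggregation",
    ERI = "RBC deformability",
    PT = "extrinsic clotting", APTT = "intrinsic clotting",
    MPAR = "platelet aggregation")
}

#' Label factors by their dominant index group
#'
#' Each factor receives the clinical label of the index group carrying its
#' maximal absolute loadings. Ties attach both labels with a warning.
#'
#' @param model A `factor_model`.
#' @param index_groups Named character vector mapping index ids to clinical
#'   group labels; defaults to [default_index_groups()].
#' @return The model with a `labels` list filled in.
#' @export
label_factors <- function(model, index_groups = default_index_groups()) {
  stopifnot(inherits(model, "factor_model"))
  idx <- rownames(model$loadings)
  missing <- setdiff(idx, names(index_groups))
  if (length(missing)) {
    abort(paste0("no clinical group for index(es): ", paste(missing, collapse = ", ")))
  }
  labels <- lapply(seq_len(ncol(model$loadings)), function(j) {
    lj <- abs(model$loadings[, j])
    top <- max(lj)
    winners <- unique(unname(index_groups[idx[lj > top - 1e-10]]))
    if (length(winners) > 1) {
      warn(sprintf("factor %d: tie in maximal loadings; attaching all labels", j))
    }
    paste(winners, collapse = " & ")
  })
  names(labels) <- colnames(model$loadings)
  model$labels <- labels
  model
}

#' @export
tidy.factor_model <- function(x, ...) {
  long <- tibble::as_tibble(x$loadings, rownames = "index")
  out <- tidyr::pivot_longer(long, -"index", names_to = "factor",
                             values_to = "loading")
  comm <- tibble::tibble(index = names(x$communalities),
                         communality = unname(x$communalities))
  dplyr::left_join(out, comm, by = "index")
}

#' @export
glance.factor_model <- function(x, ...) {
  tibble::tibble(
    n_factors = x$n_factors,
    n_indices = nrow(x$loadings),
    n_samples = x$n_samples,
    cumulative_variance_pct = x$cumulative_variance_pct
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.factor_model <- function(object, ...) {
  df <- tidy(object)
  df$index <- factor(df$index, levels = rev(rownames(object$loadings)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$index,
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "loading",
                  title = "Rotated factor loadings") +
    ggplot2::theme_minimal()
}
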