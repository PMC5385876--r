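#' Grey relational coefficients and degrees
#'
#' Measures the geometric similarity of each comparative series \eqn{x_i}
#' (a component's dimensionless peak areas over the samples) to a reference
#' series \eqn{x_0} (a factor-score series), without distributional
#' assumptions. With deviations \eqn{\Delta_{0i}(k) = |x_0(k) - x_i(k)|} and
#' extremes \eqn{\Delta_{min}, \Delta_{max}} pooled over all comparatives and
#' positions of the analysis, the coefficient at position k is
#' \deqn{\xi_i(k) = \frac{\Delta_{min} + \rho\,\Delta_{max}}
#'                      {\Delta_{0i}(k) + \rho\,\Delta_{max}}}
#' with distinguishing coefficient \eqn{\rho \in (0, 1]}, and the grey
#' relational degree is the mean \eqn{\gamma_i = \frac1n \sum_k \xi_i(k)}.
#' The higher the degree, the greater the component's association with the
#' effect. If every comparative equals the reference (\eqn{\Delta_{max}=0})
#' all coefficients are 1 by the limit convention.
#'
#' @param reference Numeric reference series x0 of length n.
#' @param comparatives Numeric matrix (n x m) or wide data frame whose columns
#'   are the comparative series.
#' @param rho Distinguishing coefficient in (0, 1]; 0.5 by convention.
#' @return A `grey_result`: `deviations`, `delta_min`, `delta_max`,
#'   `coefficients` (both n x m), `grd` (named length-m vector), `ranking`
#'   (tibble `component`, `grd`, `rank`; ties broken by column order), `rho`.
#' @examples
#' grey_relational(c(0, 1, -1), cbind(a = c(0, 1, -1), b = c(1, 1, 1)))
#' @export
grey_relational <- function(reference, comparatives, rho = 0.5) {
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0 || rho > 1) {
    abort("`rho` must be a single value in (0, 1]")
  }
  cm <- if (is.data.frame(comparatives)) {
    as.matrix(comparatives[vapply(comparatives, is.numeric, logical(1))])
  } else {
    as.matrix(comparatives)
  }
  if (!length(cm)) abort("no comparative series supplied")
  if (length(reference) != nrow(cm)) {
    abort("reference and comparative series lengths differ")
  }
  if (is.null(colnames(cm))) colnames(cm) <- component_labels(ncol(cm))
  dev <- abs(cm - reference)
  d_min <- min(dev)
  d_max <- max(dev)
  if (d_max == 0) {
    # all comparatives identical to the reference: limit convention xi = 1
    xi <- array(1, dim(dev), dimnames = dimnames(dev))
  } else {
    xi <- (d_min + rho * d_max) / (dev + rho * d_max)
  }
  grd <- colMeans(xi)
  ord <- order(-grd) # stable: ties keep column (component id) order
  ranking <- tibble::tibble(
    component = colnames(cm)[ord],
    grd = unname(grd[ord]),
    rank = seq_along(ord)
  )
  structure(list(
    deviations = dev, delta_min = d_min, delta_max = d_max,
    coefficients = xi, grd = grd, ranking = ranking, rho = rho
  ), class = "grey_result")
}

#' @export
print.grey_result <- function(x, ...) {
  cat(sprintf("Grey relational analysis (rho = %.3g, n = %d, %d comparatives)\n",
              x$rho, nrow(x$coefficients), ncol(x$coefficients)))
  print(x$ranking, n = 10)
  invisible(x)
}

#' @export
tidy.grey_result <- function(x, ...) x$ranking

#' Factor-by-component grey relational degree matrix
#'
#' Runs one grey relational analysis per factor: the factor-score series is
#' the reference, the nondimensionalized component series are the
#' comparatives, and deviation extremes are pooled within each factor's
#' analysis (not across factors). Optionally rescales the reference onto the
#' comparatives' dimensionless scale first.
#'
#' @param scores Factor-score tibble (`sample_id`, F1..Fm), e.g.
#'   `fit_factors(...)$scores`.
#' @param fingerprints Nondimensionalized fingerprint tibble (`sample_id` +
#'   component columns) with the same samples in the same order.
#' @param rho Distinguishing coefficient.
#' @param reference_scaling `"raw"` uses the factor scores as-is (default);
#'   `"mean_one"` shifts each score series to mean 1 (the comparatives'
#'   scale); `"zscore"` standardizes both reference and comparatives.
#' @return A `method_relevance` tibble: `method` ("gra"), `factor`,
#'   `component`, `score` (the GRD), `signed` (NA: GRA is unsigned), plus the
#'   per-factor `grey_result`s in attribute `details`.
#' @export
gra_relevance <- function(scores, fingerprints, rho = 0.5,
                          reference_scaling = c("raw", "mean_one", "zscore")) {
  reference_scaling <- match.arg(reference_scaling)
  if (!identical(as.character(scores[[1]]), as.character(fingerprints[[1]]))) {
    abort("sample ids of `scores` and `fingerprints` differ (order matters)")
  }
  fm <- wide_to_matrix(fingerprints)
  sm <- wide_to_matrix(scores)
  if (reference_scaling == "zscore") fm <- scale(fm)
  details <- lapply(colnames(sm), function(f) {
    ref <- sm[, f]
    ref <- switch(reference_scaling,
                  raw = ref,
                  mean_one = ref - mean(ref) + 1,
                  zscore = as.numeric(scale(ref)))
    grey_relational(ref, fm, rho = rho)
  })
  names(details) <- colnames(sm)
  out <- purrr::map_dfr(names(details), function(f) {
    grd <- details[[f]]$grd
    tibble::tibble(method = "gra", factor = f,
                   component = names(grd), score = unname(grd),
                   signed = NA_real_)
  })
  new_method_relevance(out, sign_available = FALSE, details = details)
}

new_method_relevance <- function(tbl, sign_available, details = NULL) {
  attr(tbl, "sign_available") <- sign_available
  if (!is.null(details)) attr(tbl, "details") <- details
  class(tbl) <- c("method_relevance", class(tbl))
  tbl
}
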