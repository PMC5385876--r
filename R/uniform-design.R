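#' Good-lattice-point uniform design
#'
#' Constructs a U-type design table by the good-lattice-point (GLP) method:
#' column `j` for run `i` is `((i * g_j - 1) mod n) + 1`, where `g_j` is a
#' generator coprime with the number of runs. Every column is then a
#' permutation of `1..n_runs` (the Latin property), so each factor visits each
#' level exactly once — the layout used to prepare formulation variants in
#' which the doses of the constituent herbs vary jointly but uniformly.
#'
#' @param n_runs Number of runs (= number of levels per factor).
#' @param generators Integer vector of generators, one per factor. Each must
#'   be coprime with `n_runs`.
#' @return A `design_table`: a tibble with a `run` column and one integer
#'   level column per factor (`f1`, `f2`, ...), carrying the generators and
#'   (lazily) the centered L2 discrepancy as attributes.
#' @examples
#' glp_design(9, c(1, 4))
#' @export
glp_design <- function(n_runs, generators) {
  if (!is_count(n_runs, min = 2)) abort("`n_runs` must be an integer >= 2")
  generators <- as.integer(generators)
  if (length(generators) < 1L || anyNA(generators) || any(generators < 1L)) {
    abort("`generators` must be positive integers")
  }
  bad <- generators[vapply(generators, function(g) gcd(g, n_runs) != 1L, logical(1))]
  if (length(bad)) {
    abort(sprintf(
      "generator(s) %s not coprime with n_runs = %d (gcd > 1); the column would not be a permutation of 1..%d",
      paste(bad, collapse = ", "), n_runs, n_runs
    ))
  }
  i <- seq_len(n_runs)
  cols <- lapply(generators, function(g) ((i * g - 1L) %% n_runs) + 1L)
  names(cols) <- paste0("f", seq_along(generators))
  out <- tibble::tibble(run = i, !!!cols)
  new_design_table(out, generators = generators)
}

new_design_table <- function(tbl, generators = NULL, cd2 = NULL) {
  attr(tbl, "generators") <- generators
  attr(tbl, "cd2") <- cd2
  class(tbl) <- c("design_table", class(tbl))
  tbl
}

gcd <- function(a, b) if (b == 0L) a else Recall(b, a %% b)

design_levels <- function(design) {
  stopifnot(is.data.frame(design))
  cols <- setdiff(names(design), "run")
  m <- as.matrix(design[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Centered L2 discrepancy of a design
#'
#' Hickernell's centered L2 discrepancy (CD2) of the design points mapped to
#' the unit cube by \eqn{u = (level - 0.5) / n_{runs}}. Lower is more uniform.
#' CD2 is invariant to row reordering and to the reflection \eqn{u \to 1 - u},
#' which makes it the standard uniformity criterion for number-theoretic
#' designs.
#'
#' @param design A `design_table`, or any data frame / matrix of integer
#'   levels (a `run` column, if present, is ignored).
#' @return The (square-rooted) CD2 value, a nonnegative scalar.
#' @export
centered_l2_discrepancy <- function(design) {
  m <- if (is.matrix(design)) design else design_levels(design)
  if (length(m) == 0L) abort("empty design table")
  n <- nrow(m)
  u <- (m - 0.5) / n
  a <- abs(u - 0.5)
  # term over single points
  t1 <- prod_rows(1 + 0.5 * a - 0.5 * a^2)
  # symmetric double sum via pairwise products per dimension
  s2 <- 0
  for (i in seq_len(n)) {
    # vectorized over rows k
    prods <- exp(rowSums(log(
      1 + 0.5 * rep_row(a[i, ], n) + 0.5 * a - 0.5 * abs(rep_row(u[i, ], n) - u)
    )))
    s2 <- s2 + sum(prods)
  }
  s <- ncol(m)
  cd2_sq <- (13 / 12)^s - (2 / n) * sum(t1) + s2 / n^2
  sqrt(max(cd2_sq, 0))
}

prod_rows <- function(m) exp(rowSums(log(m)))
rep_row <- function(v, n) matrix(v, nrow = n, ncol = length(v), byrow = TRUE)

#' Exhaustive search for the best single-generator-family uniform design
#'
#' Scores every tuple of distinct generators coprime with `n_runs` (the first
#' generator fixed at 1, the GLP convention) by centered L2 discrepancy and
#' returns the minimizing design. Ties are broken by the lexicographically
#' smallest generator tuple, so the search is fully deterministic.
#'
#' @inheritParams glp_design
#' @param n_factors Number of factors; must be smaller than `n_runs`.
#' @return A `design_table` with attributes `generators` and `cd2`.
#' @export
search_design <- function(n_runs, n_factors) {
  if (!is_count(n_runs, min = 2)) abort("`n_runs` must be an integer >= 2")
  if (!is_count(n_factors) || n_factors >= n_runs) {
    abort("`n_factors` must be a positive integer smaller than `n_runs`")
  }
  cand <- Filter(function(g) gcd(g, n_runs) == 1L, seq_len(n_runs - 1L))
  cand <- setdiff(cand, 1L)
  if (n_factors > 1L && length(cand) < n_factors - 1L) {
    abort("not enough coprime generators available for the requested factors")
  }
  tuples <- if (n_factors == 1L) {
    list(1L)
  } else {
    combos <- utils::combn(cand, n_factors - 1L, simplify = FALSE)
    lapply(combos, function(g) c(1L, g))
  }
  best <- NULL
  best_cd2 <- Inf
  for (g in tuples) {
    d <- glp_design(n_runs, g)
    cd2 <- centered_l2_discrepancy(d)
    # strict < keeps the lexicographically first tuple on ties (combn order)
    if (cd2 < best_cd2 - 1e-15) {
      best <- d
      best_cd2 <- cd2
    }
  }
  new_design_table(tibble::as_tibble(best), generators = attr(best, "generators"),
                  cd2 = best_cd2)
}

#' Map design levels to herb doses
#'
#' Applies a per-factor affine map `dose = intercept + slope * level` to a
#' design table, yielding the dose matrix used to prepare the formulation
#' variants. By default doses equal levels (slope 1, intercept 0).
#'
#' @param design A `design_table`.
#' @param slope,intercept Scalars or per-factor vectors.
#' @return A tibble with `sample_id` (S1..Sn) and one dose column per factor.
#' @export
design_doses <- function(design, slope = 1, intercept = 0) {
  m <- design_levels(design)
  doses <- sweep(sweep(m, 2, rep_len(slope, ncol(m)), `*`),
                 2, rep_len(intercept, ncol(m)), `+`)
  if (any(doses <= 0)) abort("affine level-to-dose map produced nonpositive doses")
  colnames(doses) <- paste0("dose_", seq_len(ncol(doses)))
  dplyr::bind_cols(tibble::tibble(sample_id = s_labels(nrow(m))),
                   tibble::as_tibble(doses))
}
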