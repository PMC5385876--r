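#' Top-k components per factor and method
#'
#' For every (factor, method) pair, the k highest-scoring components with
#' nonzero score, ties broken deterministically by component id order.
#' Components scoring exactly zero (e.g. unselected regression terms) are
#' never ranked, so a sparse method can contribute fewer than k entries.
#'
#' @param relevances A `method_relevance` tibble or a list of them
#'   (typically GRA, MLR and RBF outputs over the same components).
#' @param k Entries per (factor, method); default 3.
#' @return Tibble `factor`, `method`, `rank`, `component`, `score`, `signed`.
#' @export
per_factor_topk <- function(relevances, k = 3) {
  tbl <- bind_relevances(relevances)
  n_comp <- length(unique(tbl$component))
  if (k > n_comp) abort("`k` exceeds the number of components")
  comp_order <- unique(tbl$component)
  tbl$comp_ord <- match(tbl$component, comp_order)
  out <- tbl |>
    dplyr::filter(.data$score > 0) |>
    dplyr::group_by(.data$factor, .data$method) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$comp_ord, .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("factor", "method", "rank", "component", "score", "signed")
  out
}

bind_relevances <- function(relevances) {
  if (inherits(relevances, "method_relevance")) relevances <- list(relevances)
  if (!length(relevances)) abort("no relevance tables supplied")
  sets <- lapply(relevances, function(r) sort(unique(r$component)))
  if (length(unique(sets)) != 1) abort("relevance tables cover different component sets")
  dplyr::bind_rows(lapply(relevances, tibble::as_tibble))
}

#' Select the consensus core bioactive components
#'
#' A component joins the core set iff, for at least `min_factors` factors, it
#' ranks in the top k of at least `min_methods` methods — and its regression
#' coefficient, wherever a valid model selected it among those factors, is
#' nonnegative for at least one of them. Components that meet the rank rule
#' but carry only negative regression signs are excluded and listed with the
#' reason, mirroring the practice of dropping components whose fitted effect
#' opposes the therapeutic direction.
#'
#' @param relevances List of `method_relevance` tibbles (GRA, MLR, RBF).
#' @param k Top-k depth per (factor, method).
#' @param min_methods Methods a component must rank in for one factor
#'   (forced down to the number of methods available, with a warning).
#' @param min_factors Factors for which the method rule must hold.
#' @return A `core_report`: `core_set` (character), `exclusions` (tibble
#'   `component`, `reason`), `per_factor_topk`, `membership` (per component:
#'   qualifying factor count), `audit` (parameters used).
#' @export
select_core <- function(relevances, k = 3, min_methods = 2, min_factors = 1) {
  topk <- per_factor_topk(relevances, k = k)
  n_methods <- length(unique(topk$method))
  if (min_methods > n_methods) {
    warn(sprintf("only %d method(s) available; forcing min_methods = %d",
                 n_methods, n_methods))
    min_methods <- n_methods
  }
  # factors for which each component clears the >= min_methods rule
  hits <- topk |>
    dplyr::distinct(.data$factor, .data$method, .data$component) |>
    dplyr::count(.data$factor, .data$component, name = "n_methods") |>
    dplyr::filter(.data$n_methods >= min_methods)
  membership <- hits |>
    dplyr::count(.data$component, name = "n_factors") |>
    dplyr::filter(.data$n_factors >= min_factors)
  # sign rule: where a valid regression selected the component among its
  # qualifying factors, at least one sign must be nonnegative
  signs <- topk |>
    dplyr::filter(.data$method == "mlr", !is.na(.data$signed)) |>
    dplyr::select("factor", "component", "signed")
  exclusions <- tibble::tibble(component = character(0), reason = character(0))
  core <- character(0)
  for (comp in membership$component) {
    qual_factors <- hits$factor[hits$component == comp]
    s <- signs$signed[signs$component == comp & signs$factor %in% qual_factors]
    if (length(s) && all(s < 0)) {
      exclusions <- dplyr::bind_rows(exclusions, tibble::tibble(
        component = comp,
        reason = sprintf("negative regression coefficient for factor(s) %s",
                         paste(unique(signs$factor[signs$component == comp]),
                               collapse = ", "))
      ))
    } else {
      core <- c(core, comp)
    }
  }
  comp_order <- unique(bind_relevances(relevances)$component)
  core <- core[order(match(core, comp_order))]
  if (!length(core)) warn("empty core set")
  structure(list(
    core_set = core,
    exclusions = exclusions,
    per_factor_topk = topk,
    membership = membership,
    audit = list(k = k, min_methods = min_methods, min_factors = min_factors,
                 n_methods = n_methods)
  ), class = "core_report")
}

#' @export
print.core_report <- function(x, ...) {
  cat(sprintf("Core bioactive components (%d): %s\n", length(x$core_set),
              paste(x$core_set, collapse = ", ")))
  cat(sprintf("Rule: top-%d in >= %d method(s) for >= %d factor(s), nonnegative sign\n",
              x$audit$k, x$audit$min_methods, x$audit$min_factors))
  if (nrow(x$exclusions)) {
    cat("Excluded:\n")
    for (i in seq_len(nrow(x$exclusions))) {
      cat(sprintf("  %s - %s\n", x$exclusions$component[i], x$exclusions$reason[i]))
    }
  }
  invisible(x)
}

#' @export
tidy.core_report <- function(x, ...) x$per_factor_topk

#' @export
glance.core_report <- function(x, ...) {
  tibble::tibble(
    n_core = length(x$core_set),
    n_excluded = nrow(x$exclusions),
    k = x$audit$k,
    min_methods = x$audit$min_methods,
    min_factors = x$audit$min_factors
  )
}

#' Designate the bioactive fingerprint
#'
#' Subsets the fingerprint table to the core components — the peaks flagged
#' for quality-control monitoring — optionally annotated with each
#' component's source-herb attribution.
#'
#' @param core A `core_report` or a character vector of component ids.
#' @param fingerprints Fingerprint tibble (`sample_id` + component columns).
#' @param herb_attribution Optional named character vector component ->
#'   source herb label.
#' @return A list: `peaks` (the subset fingerprint tibble) and `components`
#'   (tibble `component`, `herb`).
#' @export
bioactive_fingerprint <- function(core, fingerprints, herb_attribution = NULL) {
  ids <- if (inherits(core, "core_report")) core$core_set else as.character(core)
  missing <- setdiff(ids, names(fingerprints))
  if (length(missing)) {
    abort(paste0("core component(s) absent from fingerprint table: ",
                 paste(missing, collapse = ", ")))
  }
  peaks <- fingerprints[c(names(fingerprints)[1], ids)]
  comp <- tibble::tibble(
    component = ids,
    herb = if (is.null(herb_attribution)) NA_character_ else unname(herb_attribution[ids])
  )
  list(peaks = peaks, components = comp)
}

#' Plot per-factor method relevance profiles
#'
#' @param object A `method_relevance` tibble (or bind several first).
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.method_relevance <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$component <- factor(df$component, levels = unique(df$component))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$score,
                                   fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~factor, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relevance score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
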