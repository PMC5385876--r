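#' Per-group means of a pharmacology panel
#'
#' Collapses per-animal records to the group level: arithmetic mean per
#' (group, index), with SD and group size carried alongside for reporting.
#' Missing values are a hard error — no imputation anywhere in the pipeline.
#'
#' @param panel Per-animal tibble: `group_id`, `animal_id`, then numeric index
#'   columns.
#' @return A list with `means` (wide tibble, `group_id` + one mean column per
#'   index) and `summary` (long tibble: `group_id`, `index`, `n`, `mean`,
#'   `sd`).
#' @export
group_means <- function(panel) {
  stopifnot(is.data.frame(panel), "group_id" %in% names(panel))
  idx_cols <- setdiff(names(panel), c("group_id", "animal_id"))
  if (!length(idx_cols)) abort("panel has no index columns")
  vals <- panel[idx_cols]
  if (!all(vapply(vals, is.numeric, logical(1)))) abort("index columns must be numeric")
  if (anyNA(vals)) abort("missing index values; no imputation is performed")
  if (any(table(panel$group_id) == 0)) abort("empty group")
  long <- tidyr::pivot_longer(panel[c("group_id", idx_cols)],
                              -"group_id", names_to = "index")
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$group_id, .data$index),
    n = dplyr::n(), mean = mean(.data$value), sd = sd(.data$value),
    .groups = "drop"
  )
  # preserve input group and index order (never locale-dependent sorting)
  summ$index <- factor(summ$index, levels = idx_cols)
  summ$group_id <- factor(summ$group_id, levels = unique(panel$group_id))
  summ <- dplyr::arrange(summ, .data$group_id, .data$index)
  summ$index <- as.character(summ$index)
  summ$group_id <- as.character(summ$group_id)
  means <- tidyr::pivot_wider(summ[c("group_id", "index", "mean")],
                              names_from = "index", values_from = "mean")
  list(means = means, summary = summ)
}

#' Orient pharmacological indices so larger always means stronger effect
#'
#' Indices for which a larger value means a weaker drug effect (e.g. blood
#' viscosity, aggregation indices) are replaced by their reciprocal; indices
#' already pointing the right way (e.g. clotting times APTT, PT) pass through
#' unchanged. Applying the map twice restores the original table.
#'
#' @param means Wide tibble (`group_id` + index columns), e.g.
#'   `group_means(panel)$means`.
#' @param orientation Named character vector mapping every index column to
#'   `"direct"` or `"inverse"`.
#' @return Tibble of the same shape with inverse indices reciprocal-transformed.
#' @export
orient <- function(means, orientation) {
  idx_cols <- setdiff(names(means), "group_id")
  missing <- setdiff(idx_cols, names(orientation))
  if (length(missing)) {
    abort(paste0("no orientation given for index(es): ", paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unname(orientation[idx_cols]), c("direct", "inverse"))
  if (length(bad)) abort("orientation values must be 'direct' or 'inverse'")
  out <- means
  for (ix in idx_cols[orientation[idx_cols] == "inverse"]) {
    v <- out[[ix]]
    if (any(v <= 0)) {
      abort(sprintf("index '%s' has nonpositive values; reciprocal orientation undefined", ix))
    }
    out[[ix]] <- 1 / v
  }
  out
}

#' Default orientation of the ten-index hemorheology/coagulation panel
#'
#' Whole-blood viscosity at the three shear rates, plasma viscosity, the
#' erythrocyte aggregation, electrophoresis and rigidity indices and the
#' maximum platelet aggregation rate all worsen as they rise, so they are
#' inverse; the clotting times APTT and PT lengthen under effective treatment,
#' so they are direct. Indices outside the canonical panel (e.g. synthetic
#' `I1..Ip`, which are generated effect-aligned) default to direct.
#'
#' @param index_ids Index column names; defaults to the canonical panel.
#' @return Named character vector usable as `orientation` in [orient()].
#' @export
default_orientation <- function(index_ids = c("WBV5", "WBV50", "WBV200", "PV",
                                              "EAI", "RCEI", "ERI",
                                              "APTT", "PT", "MPAR")) {
  inverse <- c("WBV5", "WBV50", "WBV200", "PV", "EAI", "RCEI", "ERI", "MPAR")
  setNames(ifelse(index_ids %in% inverse, "inverse", "direct"), index_ids)
}

#' Nondimensionalize columns against reference rows
#'
#' Divides every numeric column by its mean over the reference rows (the nine
#' formulation-variant groups), making each column unit-mean over those rows
#' and hence dimensionless and comparable across very different raw units.
#' Non-reference rows (control, model, positive controls) are scaled by the
#' same divisor but excluded from the averaging.
#'
#' @param x Wide tibble: first column ids, remaining columns numeric.
#' @param reference Character vector of id values forming the reference set;
#'   `NULL` (default) uses all rows.
#' @return Tibble of the same shape; reference-row column means are exactly 1.
#' @export
nondimensionalize <- function(x, reference = NULL) {
  ids <- as.character(x[[1]])
  ref <- if (is.null(reference)) rep(TRUE, nrow(x)) else ids %in% reference
  if (!any(ref)) abort("no reference rows found in `x`")
  if (!is.null(reference) && !all(reference %in% ids)) {
    abort("some `reference` ids are absent from `x`")
  }
  out <- x
  for (cn in names(x)[-1]) {
    m <- mean(x[[cn]][ref])
    if (!is.finite(m) || m == 0) {
      abort(sprintf("column '%s' has zero/non-finite reference mean", cn))
    }
    out[[cn]] <- x[[cn]] / m
  }
  out
}

#' Cluster fingerprint samples by correlation distance
#'
#' Agglomerative clustering of samples with average (between-groups) linkage
#' on the distance \eqn{d = 1 - r}, where r is the Pearson correlation between
#' two samples' peak-area vectors. Merge heights are rescaled to the 0-25
#' dendrogram scale familiar from SPSS output, and classes are read off by
#' cutting at a rescaled threshold (default 5).
#'
#' @param fingerprints Fingerprint tibble (`sample_id` + peak-area columns).
#' @param cut Rescaled-distance threshold at which classes are formed.
#' @return A `fingerprint_clusters` object: `hclust` (with rescaled heights),
#'   `classes` tibble (`sample_id`, `class`), `cut`, and the raw
#'   correlation-distance matrix.
#' @export
cluster_fingerprints <- function(fingerprints, cut = 5) {
  m <- wide_to_matrix(fingerprints)
  if (nrow(m) < 2) abort("need at least two samples to cluster")
  if (any(apply(m, 1, sd) == 0)) {
    abort("constant sample peak vector: Pearson correlation undefined")
  }
  d <- 1 - cor(t(m))
  hc <- hclust(as.dist(d), method = "average")
  max_h <- max(hc$height)
  scale <- if (max_h > 0) 25 / max_h else 1
  hc_rescaled <- hc
  hc_rescaled$height <- hc$height * scale
  classes <- cutree(hc_rescaled, h = cut)
  structure(list(
    hclust = hc_rescaled,
    classes = tibble::tibble(sample_id = rownames(m), class = unname(classes)),
    cut = cut,
    distance = d
  ), class = "fingerprint_clusters")
}

#' @export
print.fingerprint_clusters <- function(x, ...) {
  k <- length(unique(x$classes$class))
  cat(sprintf("Fingerprint clustering: %d samples in %d classes (rescaled cut %.3g)\n",
              nrow(x$classes), k, x$cut))
  grp <- split(x$classes$sample_id, x$classes$class)
  for (g in seq_along(grp)) {
    cat(sprintf("  class %d: %s\n", g, paste(grp[[g]], collapse = ", ")))
  }
  invisible(x)
}

#' Tissue-to-blood concentration ratios
#'
#' Per-animal ratio of a tissue concentration (amount per gram) to the blood
#' concentration (amount per mL), summarised per group as median and
#' quartiles — the standard way to report brain penetration of circulating
#' compounds.
#'
#' @param data Tibble of per-animal measurements.
#' @param tissue,blood Column names (strings) of the tissue and blood
#'   concentrations; blood must be strictly positive.
#' @param by Optional grouping column name (e.g. compound).
#' @return A list: `ratios` (input plus a `ratio` column) and `summary`
#'   (per group: `n`, `median`, `q25`, `q75`).
#' @export
tissue_ratio <- function(data, tissue, blood, by = NULL) {
  stopifnot(is.data.frame(data), tissue %in% names(data), blood %in% names(data))
  b <- data[[blood]]
  if (any(b <= 0)) abort("blood concentration must be strictly positive")
  out <- dplyr::mutate(data, ratio = .data[[tissue]] / b)
  grouped <- if (is.null(by)) out else dplyr::group_by(out, .data[[by]])
  summ <- dplyr::summarise(
    grouped,
    n = dplyr::n(),
    median = median(.data$ratio),
    q25 = unname(quantile(.data$ratio, 0.25)),
    q75 = unname(quantile(.data$ratio, 0.75)),
    .groups = "drop"
  )
  list(ratios = out, summary = summ)
}
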