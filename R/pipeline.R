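#' Validate a fingerprint/pharmacology input bundle
#'
#' Checks schemas, id alignment, orientation completeness and positivity
#' constraints without mutating anything; reports issues instead of throwing,
#' so a caller can display all problems at once.
#'
#' @param fingerprints Fingerprint tibble (`sample_id` + positive peak-area
#'   columns).
#' @param pharmacology Per-animal tibble (`group_id`, `animal_id`, index
#'   columns).
#' @param orientation Named character vector index -> "direct"/"inverse".
#' @return Tibble of issues (`stage`, `message`); zero rows when clean.
#' @export
validate_inputs <- function(fingerprints, pharmacology, orientation) {
  issues <- list()
  note <- function(stage, msg) {
    issues[[length(issues) + 1]] <<- tibble::tibble(stage = stage, message = msg)
  }
  if (!is.data.frame(fingerprints) || names(fingerprints)[1] != "sample_id") {
    note("fingerprints", "first column must be `sample_id`")
  } else {
    fm <- fingerprints[-1]
    if (!all(vapply(fm, is.numeric, logical(1)))) {
      note("fingerprints", "peak-area columns must be numeric")
    } else {
      bad <- which(as.matrix(fm) <= 0, arr.ind = TRUE)
      for (i in seq_len(nrow(bad))) {
        note("fingerprints", sprintf(
          "nonpositive peak area at sample '%s', component '%s'",
          fingerprints$sample_id[bad[i, 1]], names(fm)[bad[i, 2]]
        ))
      }
    }
    if (anyDuplicated(fingerprints$sample_id)) {
      note("fingerprints", "duplicate sample ids")
    }
  }
  if (!is.data.frame(pharmacology) ||
      !all(c("group_id", "animal_id") %in% names(pharmacology))) {
    note("pharmacology", "must have `group_id` and `animal_id` columns")
  } else {
    idx <- setdiff(names(pharmacology), c("group_id", "animal_id"))
    if (anyNA(pharmacology[idx])) note("pharmacology", "missing index values")
    if (is.data.frame(fingerprints) && "sample_id" %in% names(fingerprints)) {
      absent <- setdiff(fingerprints$sample_id, pharmacology$group_id)
      if (length(absent)) {
        note("pharmacology", paste0("no animal group for sample(s): ",
                                    paste(absent, collapse = ", ")))
      }
    }
    unoriented <- setdiff(idx, names(orientation))
    if (length(unoriented)) {
      note("orientation", paste0("missing orientation for index(es): ",
                                 paste(unoriented, collapse = ", ")))
    }
  }
  if (length(issues)) dplyr::bind_rows(issues) else {
    tibble::tibble(stage = character(0), message = character(0))
  }
}

#' Run the full spectrum-effect relevance pipeline
#'
#' Orchestrates every stage on one input bundle: per-group index means,
#' orientation, nondimensionalization of both data blocks, factor extraction,
#' the three relevance analyses (grey relational, gated stepwise regression,
#' RBF permutation importance), and the consensus core-component selection.
#' All parameters and seeds are echoed in `summary` so a run is reproducible
#' from the returned object alone.
#'
#' @inheritParams validate_inputs
#' @param n_factors Factors to extract.
#' @param rho Grey relational distinguishing coefficient.
#' @param reference_scaling Reference scaling for the grey stage
#'   (see [gra_relevance()]).
#' @param gate_alpha,entry_alpha,removal_alpha Regression-stage thresholds.
#' @param n_hidden,n_perm RBF architecture and permutation count.
#' @param k,min_methods,min_factors Consensus thresholds.
#' @param seed Seed for the RBF stage (the only stochastic stage).
#' @param cluster_cut Rescaled threshold for the fingerprint clustering
#'   side-report.
#' @return A `spectrum_effect_run` with elements `means`, `oriented`,
#'   `normalized_indices`, `normalized_fingerprints`, `clusters`, `factors`,
#'   `relevance` (list gra/mlr/rbf), `core`, `summary`.
#' @export
run_spectrum_effect <- function(fingerprints, pharmacology,
                                orientation = default_orientation(
                                  setdiff(names(pharmacology), c("group_id", "animal_id"))),
                                n_factors = 5, rho = 0.5,
                                reference_scaling = "raw",
                                gate_alpha = 0.05, entry_alpha = 0.05,
                                removal_alpha = 0.10,
                                n_hidden = 3, n_perm = 20,
                                k = 3, min_methods = 2, min_factors = 1,
                                seed = 1L, cluster_cut = 5) {
  issues <- validate_inputs(fingerprints, pharmacology, orientation)
  if (nrow(issues)) {
    abort(paste0("invalid inputs:\n", paste0("  [", issues$stage, "] ",
                                             issues$message, collapse = "\n")))
  }
  sample_ids <- as.character(fingerprints$sample_id)
  warnings_log <- character(0)
  withCallingHandlers({
    gm <- group_means(pharmacology)
    oriented <- orient(gm$means, orientation)
    norm_idx <- nondimensionalize(oriented, reference = sample_ids)
    norm_fp <- nondimensionalize(fingerprints)
    clusters <- cluster_fingerprints(fingerprints, cut = cluster_cut)
    s_rows <- norm_idx[match(sample_ids, norm_idx$group_id), ]
    names(s_rows)[1] <- "sample_id"
    fm <- fit_factors(s_rows, n_factors = n_factors)
    scores <- fm$scores
    rel <- list(
      gra = gra_relevance(scores, norm_fp, rho = rho,
                          reference_scaling = reference_scaling),
      mlr = mlr_relevance(scores, norm_fp, gate_alpha = gate_alpha,
                          entry_alpha = entry_alpha,
                          removal_alpha = removal_alpha),
      rbf = rbf_relevance(scores, norm_fp, n_hidden = n_hidden,
                          n_perm = n_perm, seed = seed)
    )
    core <- select_core(rel, k = k, min_methods = min_methods,
                        min_factors = min_factors)
  }, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  structure(list(
    means = gm,
    oriented = oriented,
    normalized_indices = norm_idx,
    normalized_fingerprints = norm_fp,
    clusters = clusters,
    factors = fm,
    relevance = rel,
    core = core,
    summary = list(
      n_samples = length(sample_ids),
      n_components = ncol(fingerprints) - 1L,
      n_indices = ncol(gm$means) - 1L,
      parameters = list(
        n_factors = n_factors, rho = rho,
        reference_scaling = reference_scaling,
        gate_alpha = gate_alpha, entry_alpha = entry_alpha,
        removal_alpha = removal_alpha,
        n_hidden = n_hidden, n_perm = n_perm,
        k = k, min_methods = min_methods, min_factors = min_factors,
        seed = seed, cluster_cut = cluster_cut
      ),
      mlr_paths = attr(rel$mlr, "paths"),
      warnings = warnings_log
    )
  ), class = "spectrum_effect_run")
}

#' @export
print.spectrum_effect_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Spectrum-effect run: %d samples, %d components, %d indices\n",
              s$n_samples, s$n_components, s$n_indices))
  cat(sprintf("Factors: %d (cumulative variance %.2f%%)\n",
              x$factors$n_factors, x$factors$cumulative_variance_pct))
  print(x$core)
  if (length(s$warnings)) cat(sprintf("%d warning(s) logged\n", length(s$warnings)))
  invisible(x)
}

#' @export
glance.spectrum_effect_run <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$factors),
    glance(x$core),
    tibble::tibble(n_warnings = length(x$summary$warnings),
                   seed = x$summary$parameters$seed)
  )
}

#' Read a fingerprint/pharmacology bundle from CSV files
#'
#' Reads the plain-text exchange formats written by [write_study()] (or
#' transcribed from an external study): `fingerprints.csv` with `sample_id` +
#' peak-area columns and `pharmacology.csv` with `group_id`, `animal_id` +
#' index columns.
#'
#' @param dir Directory holding the two files.
#' @return List with `fingerprints` and `pharmacology` tibbles.
#' @export
read_study_csv <- function(dir) {
  fp <- file.path(dir, "fingerprints.csv")
  ph <- file.path(dir, "pharmacology.csv")
  for (f in c(fp, ph)) if (!file.exists(f)) abort(paste0("missing file: ", f))
  list(
    fingerprints = tibble::as_tibble(utils::read.csv(fp, check.names = FALSE)),
    pharmacology = tibble::as_tibble(utils::read.csv(ph, check.names = FALSE))
  )
}
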