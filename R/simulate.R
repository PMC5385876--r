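#' Configuration for a synthetic spectrum-effect study
#'
#' Bundles every parameter of the synthetic-study generator: the study shape
#' (samples, herbs, components, indices, animals per group), the chemistry
#' (per-component herb attribution), the planted biology (a sparse signed
#' index-by-component effect matrix and per-index baselines), and the two
#' noise scales. The generator emulates a formulation-variant study: herb
#' doses follow a uniform design, component peak areas are linear in the doses
#' with multiplicative lognormal error, and per-animal index values are linear
#' in the peak areas with additive Gaussian error.
#'
#' Defaults describe the canonical desk-scale study: 9 samples from a
#' two-factor nine-level uniform design, 13 fingerprint components, 10
#' pharmacological indices measured on 10 animals per group, and 4 planted
#' active components whose smallest planted effect swings its target index by
#' at least three times the per-animal noise SD.
#'
#' @param n_samples,n_herbs,n_components,n_indices Study shape (all >= 2).
#' @param attribution `n_components x n_herbs` nonnegative matrix of
#'   area-per-dose loadings; every component must draw on at least one herb.
#'   Default: components sweep the herb-composition range from pure herb 1 to
#'   pure herb 2 with equal total magnitude.
#' @param effect_matrix `n_indices x n_components` signed coefficient matrix
#'   B; nonzero columns define the planted active components. Default: a
#'   block-sparse matrix (see [default_effect_matrix()]).
#' @param baseline Per-index baseline vector (recycled if scalar).
#' @param control_offset,model_offset Additive shifts for the control and
#'   model groups, which carry no component effects.
#' @param fingerprint_noise_sd Lognormal sigma of the multiplicative peak-area
#'   error (peak areas are positive and scale-proportional). This is also the
#'   identity-carrying perturbation of the testbed: with a two-herb design all
#'   expected peak columns live in a two-dimensional dose space, and only the
#'   per-component noise makes components statistically distinguishable. The
#'   default 0.65 makes per-component and dose-driven variation comparable.
#' @param index_noise_sd Additive Gaussian SD of per-animal index error.
#' @param animals_per_group Animals per pharmacology group.
#' @param seed Integer seed; the same config (including seed) reproduces the
#'   study bit-for-bit.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 9,
                              n_herbs = 2,
                              n_components = 13,
                              n_indices = 10,
                              attribution = NULL,
                              effect_matrix = NULL,
                              baseline = 100,
                              control_offset = 20,
                              model_offset = -20,
                              fingerprint_noise_sd = 0.65,
                              index_noise_sd = 5,
                              animals_per_group = 10,
                              seed = 1L) {
  for (nm in c("n_samples", "n_herbs", "n_components", "n_indices")) {
    if (!is_count(get(nm), min = 2)) abort(sprintf("`%s` must be an integer >= 2", nm))
  }
  if (!is_count(animals_per_group, min = 1)) {
    abort("`animals_per_group` must be a positive integer")
  }
  if (fingerprint_noise_sd < 0 || index_noise_sd < 0) {
    abort("noise SDs must be nonnegative")
  }
  attribution <- attribution %||% default_attribution(n_components, n_herbs)
  attribution <- as.matrix(attribution)
  if (!all(dim(attribution) == c(n_components, n_herbs))) {
    abort("`attribution` must be n_components x n_herbs")
  }
  if (any(attribution < 0) || any(rowSums(attribution) == 0)) {
    abort("`attribution` must be nonnegative with at least one nonzero entry per component")
  }
  effect_matrix <- effect_matrix %||% default_effect_matrix(n_indices, n_components)
  effect_matrix <- as.matrix(effect_matrix)
  if (!all(dim(effect_matrix) == c(n_indices, n_components))) {
    abort("`effect_matrix` must be n_indices x n_components")
  }
  baseline <- rep_len(baseline, n_indices)
  cfg <- list(
    n_samples = as.integer(n_samples), n_herbs = as.integer(n_herbs),
    n_components = as.integer(n_components), n_indices = as.integer(n_indices),
    attribution = attribution, effect_matrix = effect_matrix,
    baseline = baseline,
    control_offset = rep_len(control_offset, n_indices),
    model_offset = rep_len(model_offset, n_indices),
    fingerprint_noise_sd = fingerprint_noise_sd,
    index_noise_sd = index_noise_sd,
    animals_per_group = as.integer(animals_per_group),
    seed = as.integer(seed)
  )
  structure(cfg, class = "simulation_config")
}

#' Default herb attribution of fingerprint components
#'
#' Components sweep the composition range from (nearly) pure herb 1 to
#' (nearly) pure herb 2: component k sits at angle
#' \eqn{\theta_k = (k-1)/(m-1) \cdot \pi/2} on the two-herb simplex with a
#' common magnitude of 10 area units per dose unit. With more than two herbs
#' the mass is split evenly; supply an explicit matrix for richer chemistry.
#'
#' @param n_components,n_herbs Shape of the matrix.
#' @return Nonnegative `n_components x n_herbs` matrix.
#' @export
default_attribution <- function(n_components, n_herbs = 2) {
  if (n_herbs == 2) {
    theta <- seq(0, pi / 2, length.out = n_components)
    m <- 10 * cbind(cos(theta), sin(theta))
  } else {
    m <- matrix(10 / n_herbs, n_components, n_herbs)
  }
  rownames(m) <- component_labels(n_components)
  colnames(m) <- paste0("herb_", seq_len(n_herbs))
  m
}

#' Default planted effect matrix
#'
#' A block-sparse coefficient matrix encoding a rank-identifiable planted
#' structure: the indices are split into disjoint consecutive blocks, one per
#' active component, and every index in a block responds to that block's
#' active only (coefficient = `scale`); all inert component columns are zero.
#' Disjoint blocks keep the between-block index correlation at the level of
#' the shared dose signal while within-block indices share the active's full
#' noisy peak series, so factor analysis can align one factor per active —
#' the planted truth the recovery experiments test against.
#'
#' The default scale of 1 index-unit per area-unit swings each affected index
#' by far more than three per-animal noise SDs across the sample range under
#' the default attribution, so every planted effect is detectable from group
#' means.
#'
#' @param n_indices,n_components Shape of the matrix.
#' @param actives Integer ids of active components; default 4 ids spread over
#'   the component range (for 13 components: 2, 5, 9, 12).
#' @param scale Planted coefficient (index units per area unit).
#' @return `n_indices x n_components` matrix with named dims.
#' @export
default_effect_matrix <- function(n_indices, n_components,
                                  actives = NULL, scale = 1) {
  actives <- actives %||% unique(round(seq(2, n_components - 1, length.out = 4)))
  if (any(actives < 1 | actives > n_components)) {
    abort("`actives` out of component range")
  }
  n_act <- length(actives)
  if (n_indices < n_act) abort("need at least one index per active component")
  B <- matrix(0, n_indices, n_components)
  # split indices into n_act disjoint consecutive blocks, sizes as equal as
  # possible (for 10 indices, 4 actives: 2, 3, 2, 3)
  sizes <- rep(n_indices %/% n_act, n_act)
  extra <- n_indices - sum(sizes)
  if (extra > 0) {
    pref <- c(seq_len(n_act)[seq_len(n_act) %% 2 == 0],
              seq_len(n_act)[seq_len(n_act) %% 2 == 1])
    sizes[pref[seq_len(extra)]] <- sizes[pref[seq_len(extra)]] + 1
  }
  stop_at <- cumsum(sizes)
  start_at <- c(1, head(stop_at, -1) + 1)
  for (b in seq_len(n_act)) {
    B[start_at[b]:stop_at[b], actives[b]] <- scale
  }
  rownames(B) <- index_labels(n_indices)
  colnames(B) <- component_labels(n_components)
  B
}

index_labels <- function(n) paste0("I", seq_len(n))

#' Simulate fingerprint peak areas from a design
#'
#' Peak area of component k in sample i is
#' \eqn{(\sum_h c_{kh} \, dose_h(i)) \cdot e^{\varepsilon}},
#' \eqn{\varepsilon \sim N(0, \sigma_f)}: linear chemistry with multiplicative
#' lognormal instrument/preparation error, so areas stay strictly positive.
#'
#' @param design A `design_table` (levels are used as doses via
#'   [design_doses()]).
#' @param config A [simulation_config()].
#' @return A fingerprint tibble: `sample_id`, then one positive peak-area
#'   column per component (P1..Pm).
#' @export
simulate_fingerprints <- function(design, config) {
  stopifnot(inherits(config, "simulation_config"))
  doses <- design_doses(design)
  dm <- wide_to_matrix(doses)
  if (ncol(dm) != ncol(config$attribution)) {
    abort("design factor count does not match attribution herb count")
  }
  if (nrow(dm) != config$n_samples) {
    abort("design run count does not match `n_samples`")
  }
  signal <- dm %*% t(config$attribution) # samples x components
  if (any(signal <= 0)) abort("attribution produced a nonpositive expected peak area")
  noise <- withr::with_seed(config$seed, {
    matrix(rnorm(length(signal), 0, config$fingerprint_noise_sd),
           nrow(signal), ncol(signal))
  })
  peaks <- signal * exp(noise)
  colnames(peaks) <- component_labels(config$n_components)
  dplyr::bind_cols(tibble::tibble(sample_id = s_labels(nrow(peaks))),
                   tibble::as_tibble(peaks))
}

#' Simulate a per-animal pharmacology panel from fingerprints
#'
#' Each animal in sample group i gets, for index j,
#' \eqn{\mu_j + \sum_k B_{jk}\,peak_k(i) + N(0, \sigma_y)}. Control and model
#' groups are emitted with their configured additive offsets and no component
#' effects, so the downstream table has the same group structure as a
#' formulation-variant animal experiment.
#'
#' @param fingerprints Fingerprint tibble from [simulate_fingerprints()].
#' @param config A [simulation_config()].
#' @return Per-animal tibble: `group_id`, `animal_id`, then one column per
#'   index (I1..Ip).
#' @export
simulate_pharmacology <- function(fingerprints, config) {
  stopifnot(inherits(config, "simulation_config"))
  peaks <- wide_to_matrix(fingerprints)
  if (ncol(peaks) != ncol(config$effect_matrix)) {
    abort("effect_matrix columns do not match fingerprint components")
  }
  if (is.null(config$baseline) || anyNA(config$baseline)) abort("missing baseline")
  if (config$animals_per_group < 1) abort("negative or zero animals_per_group")
  mu <- config$baseline
  group_signal <- rbind(
    control = mu + config$control_offset,
    model = mu + config$model_offset,
    sweep(peaks %*% t(config$effect_matrix), 2, mu, `+`)
  )
  a <- config$animals_per_group
  withr::with_seed(config$seed + 1L, {
    rows <- purrr::map(rownames(group_signal), function(g) {
      vals <- matrix(rep(group_signal[g, ], each = a), nrow = a) +
        matrix(rnorm(a * length(mu), 0, config$index_noise_sd), nrow = a)
      colnames(vals) <- index_labels(length(mu))
      dplyr::bind_cols(
        tibble::tibble(group_id = g, animal_id = seq_len(a)),
        tibble::as_tibble(vals)
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Simulate a complete synthetic study
#'
#' Bundles the uniform design (from [search_design()]), fingerprints,
#' pharmacology, and the planted ground truth into one reproducible object.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_study` list: `design`, `fingerprints`,
#'   `pharmacology`, `truth`, `seed`. `truth` records the active component
#'   set, the per-index signed active map, and a copy of the effect matrix.
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  design <- search_design(config$n_samples, config$n_herbs)
  fingerprints <- simulate_fingerprints(design, config)
  pharmacology <- simulate_pharmacology(fingerprints, config)
  B <- config$effect_matrix
  comp <- component_labels(config$n_components)
  active <- comp[colSums(B != 0) > 0]
  per_index <- purrr::map(seq_len(nrow(B)), function(j) {
    k <- which(B[j, ] != 0)
    setNames(sign(B[j, k]), comp[k])
  })
  names(per_index) <- index_labels(config$n_indices)
  structure(list(
    design = design,
    fingerprints = fingerprints,
    pharmacology = pharmacology,
    truth = list(active_components = active,
                 per_index_actives = per_index,
                 effect_matrix = B),
    seed = config$seed
  ), class = "synthetic_study")
}

#' Write a synthetic study to plain-text fixture files
#'
#' Writes `design.csv`, `fingerprints.csv`, `pharmacology.csv` and a sidecar
#' `truth.json` so tests never re-derive the planted structure.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("design.csv", "fingerprints.csv",
                            "pharmacology.csv", "truth.json"))
  utils::write.csv(study$design, paths[1], row.names = FALSE)
  utils::write.csv(study$fingerprints, paths[2], row.names = FALSE)
  utils::write.csv(study$pharmacology, paths[3], row.names = FALSE)
  truth <- study$truth
  truth$effect_matrix <- as.data.frame(truth$effect_matrix)
  jsonlite::write_json(truth, paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
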