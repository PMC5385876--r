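test_that("zero-noise single-herb fingerprints equal the dose column", {
  d <- glp_design(9, 1) # levels 1..9 in order
  cfg <- simulation_config(
    n_samples = 9, n_herbs = 2, n_components = 2, n_indices = 2,
    attribution = rbind(c(1, 0), c(0, 1)),
    effect_matrix = matrix(0, 2, 2),
    fingerprint_noise_sd = 0, seed = 1
  )
  d2 <- glp_design(9, c(1, 2))
  fp <- simulate_fingerprints(d2, cfg)
  expect_equal(fp$P1, as.numeric(d2$f1))
  expect_equal(fp$P2, as.numeric(d2$f2))
})

test_that("the same config and seed reproduce the study bit-for-bit", {
  cfg <- simulation_config(seed = 42)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$fingerprints, s2$fingerprints)
  expect_identical(s1$pharmacology, s2$pharmacology)
  # different seeds share the deterministic design but differ in noise
  s3 <- simulate_study(simulation_config(seed = 43))
  expect_identical(tibble::as_tibble(s1$design), tibble::as_tibble(s3$design))
  expect_false(identical(s1$fingerprints, s3$fingerprints))
})

test_that("zero-noise two-herb peaks are exact linear combinations of doses", {
  cfg <- simulation_config(fingerprint_noise_sd = 0, seed = 5)
  design <- search_design(9, 2)
  fp <- simulate_fingerprints(design, cfg)
  doses <- as.matrix(design_doses(design)[, -1])
  # least-squares oracle: residuals of peak ~ doses are zero
  for (p in paste0("P", 1:13)) {
    fit <- lm(fp[[p]] ~ doses)
    expect_lt(max(abs(residuals(fit))), 1e-9)
  }
})

test_that("null effect matrix with zero noise returns baselines everywhere", {
  cfg <- simulation_config(effect_matrix = matrix(0, 10, 13),
                           index_noise_sd = 0, baseline = 100, seed = 2)
  st <- simulate_study(cfg)
  gm <- group_means(st$pharmacology)
  s_rows <- gm$means$group_id %in% paste0("S", 1:9)
  expect_true(all(abs(as.matrix(gm$means[s_rows, -1]) - 100) < 1e-9))
  expect_equal(unname(unlist(gm$means[gm$means$group_id == "control", -1])),
               rep(120, 10))
  expect_equal(unname(unlist(gm$means[gm$means$group_id == "model", -1])),
               rep(80, 10))
})

test_that("one planted active with zero noise forces exact collinearity", {
  B <- matrix(0, 10, 13)
  B[1, 3] <- 2
  cfg <- simulation_config(effect_matrix = B, index_noise_sd = 0, seed = 3)
  st <- simulate_study(cfg)
  gm <- group_means(st$pharmacology)
  s_means <- gm$means[match(paste0("S", 1:9), gm$means$group_id), ]
  expect_equal(unname(cor(s_means$I1, st$fingerprints$P3)), 1, tolerance = 1e-12)
})

test_that("planted group means equal the matrix-arithmetic oracle", {
  cfg <- simulation_config(index_noise_sd = 0, seed = 8)
  st <- simulate_study(cfg)
  peaks <- as.matrix(st$fingerprints[, -1])
  expected <- sweep(peaks %*% t(cfg$effect_matrix), 2, cfg$baseline, `+`)
  gm <- group_means(st$pharmacology)
  s_means <- as.matrix(gm$means[match(paste0("S", 1:9), gm$means$group_id), -1])
  expect_equal(unname(s_means), unname(expected), tolerance = 1e-9)
})

test_that("ground truth bookkeeping matches the configured active set", {
  st <- simulate_study(simulation_config(seed = 1))
  expect_equal(st$truth$active_components, recovery_actives)
  per_index <- st$truth$per_index_actives
  expect_equal(sort(unique(unlist(lapply(per_index, names)))),
               sort(recovery_actives))
  # every per-index active has a nonzero entry in the stored matrix
  for (ix in names(per_index)) {
    for (p in names(per_index[[ix]])) {
      expect_true(st$truth$effect_matrix[ix, p] != 0)
    }
  }
})

test_that("fingerprint entries are strictly positive and shapes are consistent", {
  st <- simulate_study(simulation_config(seed = 10))
  expect_true(all(as.matrix(st$fingerprints[, -1]) > 0))
  expect_equal(nrow(st$fingerprints), 9)
  expect_equal(ncol(st$fingerprints), 14)
  expect_equal(nrow(st$pharmacology), (9 + 2) * 10)
  expect_equal(sort(unique(st$pharmacology$group_id)),
               sort(c("control", "model", paste0("S", 1:9))))
})

test_that("config validation rejects malformed inputs", {
  expect_error(simulation_config(n_samples = 1), "n_samples")
  expect_error(simulation_config(attribution = matrix(0, 13, 2)), "nonzero")
  expect_error(simulation_config(effect_matrix = matrix(0, 3, 3)),
               "n_indices x n_components")
  expect_error(simulation_config(fingerprint_noise_sd = -1), "nonnegative")
})

test_that("fixture files round-trip through write_study", {
  st <- simulate_study(simulation_config(seed = 6))
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  expect_true(all(file.exists(paths)))
  back <- read_study_csv(dir)
  expect_equal(back$fingerprints, st$fingerprints, tolerance = 1e-12)
  expect_equal(back$pharmacology, st$pharmacology, tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$active_components, st$truth$active_components)
  # byte-identical fixture files under the same config
  dir2 <- withr::local_tempdir()
  write_study(simulate_study(simulation_config(seed = 6)), dir2)
  for (f in c("design.csv", "fingerprints.csv", "pharmacology.csv", "truth.json")) {
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))
  }
})
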