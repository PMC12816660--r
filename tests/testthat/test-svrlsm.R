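# small lesion cohorts for fast unit checks
tiny_masks <- function(n, dims = c(3, 3, 3), seed = 1, k = 4) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    mask_from_idx(sample(prod(dims), k), dims = dims))
}

test_that("voxel inclusion uses ceiling(fraction * n) and is monotone", {
  # n = 82: at least 10% means at least ceil(8.2) = 9 subjects
  masks <- tiny_masks(82, k = 6, seed = 2)
  lm <- build_lesion_matrix(masks, 0.10)
  expect_equal(lm$threshold, 9L)
  counts <- rowSums(vapply(masks, function(m) as.vector(m$data), numeric(27)))
  expect_setequal(lm$included, which(counts >= 9))
  # fraction 0: every lesioned-anywhere voxel enters (threshold floor is 1)
  lm0 <- build_lesion_matrix(masks, 0)
  expect_setequal(lm0$included, which(counts >= 1))
  # monotone: raising the fraction never adds voxels
  prev <- lm0$included
  for (f in c(0.05, 0.1, 0.2, 0.4)) {
    cur <- tryCatch(build_lesion_matrix(masks, f)$included, error = function(e) integer(0))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  # single shared voxel
  shared <- lapply(1:5, function(i) mask_from_idx(c(1, i + 1), dims = c(3, 3, 3)))
  lm1 <- build_lesion_matrix(shared, 1.0)
  expect_equal(ncol(lm1$X), 1L)
  expect_error(build_lesion_matrix(tiny_masks(2, k = 1, seed = 3), 1.0),
               "no voxel")
})

test_that("dTLVC scales rows by inverse sqrt volume and preserves zeros", {
  X <- rbind(c(1, 1, 1, 1), c(1, 1, 0, 0))
  vol <- c(4, 100)   # volumes over the whole mask
  S <- apply_dtlvc(X, vol)
  expect_equal(S[1, ], rep(0.5, 4))
  expect_equal(S[2, ], c(0.1, 0.1, 0, 0))
  expect_equal(S == 0, X == 0)
  # idempotent only at volume 1
  expect_equal(apply_dtlvc(matrix(1, 1, 2), 1), matrix(1, 1, 2))
  expect_error(apply_dtlvc(X, c(4, 0)), "zero lesion volume")
})

test_that("behaviour residualization removes covariate structure", {
  set.seed(12)
  n <- 200
  age <- rnorm(n, 45, 12)
  planted <- rnorm(n)
  score <- planted + 2 * age
  r <- residualize_behaviour(score, data.frame(age = age))
  expect_lt(abs(cor(r, age)), 1e-9)          # exactly orthogonal by OLS
  expect_gt(cor(r, planted), 0.9)
  # score exactly linear in age: residuals vanish
  r0 <- residualize_behaviour(3 + 2 * age, data.frame(age = age))
  expect_lt(max(abs(r0)), 1e-9)
  # zero-variance covariate dropped with a warning, leaving centring
  expect_warning(rc <- residualize_behaviour(score, data.frame(k = rep(1, n))),
                 "zero-variance")
  expect_equal(rc, score - mean(score), tolerance = 1e-12)
  expect_error(residualize_behaviour(score, data.frame(a = age, b = 2 * age)),
               "rank-deficient")
})

test_that("SVR beta back-projection localizes a planted effect and is deterministic", {
  set.seed(13)
  n <- 60; V <- 40
  X <- matrix(rbinom(n * V, 1, 0.3), n, V)
  X[, 7] <- rbinom(n, 1, 0.5)
  score <- 2 * X[, 7]                        # noiseless single-voxel effect
  vol <- pmax(rowSums(X), 1)
  Xs <- apply_dtlvc(X, vol)
  b <- fit_svrlsm_beta(Xs, score - mean(score), C = 10, sigma = 3,
                       epsilon = 0.1)$beta
  expect_equal(which.max(abs(b)), 7L)
  expect_gt(b[7], 0)                         # worsening direction is positive
  b2 <- fit_svrlsm_beta(Xs, score - mean(score), C = 10, sigma = 3,
                        epsilon = 0.1)$beta
  expect_identical(b, b2)
  expect_error(fit_svrlsm_beta(Xs, rep(1, n), 10, 3, 0.1), "constant")
})

test_that("hyperparameter search is seeded, in range, and flags degenerate fits", {
  set.seed(14)
  X <- matrix(rbinom(40 * 20, 1, 0.4), 40, 20)
  score <- X[, 3] + rnorm(40, 0, 0.5)
  cfg <- svrlsm_config(n_opt_iterations = 8, seed = 99)
  h1 <- optimize_hyperparameters(apply_dtlvc(X, pmax(rowSums(X), 1)),
                                 score - mean(score), cfg)
  h2 <- optimize_hyperparameters(apply_dtlvc(X, pmax(rowSums(X), 1)),
                                 score - mean(score), cfg)
  expect_equal(h1[c("C", "sigma", "epsilon")], h2[c("C", "sigma", "epsilon")])
  expect_gte(h1$C, 1); expect_lte(h1$C, 80)
  expect_gte(h1$sigma, 0.1); expect_lte(h1$sigma, 30)
})

test_that("permutation p-values follow the add-one formula and are valid under the null", {
  set.seed(15)
  n <- 30; V <- 15
  X <- matrix(rbinom(n * V, 1, 0.4), n, V)
  Xs <- apply_dtlvc(X, pmax(rowSums(X), 1))
  score <- rnorm(n); score <- score - mean(score)
  expect_error(permutation_pmap(Xs, score, list(C = 5, sigma = 2, epsilon = 0.2),
                                n_permutations = 10), "at least 20")
  expect_warning(pm <- permutation_pmap(Xs, score,
                                        list(C = 5, sigma = 2, epsilon = 0.2),
                                        n_permutations = 99, seed = 5),
                 "coarse")
  expect_true(all(pm$p >= 1 / 100 & pm$p <= 1))
  # p = (1 + #{perm >= obs}) / (n + 1): reconstruct from retained maps
  exceed <- colSums(sweep(pm$perm_beta, 2, pm$beta, ">="))
  expect_equal(pm$p, (1 + exceed) / 100)
  # null p-values are approximately uniform across voxels
  ks <- suppressWarnings(ks.test(pm$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("CFWER keeps significant voxels inside the included set and respects limits", {
  set.seed(16)
  n <- 30; dims <- c(5, 5, 5)
  masks <- tiny_masks(n, dims = dims, seed = 16, k = 30)
  lm <- build_lesion_matrix(masks, 0.10)
  Xs <- apply_dtlvc(lm$X, lm$total_volumes)
  score <- rnorm(n); score <- score - mean(score)
  pm <- suppressWarnings(permutation_pmap(Xs, score,
                                          list(C = 5, sigma = 2, epsilon = 0.2),
                                          n_permutations = 60, seed = 6))
  cf <- cfwer_threshold(pm, lm$included, lm$included_mask, alpha = 0.05, v = 1)
  expect_true(all(which(cf$mask$data != 0) %in% lm$included))
  expect_error(cfwer_threshold(pm, lm$included, lm$included_mask,
                               v = length(pm$p)), "smaller")
  # alpha -> 1: the critical pair is the loosest recorded, voxel_p dominates
  cf1 <- cfwer_threshold(pm, lm$included, lm$included_mask, alpha = 0.999,
                         v = 1, voxel_p = 0.999)
  expect_gte(sum(cf1$significant), sum(cf$significant))
})

test_that("reproducibility index separates lesion-driven from noise scores", {
  half <- tiny_masks(12, dims = c(4, 4, 4), seed = 18, k = 10)
  masks <- c(half, half)                     # duplicated cohort
  lm <- build_lesion_matrix(masks, 0.10)
  Xs <- apply_dtlvc(lm$X, lm$total_volumes)
  # score an exact function of the lesions: half-fits estimate the same map
  score <- as.numeric(lm$X[, 3]) * 2 + as.numeric(lm$X[, 7])
  r_sig <- reproducibility_index(Xs, score - mean(score),
                                 list(C = 5, sigma = 3, epsilon = 0.1),
                                 n_splits = 5, seed = 7)
  set.seed(17)
  r_noise <- reproducibility_index(Xs, rnorm(24),
                                   list(C = 5, sigma = 3, epsilon = 0.1),
                                   n_splits = 10, seed = 7)
  expect_gt(as.numeric(r_sig), as.numeric(r_noise))
  expect_lt(abs(as.numeric(r_noise)), 0.35)
  expect_error(reproducibility_index(Xs[1:10, ], score[1:10],
                                     list(C = 5, sigma = 3, epsilon = 0.1)),
               "n >= 20")
})

test_that("atlas overlap percentages per parcel and network", {
  parc <- voxel_image(array(rep(1:2, each = 32), c(4, 4, 4)))
  cl <- mask_from_idx(1:8, dims = c(4, 4, 4))
  ov <- atlas_overlap(cl, parc)
  expect_equal(ov$per_parcel$overlap_pct[ov$per_parcel$label == 1], 25)
  expect_equal(ov$per_parcel$overlap_pct[ov$per_parcel$label == 2], 0)
  # cluster equals parcel: 100%
  cl2 <- mask_from_idx(1:32, dims = c(4, 4, 4))
  ov2 <- atlas_overlap(cl2, parc,
                       networks = data.frame(label = 1:2,
                                             parcel_name = c("p1", "p2"),
                                             network_name = c("DAN", "VAN")))
  expect_equal(ov2$per_parcel$overlap_pct[ov2$per_parcel$label == 1], 100)
  expect_equal(ov2$per_network$overlap_pct[ov2$per_network$network_name == "DAN"], 100)
  expect_equal(ov2$per_network$overlap_pct[ov2$per_network$network_name == "VAN"], 0)
  bad <- voxel_image(array(1L, c(3, 3, 3)))
  expect_error(atlas_overlap(cl, bad), "grid")
})

test_that("end-to-end svrlsm object exposes maps, hyperparameters and methods", {
  spec <- synth_spec(seed = 21, lesion = list(n_subjects = 30L,
                                              grid_shape = c(8L, 8L, 8L),
                                              blob_radius_range = c(1.5, 3),
                                              planted_centre = c(4, 4, 4),
                                              planted_radius = 1.6))
  coh <- make_lesion_cohort(spec)
  fit <- suppressWarnings(svrlsm(
    coh$masks, coh$behaviour$delta_asymmetry_cont,
    covariates = coh$behaviour[, c("age", "education", "grade")],
    config = svrlsm_config(n_permutations = 60, n_opt_iterations = 6,
                           n_splits = 3, seed = 21)))
  expect_s3_class(fit, "svrlsm")
  expect_true(all(fit$p_values > 0 & fit$p_values <= 1))
  expect_equal(length(coef(fit)), length(fit$included))
  expect_output(print(fit), "svrlsm")
  expect_output(summary(fit), "accuracy")
  # maps are NA outside the included mask, filled inside
  inc <- fit$included_voxel_mask$data == 1
  expect_true(all(!is.na(fit$beta_map$data[inc])))
  expect_true(all(is.na(fit$beta_map$data[!inc])))
  # determinism: same config, same seed, same maps
  fit2 <- suppressWarnings(svrlsm(
    coh$masks, coh$behaviour$delta_asymmetry_cont,
    covariates = coh$behaviour[, c("age", "education", "grade")],
    config = svrlsm_config(n_permutations = 60, n_opt_iterations = 6,
                           n_splits = 3, seed = 21)))
  expect_identical(fit$beta_values, fit2$beta_values)
  expect_identical(fit$p_values, fit2$p_values)
})
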