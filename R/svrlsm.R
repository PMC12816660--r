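#' Configuration for SVR-LSM
#'
#' Defaults follow common practice for multivariate lesion-symptom mapping
#' with an RBF-kernel support vector regression: voxels resected in at least
#' `min_lesion_fraction` of the cohort enter the model; lesion volume is
#' controlled by dTLVC; inference uses permutation of the behavioural score
#' with continuum family-wise error (CFWER) correction.
#'
#' @param min_lesion_fraction minimum fraction of subjects lesioned at a
#'   voxel for inclusion (default 0.10); threshold is `ceiling(fraction * n)`.
#' @param C_range box-constraint search range (default c(1, 80)).
#' @param sigma_range RBF kernel scale search range (default c(0.1, 30));
#'   the libsvm `gamma` is `1 / (2 * sigma^2)`.
#' @param epsilon_range epsilon-insensitive band search range; `NULL` (the
#'   default) uses `c(1e-3, 1e2) * IQR(score) / 1.349` (the robust-sd-scaled
#'   default range of common SVR tooling), sampled log-uniformly.
#' @param n_permutations permutations for voxelwise p-values (default 5000).
#' @param voxel_p voxelwise threshold applied before cluster correction
#'   (default 0.005).
#' @param cfwer_alpha family-wise alpha (default 0.05).
#' @param cfwer_v CFWER v parameter: control is over the v-th most extreme
#'   voxelwise p (default 1).
#' @param n_folds cross-validation folds for hyperparameter search (default 5).
#' @param n_opt_iterations points evaluated by the seeded random
#'   hyperparameter search (default 200).
#' @param n_splits half-split repetitions for the reproducibility index
#'   (default 10).
#' @param two_tailed use two-tailed permutation p-values (default FALSE:
#'   one-tailed in the direction associating lesion with worsening).
#' @param seed integer seed driving all randomness (permutations, folds,
#'   search, splits) through derived substreams.
#' @return list of class `svrlsm_config`.
#' @export
svrlsm_config <- function(min_lesion_fraction = 0.10,
                          C_range = c(1, 80),
                          sigma_range = c(0.1, 30),
                          epsilon_range = NULL,
                          n_permutations = 5000L,
                          voxel_p = 0.005,
                          cfwer_alpha = 0.05,
                          cfwer_v = 1L,
                          n_folds = 5L,
                          n_opt_iterations = 200L,
                          n_splits = 10L,
                          two_tailed = FALSE,
                          seed = 1L) {
  stopifnot(voxel_p > 0, voxel_p < 1, cfwer_v >= 1,
            diff(range(C_range)) >= 0, diff(range(sigma_range)) >= 0)
  structure(list(min_lesion_fraction = min_lesion_fraction,
                 C_range = C_range, sigma_range = sigma_range,
                 epsilon_range = epsilon_range,
                 n_permutations = as.integer(n_permutations),
                 voxel_p = voxel_p, cfwer_alpha = cfwer_alpha,
                 cfwer_v = as.integer(cfwer_v),
                 n_folds = as.integer(n_folds),
                 n_opt_iterations = as.integer(n_opt_iterations),
                 n_splits = as.integer(n_splits),
                 two_tailed = two_tailed, seed = as.integer(seed)),
            class = "svrlsm_config")
}

# derive a reproducible substream seed; keeps results invariant to the order
# in which stages consume randomness
substream_seed <- function(seed, stage) {
  offsets <- c(folds = 1000L, search = 2000L, perm = 3000L, split = 4000L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Subjects-by-voxels lesion matrix with the inclusion mask
#'
#' A voxel is included iff it is lesioned in at least
#' `ceiling(min_lesion_fraction * n)` subjects. Columns are ordered by the
#' linear (column-major, x fastest) voxel index of the shared grid.
#'
#' @param masks list of `voxel_image` binary masks on a shared grid.
#' @param min_lesion_fraction inclusion fraction.
#' @return list with `X` (n x V binary matrix), `included` (linear voxel
#'   indices of the columns), `included_mask` (`voxel_image`), `threshold`.
#' @export
build_lesion_matrix <- function(masks, min_lesion_fraction = 0.10) {
  n <- length(masks)
  if (n < 2L) stop("need at least 2 subjects")
  ref <- masks[[1]]
  for (m in masks) {
    if (!same_grid(ref, m)) stop("lesion masks do not share a grid")
    if (!all(m$data %in% c(0, 1))) stop("masks must be binary")
  }
  flat <- vapply(masks, function(m) as.vector(m$data), numeric(length(ref$data)))
  counts <- rowSums(flat)
  thr <- max(1L, ceiling(min_lesion_fraction * n))
  included <- which(counts >= thr)
  if (length(included) == 0L) {
    stop(sprintf(paste0("no voxel is lesioned in >= %d of %d subjects; ",
                        "max overlap is %d"), thr, n, max(counts)))
  }
  inc_mask <- array(0L, dim(ref$data)); inc_mask[included] <- 1L
  list(X = t(flat[included, , drop = FALSE]),
       included = included,
       included_mask = voxel_image(inc_mask, ref$affine, ref$space_tag),
       threshold = thr,
       total_volumes = colSums(flat))
}

#' Direct total lesion volume control (dTLVC)
#'
#' Scales each subject's lesion vector by 1/sqrt(total lesion volume in
#' voxels), computed over the whole mask (not only included columns), so
#' larger resections do not dominate the kernel purely through size.
#'
#' @param X n x V binary lesion matrix.
#' @param total_volumes per-subject total lesion volume in voxels.
#' @return scaled numeric matrix.
#' @export
apply_dtlvc <- function(X, total_volumes) {
  stopifnot(nrow(X) == length(total_volumes))
  if (any(total_volumes <= 0)) stop("subject with zero lesion volume")
  X * (1 / sqrt(total_volumes))
}

#' Residualize a behavioural score on nuisance covariates
#'
#' Ordinary least-squares residuals of the score on an intercept plus the
#' covariate columns. Zero-variance covariates are dropped with a warning.
#'
#' @param score numeric vector.
#' @param covariates data frame or matrix of covariates (may be NULL).
#' @return residual vector (centred score when no covariates remain).
#' @export
residualize_behaviour <- function(score, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0L)
    return(score - mean(score))
  Z <- as.matrix(covariates)
  keep <- apply(Z, 2, function(z) stats::sd(z) > 0)
  if (!all(keep)) {
    warning("dropping zero-variance covariate(s): ",
            paste(colnames(Z)[!keep], collapse = ", "))
    Z <- Z[, keep, drop = FALSE]
  }
  if (ncol(Z) == 0L) return(score - mean(score))
  qrd <- qr(cbind(1, Z))
  if (qrd$rank < ncol(Z) + 1L) stop("rank-deficient covariate design")
  unname(stats::lsfit(Z, score)$residuals)
}

#' Fit the epsilon-SVR and back-project voxelwise beta weights
#'
#' RBF-kernel epsilon-SVR (libsvm via e1071) fitted on all subjects; the
#' voxelwise beta map is the back-projection `t(X) %*% alpha` of the
#' sign-carrying dual coefficients, the convention used by SVR-LSM toolboxes
#' for nonlinear kernels.
#'
#' @param X scaled lesion matrix (n x V).
#' @param score adjusted behavioural score.
#' @param C,sigma,epsilon SVR hyperparameters (`gamma = 1 / (2 sigma^2)`).
#' @return list with `beta` (length V) and the fitted `model`.
#' @export
fit_svrlsm_beta <- function(X, score, C, sigma, epsilon) {
  if (stats::sd(score) == 0) stop("constant score: SVR degenerate")
  fit <- e1071::svm(x = X, y = score, type = "eps-regression",
                    kernel = "radial", gamma = 1 / (2 * sigma^2),
                    cost = C, epsilon = epsilon, scale = FALSE,
                    fitted = FALSE)
  alpha <- numeric(nrow(X))
  alpha[fit$index] <- fit$coefs
  list(beta = drop(crossprod(X, alpha)), model = fit, alpha = alpha)
}

svr_predict <- function(Xtrain, score, Xtest, C, sigma, epsilon) {
  fit <- e1071::svm(x = Xtrain, y = score, type = "eps-regression",
                    kernel = "radial", gamma = 1 / (2 * sigma^2),
                    cost = C, epsilon = epsilon, scale = FALSE,
                    fitted = FALSE)
  if (fit$tot.nSV == 0L)   # band swallowed every residual: constant fit
    return(rep(mean(score), nrow(Xtest)))
  stats::predict(fit, Xtest)
}

#' Hyperparameter search with cross-validated accuracy
#'
#' Seeded random search over log-uniform C and sigma and a uniform epsilon
#' range, scoring each candidate by k-fold cross-validation. Accuracy is the
#' mean (with sd) across folds of the Pearson correlation between out-of-fold
#' predictions and scores; the selected candidate minimizes cross-validated
#' mean squared error. Deterministic given the config seed.
#'
#' @param X scaled lesion matrix.
#' @param score adjusted score.
#' @param config an [svrlsm_config()].
#' @return list with `C`, `sigma`, `epsilon`, `accuracy`, `accuracy_sd`,
#'   `cv_mse`.
#' @export
optimize_hyperparameters <- function(X, score, config = svrlsm_config()) {
  n <- nrow(X)
  eps_range <- config$epsilon_range
  if (is.null(eps_range)) {
    iqr <- stats::IQR(score)
    if (iqr == 0) iqr <- stats::sd(score)
    eps_range <- c(1e-3, 1e2) * iqr / 1.349
  }
  rng_state <- local_rng(substream_seed(config$seed, "search"))
  on.exit(restore_rng(rng_state), add = TRUE)
  k <- config$n_folds
  folds <- sample(rep_len(seq_len(k), n))
  cand <- data.frame(
    C = exp(stats::runif(config$n_opt_iterations,
                         log(config$C_range[1]), log(config$C_range[2]))),
    sigma = exp(stats::runif(config$n_opt_iterations,
                             log(config$sigma_range[1]), log(config$sigma_range[2]))),
    epsilon = exp(stats::runif(config$n_opt_iterations,
                               log(eps_range[1]), log(eps_range[2]))))
  stats_i <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    pred <- numeric(n)
    rfold <- msefold <- numeric(k)
    for (f in seq_len(k)) {
      te <- folds == f
      p <- svr_predict(X[!te, , drop = FALSE], score[!te],
                       X[te, , drop = FALSE],
                       cand$C[i], cand$sigma[i], cand$epsilon[i])
      pred[te] <- p
      msefold[f] <- mean((p - score[te])^2)
      rfold[f] <- if (stats::sd(p) == 0 || stats::sd(score[te]) == 0) NA_real_
                  else stats::cor(p, score[te])
    }
    stats_i[[i]] <- list(cv_mse = mean(msefold),
                         cv_mse_se = stats::sd(msefold) / sqrt(k),
                         accuracy = mean(rfold, na.rm = TRUE),
                         accuracy_sd = stats::sd(rfold, na.rm = TRUE),
                         accuracy_undefined = all(is.na(rfold)))
  }
  # the cross-validated loss is 1 - accuracy, where accuracy is the mean
  # out-of-fold Pearson correlation between predictions and scores — the
  # model-quality index such mapping studies report. Correlation is
  # scale-free, so the loss does not punish the shrinkage of strongly
  # regularized fits, whose tight permutation nulls the beta-map inference
  # depends on.
  loss <- vapply(stats_i, function(s)
    if (s$accuracy_undefined) Inf else 1 - s$accuracy, 0)
  loss_se <- vapply(stats_i, function(s)
    if (s$accuracy_undefined) Inf else s$accuracy_sd / sqrt(k), 0)
  ibest <- which.min(loss)
  # one-standard-error rule: among candidates statistically
  # indistinguishable from the best, take the most regularized (smallest C);
  # guards against the winner's-curse selection of extreme, interpolating
  # fits, whose erratic permutation nulls degrade the beta-map inference
  within1se <- which(loss <= loss[ibest] + loss_se[ibest])
  isel <- within1se[order(cand$C[within1se], -cand$epsilon[within1se])][1]
  c(list(C = cand$C[isel], sigma = cand$sigma[isel],
         epsilon = cand$epsilon[isel]), stats_i[[isel]])
}

#' Permutation p-map for the observed beta map
#'
#' The behavioural score is permuted `n_permutations` times; the full SVR is
#' refitted per permutation and voxelwise one-tailed p-values are computed as
#' `(1 + #{permuted beta >= observed}) / (n + 1)` in the direction
#' associating lesion with worsening (larger beta). Two-tailed p-values use
#' |beta|. The permutation beta maps are retained for CFWER.
#'
#' @param X scaled lesion matrix.
#' @param score adjusted score.
#' @param hyper list with `C`, `sigma`, `epsilon`.
#' @param n_permutations number of permutations (>= 20; < 100 warns).
#' @param seed substream seed.
#' @param two_tailed two-tailed flag.
#' @return list with `p` (length V), `beta` (observed), `perm_beta`
#'   (n_permutations x V matrix).
#' @export
permutation_pmap <- function(X, score, hyper, n_permutations = 5000L,
                             seed = 1L, two_tailed = FALSE) {
  if (n_permutations < 20L) stop("need at least 20 permutations")
  if (n_permutations < 100L) warning("fewer than 100 permutations: p-values are coarse")
  obs <- fit_svrlsm_beta(X, score, hyper$C, hyper$sigma, hyper$epsilon)$beta
  rng_state <- local_rng(seed)
  on.exit(restore_rng(rng_state), add = TRUE)
  V <- ncol(X)
  perm_beta <- matrix(0, n_permutations, V)
  for (b in seq_len(n_permutations)) {
    sp <- sample(score)
    perm_beta[b, ] <- fit_svrlsm_beta(X, sp, hyper$C, hyper$sigma,
                                      hyper$epsilon)$beta
  }
  stat_obs <- if (two_tailed) abs(obs) else obs
  stat_perm <- if (two_tailed) abs(perm_beta) else perm_beta
  exceed <- colSums(sweep(stat_perm, 2, stat_obs, ">="))
  p <- (1 + exceed) / (n_permutations + 1)
  list(p = p, beta = obs, perm_beta = perm_beta, two_tailed = two_tailed)
}

# voxelwise p of each map (observed + permutations) against the pooled
# ensemble, by descending rank of the test statistic
pooled_pvalues <- function(stat_all) {
  n_all <- nrow(stat_all)
  apply(stat_all, 2, function(col) {
    (n_all + 1 - rank(col, ties.method = "min")) / n_all
  })
}

#' CFWER critical p and the significant-voxel mask
#'
#' Continuum family-wise error correction: the observed and permutation beta
#' maps are pooled; each map's voxelwise p is its rank against the ensemble.
#' For every permutation map the v-th smallest p (ties broken by larger
#' |beta|) is recorded, and the critical value is the alpha-quantile of that
#' distribution. Observed voxels at or below the critical (p, |beta|) pair
#' that also pass the voxelwise threshold form the significant mask, labelled
#' into 26-connectivity clusters.
#'
#' @param perm result of [permutation_pmap()].
#' @param included linear voxel indices of the map columns.
#' @param grid a `voxel_image` providing the grid (dims + affine).
#' @param alpha family-wise alpha.
#' @param v CFWER v (control over the v-th most extreme voxel).
#' @param voxel_p voxelwise p threshold.
#' @return list with `critical_p`, `significant` (logical per column),
#'   `cluster_labels` (3D array), `mask` (`voxel_image`), `p_pooled`
#'   (observed pooled p per column), `cluster_table`.
#' @export
cfwer_threshold <- function(perm, included, grid, alpha = 0.05, v = 1L,
                            voxel_p = 0.005) {
  V <- length(perm$p)
  if (v >= V) stop("v must be smaller than the number of included voxels")
  stat_obs <- if (perm$two_tailed) abs(perm$beta) else perm$beta
  stat_perm <- if (perm$two_tailed) abs(perm$perm_beta) else perm$perm_beta
  # studentize against the pooled ensemble (observed + permutations) so
  # magnitudes are comparable across voxels; exchangeability is preserved
  # because every map is standardized by the same pooled moments, and the
  # per-voxel rank p-values are unchanged (the transform is monotone)
  all_stat <- rbind(stat_obs, stat_perm)
  mj <- colMeans(all_stat)
  sj <- apply(all_stat, 2, stats::sd)
  sj[sj == 0] <- 1
  all_stat <- sweep(sweep(all_stat, 2, mj), 2, sj, "/")
  p_all <- pooled_pvalues(all_stat)
  n_maps <- nrow(all_stat)
  # v-th smallest (p, -|beta|) pair per permutation map
  vth <- t(vapply(seq.int(2L, n_maps), function(m) {
    o <- order(p_all[m, ], -abs(all_stat[m, ]))[v]
    c(p_all[m, o], -abs(all_stat[m, o]))
  }, numeric(2)))
  # alpha-quantile under lexicographic (p, -|beta|) order
  ord <- order(vth[, 1], vth[, 2])
  k <- max(1L, floor(alpha * (nrow(vth) + 1)))
  crit <- vth[ord[k], ]
  p_obs <- p_all[1, ]
  b_obs <- abs(all_stat[1, ])
  sig <- (p_obs < crit[1] | (p_obs == crit[1] & -b_obs <= crit[2])) &
         p_obs < voxel_p
  mask_arr <- array(0L, dim(grid$data))
  mask_arr[included[sig]] <- 1L
  labels <- label_clusters(mask_arr)
  tab <- NULL
  ncl <- max(labels)
  if (ncl > 0) {
    tab <- do.call(rbind, lapply(seq_len(ncl), function(cl) {
      lin <- which(labels == cl)
      ci <- match(lin, included)
      peak <- lin[which.max(b_obs[ci])]
      pk <- voxel_to_world(grid, arrayInd(peak, dim(grid$data)))
      data.frame(cluster = cl, size = length(lin),
                 peak_x = pk[1], peak_y = pk[2], peak_z = pk[3])
    }))
  }
  list(critical_p = crit[1], critical_pair = crit, significant = sig,
       cluster_labels = labels,
       mask = voxel_image(mask_arr, grid$affine, grid$space_tag),
       p_pooled = p_obs, cluster_table = tab)
}

#' Reproducibility index of the beta map
#'
#' Repeated random half-splits of the cohort; the beta map is fitted on each
#' half and the Pearson correlation between half-maps across included voxels
#' is averaged over splits. Splits yielding a constant score in either half
#' are resampled.
#'
#' @param X scaled lesion matrix (n >= 20).
#' @param score adjusted score.
#' @param hyper hyperparameter list.
#' @param n_splits half-split repetitions (default 10).
#' @param seed substream seed.
#' @return mean correlation across splits (attribute `"per_split"` holds all).
#' @export
reproducibility_index <- function(X, score, hyper, n_splits = 10L, seed = 1L) {
  n <- nrow(X)
  if (n < 20L) stop("need n >= 20 for half-split reproducibility")
  rng_state <- local_rng(seed)
  on.exit(restore_rng(rng_state), add = TRUE)
  rs <- numeric(n_splits)
  for (s in seq_len(n_splits)) {
    repeat {
      h1 <- sample(n, floor(n / 2))
      if (stats::sd(score[h1]) > 0 && stats::sd(score[-h1]) > 0) break
    }
    b1 <- fit_svrlsm_beta(X[h1, , drop = FALSE], score[h1],
                          hyper$C, hyper$sigma, hyper$epsilon)$beta
    b2 <- fit_svrlsm_beta(X[-h1, , drop = FALSE], score[-h1],
                          hyper$C, hyper$sigma, hyper$epsilon)$beta
    rs[s] <- if (stats::sd(b1) == 0 || stats::sd(b2) == 0) NA_real_
             else stats::cor(b1, b2)
  }
  out <- mean(rs, na.rm = TRUE)
  attr(out, "per_split") <- rs
  out
}

#' Fit a full SVR-LSM analysis
#'
#' End-to-end multivariate lesion-symptom mapping: voxel inclusion, dTLVC
#' scaling, covariate residualization of the behavioural score, RBF-kernel
#' epsilon-SVR with hyperparameter search (or fixed hyperparameters),
#' permutation-based voxelwise p-values, CFWER cluster correction, and the
#' model-quality indices (cross-validated prediction accuracy and half-split
#' reproducibility).
#'
#' @param masks list of per-subject binary `voxel_image` resection masks on a
#'   shared grid.
#' @param score behavioural score vector (positive = worsening), one per
#'   subject.
#' @param covariates optional data frame of nuisance covariates.
#' @param config an [svrlsm_config()].
#' @param hyperparameters optional list (C, sigma, epsilon) to bypass the
#'   search.
#' @param quality compute accuracy/reproducibility indices (default TRUE;
#'   FALSE skips them, e.g. in calibration loops).
#' @return object of class `svrlsm`; see [summary.svrlsm()].
#' @export
svrlsm <- function(masks, score, covariates = NULL,
                   config = svrlsm_config(), hyperparameters = NULL,
                   quality = TRUE) {
  if (length(masks) != length(score))
    stop("one score per subject required")
  lm <- build_lesion_matrix(masks, config$min_lesion_fraction)
  Xs <- apply_dtlvc(lm$X, lm$total_volumes)
  adj <- residualize_behaviour(score, covariates)
  if (is.null(hyperparameters)) {
    hyper <- optimize_hyperparameters(Xs, adj, config)
  } else {
    hyper <- hyperparameters
    if (quality) {
      hyper <- c(hyper, cv_accuracy(Xs, adj, hyper, config))
    }
  }
  perm <- permutation_pmap(Xs, adj, hyper, config$n_permutations,
                           seed = substream_seed(config$seed, "perm"),
                           two_tailed = config$two_tailed)
  cf <- cfwer_threshold(perm, lm$included, lm$included_mask,
                        alpha = config$cfwer_alpha, v = config$cfwer_v,
                        voxel_p = config$voxel_p)
  repro <- if (quality && length(masks) >= 20)
    reproducibility_index(Xs, adj, hyper, config$n_splits,
                          seed = substream_seed(config$seed, "split"))
  else NA_real_
  grid <- lm$included_mask
  to_map <- function(vals) {
    a <- array(NA_real_, dim(grid$data)); a[lm$included] <- vals
    voxel_image(a, grid$affine, grid$space_tag)
  }
  structure(list(
    beta_map = to_map(perm$beta),
    p_map = to_map(perm$p),
    significant_cluster_mask = cf$mask,
    included_voxel_mask = grid,
    included = lm$included,
    inclusion_threshold = lm$threshold,
    hyperparameters = hyper[c("C", "sigma", "epsilon")],
    prediction_accuracy = hyper$accuracy,
    prediction_accuracy_sd = hyper$accuracy_sd,
    reproducibility = as.numeric(repro),
    critical_p = cf$critical_p,
    cluster_table = cf$cluster_table,
    p_values = perm$p,
    beta_values = perm$beta,
    adjusted_score = adj,
    config = config,
    n = length(masks)),
    class = "svrlsm")
}

cv_accuracy <- function(X, score, hyper, config) {
  n <- nrow(X)
  rng_state <- local_rng(substream_seed(config$seed, "folds"))
  on.exit(restore_rng(rng_state), add = TRUE)
  folds <- sample(rep_len(seq_len(config$n_folds), n))
  rfold <- numeric(config$n_folds)
  for (f in seq_len(config$n_folds)) {
    te <- folds == f
    p <- svr_predict(X[!te, , drop = FALSE], score[!te], X[te, , drop = FALSE],
                     hyper$C, hyper$sigma, hyper$epsilon)
    rfold[f] <- if (stats::sd(p) == 0 || stats::sd(score[te]) == 0) NA_real_
                else stats::cor(p, score[te])
  }
  list(accuracy = mean(rfold, na.rm = TRUE),
       accuracy_sd = stats::sd(rfold, na.rm = TRUE))
}

#' @export
print.svrlsm <- function(x, ...) {
  cat(sprintf("<svrlsm> n = %d subjects, %d included voxels\n",
              x$n, length(x$included)))
  cat(sprintf("  hyperparameters: C = %.3g, sigma = %.3g, epsilon = %.3g\n",
              x$hyperparameters$C, x$hyperparameters$sigma,
              x$hyperparameters$epsilon))
  cat(sprintf("  significant voxels: %d (critical p = %.4g)\n",
              sum(x$significant_cluster_mask$data), x$critical_p))
  invisible(x)
}

#' Summarise an SVR-LSM fit
#' @param object an `svrlsm` object.
#' @param ... unused.
#' @return the object, invisibly, after printing the cluster table and
#'   quality indices.
#' @export
summary.svrlsm <- function(object, ...) {
  print(object)
  cat(sprintf("  prediction accuracy = %.3f +/- %.3f; reproducibility r = %.3f\n",
              object$prediction_accuracy,
              if (is.null(object$prediction_accuracy_sd) ||
                  is.na(object$prediction_accuracy_sd)) NA
              else object$prediction_accuracy_sd,
              object$reproducibility))
  if (!is.null(object$cluster_table)) {
    cat("  clusters (size, peak mm):\n")
    print(object$cluster_table, row.names = FALSE)
  } else cat("  no significant clusters\n")
  invisible(object)
}

#' Voxelwise beta weights of an SVR-LSM fit
#' @param object an `svrlsm` object.
#' @param ... unused.
#' @return named numeric vector of beta values over included voxels (names
#'   are linear voxel indices).
#' @export
coef.svrlsm <- function(object, ...) {
  stats::setNames(object$beta_values, object$included)
}

#' Plot the mid-axial slice of the SVR-LSM beta map with the significant mask
#' @param x an `svrlsm` object.
#' @param slice axial (3rd-dimension) slice index; default middle.
#' @param ... passed to `image`.
#' @export
plot.svrlsm <- function(x, slice = NULL, ...) {
  d <- dim(x$beta_map$data)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  img <- x$beta_map$data[, , slice]
  graphics::image(seq_len(d[1]), seq_len(d[2]), img,
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  xlab = "x (voxel)", ylab = "y (voxel)",
                  main = sprintf("SVR-LSM beta, slice %d", slice), ...)
  sig <- x$significant_cluster_mask$data[, , slice]
  if (any(sig != 0)) graphics::contour(seq_len(d[1]), seq_len(d[2]), sig,
                                       levels = 0.5, add = TRUE, lwd = 2,
                                       drawlabels = FALSE)
  invisible(x)
}

#' Overlap of a cluster mask with a parcellation
#'
#' For every parcel: 100 * |cluster intersect parcel| / |parcel|; network
#' percentages aggregate parcels by their network assignment.
#'
#' @param cluster_mask binary `voxel_image`.
#' @param parcellation integer-label `voxel_image` on the same grid.
#' @param networks optional data frame (label, parcel_name, network_name).
#' @return list with data frames `per_parcel` and `per_network`.
#' @export
atlas_overlap <- function(cluster_mask, parcellation, networks = NULL) {
  if (!same_grid(cluster_mask, parcellation))
    stop("parcellation grid does not match the cluster mask")
  cl <- cluster_mask$data != 0
  lab <- parcellation$data
  labs <- sort(unique(lab[lab != 0]))
  per_parcel <- do.call(rbind, lapply(labs, function(l) {
    inp <- lab == l
    data.frame(label = l, n_voxels = sum(inp),
               overlap_pct = 100 * sum(cl & inp) / sum(inp))
  }))
  per_network <- NULL
  if (!is.null(networks)) {
    per_parcel <- merge(per_parcel, networks, by = "label", all.x = TRUE)
    nets <- unique(networks$network_name)
    per_network <- do.call(rbind, lapply(nets, function(nn) {
      ls <- networks$label[networks$network_name == nn]
      inn <- lab %in% ls
      data.frame(network_name = nn, n_voxels = sum(inn),
                 overlap_pct = if (sum(inn)) 100 * sum(cl & inn) / sum(inn)
                               else NA_real_)
    }))
  }
  list(per_parcel = per_parcel, per_network = per_network)
}

# --- RNG helpers ------------------------------------------------------------

local_rng <- function(seed) {
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  state
}

restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
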