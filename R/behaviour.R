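#' Score one administration of the Bells cancellation test
#'
#' The test asks the patient to find and cancel 35 bell targets embedded among
#' 280 distractors. The total score is the number of omitted targets; the
#' asymmetry score is the number of left-sided omissions minus right-sided
#' omissions, an index of lateralised (neglect-like) inattention.
#'
#' @param omissions_left,omissions_right non-negative counts of omitted
#'   targets on each side of the sheet.
#' @param n_targets_total total number of targets on the sheet (default 35).
#' @return list with `total` and `asymmetry`.
#' @examples
#' score_bells(5, 0)   # total 5, asymmetry 5
#' score_bells(2, 3)   # total 5, asymmetry -1
#' @export
score_bells <- function(omissions_left, omissions_right, n_targets_total = 35L) {
  if (length(omissions_left) != length(omissions_right))
    stop("left and right counts must have equal length")
  if (any(omissions_left < 0) || any(omissions_right < 0))
    stop("omission counts must be non-negative")
  total <- omissions_left + omissions_right
  if (any(total > n_targets_total))
    stop("omissions exceed the number of targets on the sheet")
  list(total = total, asymmetry = omissions_left - omissions_right)
}

#' Build a behaviour table with pre/post deltas from raw omission counts
#'
#' Sign convention: delta = post - pre, so positive deltas mean postoperative
#' worsening (more omissions, or a stronger leftward bias).
#'
#' @param df data frame with columns `subject_id`, `hemisphere`
#'   (\code{"left"}/\code{"right"}, side of the lesion), `pre_left`,
#'   `pre_right`, `post_left`, `post_right`, and optionally covariates
#'   (`age`, `education`, `grade`, `resection_volume_mm3`).
#' @param n_targets_total targets per sheet (default 35).
#' @return the input with `pre_total`, `pre_asymmetry`, `post_total`,
#'   `post_asymmetry`, `delta_total`, `delta_asymmetry` columns appended.
#' @export
behaviour_table <- function(df, n_targets_total = 35L) {
  need <- c("subject_id", "hemisphere", "pre_left", "pre_right",
            "post_left", "post_right")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  pre <- score_bells(df$pre_left, df$pre_right, n_targets_total)
  post <- score_bells(df$post_left, df$post_right, n_targets_total)
  df$pre_total <- pre$total
  df$pre_asymmetry <- pre$asymmetry
  df$post_total <- post$total
  df$post_asymmetry <- post$asymmetry
  df$delta_total <- post$total - pre$total
  df$delta_asymmetry <- post$asymmetry - pre$asymmetry
  df
}

#' Read a behaviour CSV into a behaviour table
#' @param path CSV with header subject_id, hemisphere, pre_left, pre_right,
#'   post_left, post_right, age, education, grade, resection_volume_mm3.
#' @param ... passed to [behaviour_table()].
#' @return a behaviour table data frame.
#' @export
read_behaviour <- function(path, ...) {
  behaviour_table(utils::read.csv(path, stringsAsFactors = FALSE), ...)
}

#' Flag pathological scores against normative cutoffs
#'
#' Scores strictly above a cutoff are pathological. Normative cutoffs depend
#' on the published norms in use and must be supplied by the caller; the
#' defaults here are placeholders, not published norms.
#'
#' @param table behaviour table (from [behaviour_table()]).
#' @param cutoffs named list with elements `total` and `asymmetry`.
#' @return the table with logical columns `path_total_pre`, `path_total_post`,
#'   `path_asym_pre`, `path_asym_post`, plus a per-hemisphere count summary in
#'   attribute `"counts"`.
#' @export
classify_pathological <- function(table, cutoffs = list(total = 4, asymmetry = 2)) {
  if (is.null(cutoffs$total) || is.null(cutoffs$asymmetry))
    stop("cutoffs must supply `total` and `asymmetry`")
  table$path_total_pre <- table$pre_total > cutoffs$total
  table$path_total_post <- table$post_total > cutoffs$total
  table$path_asym_pre <- abs(table$pre_asymmetry) > cutoffs$asymmetry
  table$path_asym_post <- abs(table$post_asymmetry) > cutoffs$asymmetry
  counts <- stats::aggregate(
    cbind(path_total_pre, path_total_post, path_asym_pre, path_asym_post)
    ~ hemisphere, data = table, FUN = sum)
  attr(table, "counts") <- counts
  table
}

#' Partial eta squared from an F ratio
#'
#' For a one-degree contrast in a split-plot ANOVA,
#' eta^2_p = F * df1 / (F * df1 + df2).
#' @param F_value F ratio.
#' @param df1,df2 numerator / denominator degrees of freedom.
#' @return partial eta squared in [0, 1].
#' @export
partial_eta_sq <- function(F_value, df1, df2) {
  (F_value * df1) / (F_value * df1 + df2)
}

#' Cohen's d_z from a paired t statistic
#' @param t_value paired t statistic.
#' @param n number of pairs.
#' @return standardized mean difference d_z = t / sqrt(n).
#' @export
cohens_dz_from_t <- function(t_value, n) t_value / sqrt(n)

#' Two-way mixed (split-plot) ANOVA for a 2-timepoint design
#'
#' Repeated-measures ANOVA with one between-subject factor (`group`,
#' typically lesion hemisphere) and one within-subject factor (time:
#' pre/post). Returns the Time main effect and the Time x Group interaction
#' with partial eta squared for each. Fitted with `stats::aov` using an
#' `Error(subject)` stratum, the standard split-plot decomposition.
#'
#' @param pre,post numeric vectors, one value per subject.
#' @param group factor (2 levels) of between-subject group membership.
#' @return list of class `effect_size_report` with elements `time` and
#'   `interaction`, each holding `F`, `df1`, `df2`, `p`, `partial_eta_sq`.
#' @export
mixed_rm_anova <- function(pre, post, group) {
  n <- length(pre)
  stopifnot(length(post) == n, length(group) == n)
  group <- factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required")
  if (any(table(group) < 2L)) stop("need at least 2 subjects per group")
  if (stats::var(c(pre, post)) == 0)
    stop("constant data: F undefined")
  long <- data.frame(
    y = c(pre, post),
    time = factor(rep(c("pre", "post"), each = n), levels = c("pre", "post")),
    grp = rep(group, 2L),
    subj = factor(rep(seq_len(n), 2L)))
  fit <- stats::aov(y ~ grp * time + Error(subj/time), data = long)
  within <- summary(fit)[["Error: subj:time"]][[1]]
  rn <- trimws(rownames(within))
  get_row <- function(name) {
    i <- match(name, rn)
    list(F = within[i, "F value"], df1 = within[i, "Df"],
         df2 = within[match("Residuals", rn), "Df"],
         p = within[i, "Pr(>F)"])
  }
  tt <- get_row("time"); ti <- get_row("grp:time")
  tt$partial_eta_sq <- partial_eta_sq(tt$F, tt$df1, tt$df2)
  ti$partial_eta_sq <- partial_eta_sq(ti$F, ti$df1, ti$df2)
  structure(list(time = tt, interaction = ti, n = n,
                 groups = table(group)),
            class = "effect_size_report")
}

#' @export
print.effect_size_report <- function(x, ...) {
  fmt <- function(nm, e) {
    if (!is.null(e$F))
      cat(sprintf("  %s: F(%g,%g) = %.3f, p = %.4g, eta^2_p = %.3f\n",
                  nm, e$df1, e$df2, e$F, e$p, e$partial_eta_sq))
  }
  cat("<effect_size_report>\n")
  for (nm in setdiff(names(x), c("n", "groups"))) {
    e <- x[[nm]]
    if (is.list(e)) fmt(nm, e)
  }
  invisible(x)
}

#' Paired-samples effects: t, Cohen's d_z, Wilcoxon signed rank, r_rb
#'
#' Paired t with df = n - 1 and d_z = t / sqrt(n). The Wilcoxon signed-rank
#' test drops zero differences, uses mid-ranks for ties, and for n > 25 a
#' normal approximation with continuity correction; the matched-pairs
#' rank-biserial correlation is r_rb = (W+ - W-) / (W+ + W-).
#'
#' @param pre,post paired numeric vectors.
#' @return list of class `paired_effects` with `t`, `df`, `p_t`, `cohens_dz`,
#'   `W_pos`, `W_neg`, `Z`, `p_wilcoxon`, `r_rb`, `n`.
#' @export
paired_effects <- function(pre, post) {
  n <- length(pre)
  stopifnot(length(post) == n, n >= 2)
  d <- post - pre
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    # (numerically) zero spread: t undefined (all-zero) or infinite shift
    tt <- list(p.value = NA_real_)
    t_stat <- if (all(d == 0)) NA_real_ else sign(mean(d)) * Inf
  } else {
    tt <- stats::t.test(post, pre, paired = TRUE)
    t_stat <- unname(tt$statistic)
  }
  dz <- t_stat / sqrt(n)
  dnz <- d[d != 0]
  if (length(dnz) == 0L) {
    W_pos <- W_neg <- 0; r_rb <- NA_real_; Z <- NA_real_; p_w <- NA_real_
    warning("all differences zero: Wilcoxon undefined")
  } else {
    r <- rank(abs(dnz))             # mid-ranks for ties
    W_pos <- sum(r[dnz > 0])
    W_neg <- sum(r[dnz < 0])
    r_rb <- (W_pos - W_neg) / (W_pos + W_neg)
    m <- length(dnz)
    mu <- m * (m + 1) / 4
    ties <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 -
      sum(ties^3 - ties) / 48
    W <- min(W_pos, W_neg)
    if (m > 25) {
      Z <- (W - mu + 0.5) / sqrt(sigma2)   # continuity-corrected
      p_w <- 2 * stats::pnorm(Z)
      p_w <- min(1, p_w)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE,
                                                exact = TRUE))
      p_w <- wt$p.value
      Z <- (W - mu) / sqrt(sigma2)
    }
  }
  structure(list(t = t_stat, df = n - 1L, p_t = tt$p.value,
                 cohens_dz = dz, W_pos = W_pos, W_neg = W_neg,
                 Z = Z, p_wilcoxon = p_w, r_rb = r_rb, n = n),
            class = "paired_effects")
}

#' @export
print.paired_effects <- function(x, ...) {
  cat(sprintf("<paired_effects> n = %d\n  t(%d) = %.3f, p = %.4g, dz = %.3f\n",
              x$n, x$df, x$t, x$p_t, x$cohens_dz))
  cat(sprintf("  Wilcoxon W+ = %.1f, W- = %.1f, Z = %.2f, p = %.4g, r_rb = %.3f\n",
              x$W_pos, x$W_neg, x$Z, x$p_wilcoxon, x$r_rb))
  invisible(x)
}

#' Companion t statistic for a Spearman correlation
#'
#' t = rho * sqrt((n - 2) / (1 - rho^2)), df = n - 2, the usual large-sample
#' reference for a rank correlation.
#' @param rho Spearman correlation.
#' @param n number of pairs.
#' @return t statistic (Inf when |rho| = 1).
#' @export
spearman_t <- function(rho, n) {
  if (abs(rho) >= 1 - 1e-12) return(sign(rho) * Inf)
  rho * sqrt((n - 2) / (1 - rho^2))
}

#' Spearman correlation with t-based inference
#'
#' Spearman's rho on mid-ranks with the companion t statistic
#' (df = n - 2) and its two-sided p. Degenerate inputs (zero variance, or
#' |rho| = 1 where the t diverges) are flagged rather than reported.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list of class `spearman_report` with `rho`, `t`, `df`, `p`,
#'   `n`, `degenerate`.
#' @export
spearman_report <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(rho = NA_real_, t = NA_real_, df = n - 2L,
                          p = NA_real_, n = n, degenerate = TRUE),
                     class = "spearman_report"))
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1 - 1e-12) {
    return(structure(list(rho = rho, t = NA_real_, df = n - 2L,
                          p = NA_real_, n = n, degenerate = TRUE),
                     class = "spearman_report"))
  }
  t_stat <- spearman_t(rho, n)
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  structure(list(rho = rho, t = t_stat, df = n - 2L, p = p, n = n,
                 degenerate = FALSE),
            class = "spearman_report")
}

#' @export
print.spearman_report <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<spearman_report> n = %d, degenerate (rho = %s)\n",
                x$n, format(x$rho)))
  } else {
    cat(sprintf("<spearman_report> rho = %.3f, t(%d) = %.3f, p = %.4g\n",
                x$rho, x$df, x$t, x$p))
  }
  invisible(x)
}

#' Two-sided Spearman p-value via the t approximation, Bonferroni-adjusted
#'
#' @param rho Spearman correlation.
#' @param n number of pairs.
#' @param m number of comparisons (Bonferroni factor); must be given
#'   explicitly.
#' @return list with `p_raw` and `p_adjusted` (clipped at 1).
#' @export
spearman_p_bonferroni <- function(rho, n, m) {
  t_stat <- spearman_t(rho, n)
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  list(p_raw = p, p_adjusted = min(1, m * p))
}

#' Render a synthetic Bells test sheet from omission counts
#'
#' Lays the 35 targets out on the two halves of the sheet (17 on the left,
#' 18 on the right) and marks which were cancelled, so that recounting the
#' sheet reproduces the scores exactly. Omitted targets are the first
#' `omissions_left` / `omissions_right` of each half.
#'
#' @param omissions_left,omissions_right omitted-target counts (left <= 17,
#'   right <= 18).
#' @return data frame with `target_id`, `side`, `cancelled`.
#' @export
render_bells_sheet <- function(omissions_left, omissions_right) {
  if (omissions_left < 0 || omissions_left > 17 ||
      omissions_right < 0 || omissions_right > 18)
    stop("omissions out of range for the sheet layout (17 left, 18 right)")
  data.frame(
    target_id = seq_len(35),
    side = rep(c("left", "right"), c(17, 18)),
    cancelled = c(seq_len(17) > omissions_left,
                  seq_len(18) > omissions_right))
}

#' Recount a rendered Bells sheet
#' @param sheet data frame from [render_bells_sheet()].
#' @return list with `total` and `asymmetry`, as [score_bells()].
#' @export
recount_bells_sheet <- function(sheet) {
  om_l <- sum(!sheet$cancelled & sheet$side == "left")
  om_r <- sum(!sheet$cancelled & sheet$side == "right")
  score_bells(om_l, om_r)
}

#' Confidence intervals for the reported effect sizes
#'
#' Partial eta squared: inversion of the noncentral-F pivot (the noncentral
#' parameter bounds solve `pf(F, df1, df2, ncp) = 1 -/+ level/2`), mapped to
#' eta^2 via ncp/(ncp + df1 + df2 + 1). Spearman rho and the rank-biserial
#' r_rb: seeded nonparametric bootstrap (percentile interval).
#'
#' @param F_value,df1,df2 F ratio and degrees of freedom (for `eta_sq_ci`).
#' @param level confidence level (default 0.95).
#' @return two-element numeric vector (lower, upper).
#' @export
eta_sq_ci <- function(F_value, df1, df2, level = 0.95) {
  a <- (1 - level) / 2
  bound <- function(target) {
    f <- function(ncp) stats::pf(F_value, df1, df2, ncp = ncp) - target
    if (f(0) < 0) return(0)
    stats::uniroot(f, c(0, 1e6), extendInt = "downX")$root
  }
  ncp_lo <- bound(1 - a)
  ncp_hi <- bound(a)
  ncp_to_eta <- function(ncp) ncp / (ncp + df1 + df2 + 1)
  c(ncp_to_eta(ncp_lo), ncp_to_eta(ncp_hi))
}

#' @rdname eta_sq_ci
#' @param x,y paired vectors (`x` = pre, `y` = post for `r_rb_ci`).
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed bootstrap seed.
#' @export
spearman_rho_ci <- function(x, y, level = 0.95, n_boot = 2000L, seed = 1L) {
  state <- local_rng(seed)
  on.exit(restore_rng(state), add = TRUE)
  n <- length(x)
  reps <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, replace = TRUE)
    suppressWarnings(stats::cor(x[i], y[i], method = "spearman"))
  }, 0)
  unname(stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                         na.rm = TRUE))
}

#' @rdname eta_sq_ci
#' @export
r_rb_ci <- function(x, y, level = 0.95, n_boot = 2000L, seed = 1L) {
  state <- local_rng(seed)
  on.exit(restore_rng(state), add = TRUE)
  n <- length(x)
  reps <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, replace = TRUE)
    suppressWarnings(paired_effects(x[i], y[i])$r_rb)
  }, 0)
  unname(stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                         na.rm = TRUE))
}
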