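test_that("Bells scoring follows the total/asymmetry formulas and validates input", {
  expect_equal(score_bells(5, 0), list(total = 5, asymmetry = 5))
  expect_equal(score_bells(0, 0), list(total = 0, asymmetry = 0))
  expect_equal(score_bells(2, 3), list(total = 5, asymmetry = -1))
  expect_error(score_bells(-1, 0), "non-negative")
  expect_error(score_bells(20, 20), "exceed")
  # vectorized over a cohort, |asymmetry| <= total always
  set.seed(1)
  l <- rpois(50, 3); r <- rpois(50, 3)
  s <- score_bells(l, r)
  expect_true(all(abs(s$asymmetry) <= s$total))
})

test_that("behaviour table deltas use the worsening-positive sign convention", {
  df <- data.frame(subject_id = c("a", "b"), hemisphere = c("right", "left"),
                   pre_left = c(1, 0), pre_right = c(0, 0),
                   post_left = c(4, 0), post_right = c(1, 2))
  tb <- behaviour_table(df)
  expect_equal(tb$delta_total, c(4, 2))       # post - pre: worsening positive
  expect_equal(tb$delta_asymmetry, c(2, -2))
})

test_that("pathological classification uses strict cutoffs", {
  df <- behaviour_table(data.frame(
    subject_id = c("a", "b", "c"), hemisphere = "right",
    pre_left = c(3, 1, 0), pre_right = c(2, 1, 0),
    post_left = c(3, 1, 0), post_right = c(2, 1, 0)))
  fl <- classify_pathological(df, cutoffs = list(total = 4, asymmetry = 2))
  expect_equal(fl$path_total_pre, c(TRUE, FALSE, FALSE))   # 5 > 4; 2; 0
  # boundary: asymmetry exactly at the cutoff is not pathological
  df2 <- behaviour_table(data.frame(
    subject_id = "d", hemisphere = "right", pre_left = 2, pre_right = 0,
    post_left = 2, post_right = 0))
  fl2 <- classify_pathological(df2, cutoffs = list(total = 4, asymmetry = 2))
  expect_false(fl2$path_asym_pre)
  expect_error(classify_pathological(df, cutoffs = list(total = 4)),
               "cutoffs")
  # all-zero cohort: no flags
  df0 <- behaviour_table(data.frame(
    subject_id = c("x", "y"), hemisphere = "right",
    pre_left = 0, pre_right = 0, post_left = 0, post_right = 0))
  fl0 <- classify_pathological(df0)
  expect_equal(sum(fl0$path_total_post, fl0$path_asym_post), 0)
})

# independent split-plot oracle: closed-form sums of squares on difference
# scores (within-subject stratum of the 2x2 mixed design)
anova_oracle <- function(pre, post, group) {
  d <- post - pre; g <- factor(group); N <- length(d)
  SS_time <- sum(d)^2 / (2 * N)
  SS_cells <- sum(tapply(d, g, function(x) length(x) * mean(x)^2)) / 2
  SS_int <- SS_cells - SS_time
  SS_res <- sum((d - ave(d, g))^2) / 2
  df2 <- N - nlevels(g)
  list(F_time = SS_time / (SS_res / df2),
       F_int = SS_int / (SS_res / df2), df2 = df2,
       eta_time = SS_time / (SS_time + SS_res))
}

test_that("mixed RM-ANOVA matches the sums-of-squares oracle, balanced and not", {
  set.seed(11)
  for (sizes in list(c(10, 10), c(8, 13), c(20, 21))) {
    n <- sum(sizes)
    pre <- rnorm(n); post <- pre + rnorm(n, 0.4, 1)
    g <- rep(c("left", "right"), sizes)
    fit <- mixed_rm_anova(pre, post, g)
    o <- anova_oracle(pre, post, g)
    expect_equal(fit$time$F, o$F_time, tolerance = 1e-9)
    expect_equal(fit$interaction$F, o$F_int, tolerance = 1e-9)
    expect_equal(fit$time$df2, o$df2)
    # partial eta^2 from F equals the SS-based definition
    expect_equal(fit$time$partial_eta_sq, o$eta_time, tolerance = 1e-12)
    expect_equal(fit$time$partial_eta_sq,
                 partial_eta_sq(fit$time$F, fit$time$df1, fit$time$df2),
                 tolerance = 1e-12)
  }
  expect_error(mixed_rm_anova(rep(1, 10), rep(1, 10), rep(c("a", "b"), 5)),
               "constant")
})

test_that("mixed RM-ANOVA rejects at nominal rate under the null", {
  set.seed(2024)
  n <- 40; reps <- 1000
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    pre <- rnorm(n); post <- rnorm(n)   # no time effect
    fit <- mixed_rm_anova(pre, post, rep(c("l", "r"), each = n / 2))
    rej[r] <- fit$time$p < 0.05
  }
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})

test_that("paired effects: dz identity, rank sums, and shift invariance", {
  # dz = t / sqrt(n) identity on arbitrary paired data
  set.seed(3)
  x <- rnorm(12)
  pe <- paired_effects(rep(0, 12), x + 1)
  expect_equal(pe$cohens_dz, pe$t / sqrt(12), tolerance = 1e-12)
  # all post = pre + 1: one-sided ranks
  pre <- rnorm(10)
  pe1 <- paired_effects(pre, pre + 1)
  expect_equal(pe1$W_neg, 0)
  expect_equal(pe1$r_rb, 1)
  # shift invariance of dz and r_rb
  set.seed(4)
  a <- rnorm(30); b <- a + rnorm(30, 0.3)
  p0 <- paired_effects(a, b)
  p5 <- paired_effects(a + 5, b + 5)
  expect_equal(p0$cohens_dz, p5$cohens_dz, tolerance = 1e-12)
  expect_equal(p0$r_rb, p5$r_rb, tolerance = 1e-12)
  # degenerate: all differences zero
  expect_warning(pz <- paired_effects(a, a), "Wilcoxon undefined")
  expect_true(is.na(pz$r_rb))
})

test_that("Wilcoxon agrees with stats::wilcox.test on rank sums", {
  set.seed(9)
  a <- rnorm(15); b <- a + rnorm(15, 0.4)
  pe <- paired_effects(a, b)
  V <- unname(suppressWarnings(wilcox.test(b, a, paired = TRUE))$statistic)
  expect_equal(pe$W_pos, V)
})

test_that("Spearman report: t companion formula and degenerate flags", {
  set.seed(5)
  x <- rnorm(40); y <- x + rnorm(40)
  sp <- spearman_report(x, y)
  expect_equal(sp$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(sp$t, sp$rho * sqrt((40 - 2) / (1 - sp$rho^2)),
               tolerance = 1e-12)
  # perfectly monotone pair: t diverges, flagged
  sp1 <- spearman_report(1:5, c(2, 4, 8, 16, 32))
  expect_true(sp1$degenerate)
  expect_equal(sp1$rho, 1)
  # zero variance flagged
  expect_true(spearman_report(rep(1, 5), rnorm(5))$degenerate)
  # near-zero rho gives near-zero t
  expect_equal(spearman_t(0, 50), 0)
})

test_that("worked-example statistics reproduce the reported values", {
  ex <- verify_paper_examples()
  expect_equal(ex$value[ex$input == "F(1,161)=54.23"], 0.252, tolerance = 0.002)
  expect_equal(ex$value[ex$input == "t(81)=-5.272, n=82"], -0.582,
               tolerance = 0.002)
  expect_equal(ex$value[ex$input == "rho=0.770, n=82"], 10.79,
               tolerance = 0.001)
})

test_that("a rendered synthetic sheet recounts to the original scores", {
  for (lr in list(c(0, 0), c(5, 0), c(2, 3), c(17, 18))) {
    sheet <- render_bells_sheet(lr[1], lr[2])
    expect_equal(nrow(sheet), 35)
    rs <- recount_bells_sheet(sheet)
    expect_equal(rs$total, lr[1] + lr[2])
    expect_equal(rs$asymmetry, lr[1] - lr[2])
  }
  expect_error(render_bells_sheet(18, 0), "out of range")
})

test_that("effect-size confidence intervals behave sensibly", {
  ci <- eta_sq_ci(54.23, 1, 161)
  eta <- partial_eta_sq(54.23, 1, 161)
  expect_lt(ci[1], eta); expect_gt(ci[2], eta)
  expect_true(all(ci >= 0 & ci <= 1))
  # F below the central quantile: lower bound collapses to 0
  expect_equal(eta_sq_ci(0.10, 1, 45)[1], 0)
  # bootstrap CIs bracket the point estimates and are seed-stable
  set.seed(8); x <- rnorm(40); y <- x + rnorm(40)
  ci_r <- spearman_rho_ci(x, y, n_boot = 300, seed = 2)
  expect_identical(ci_r, spearman_rho_ci(x, y, n_boot = 300, seed = 2))
  rho <- cor(x, y, method = "spearman")
  expect_lt(ci_r[1], rho); expect_gt(ci_r[2], rho)
  ci_rb <- suppressWarnings(r_rb_ci(x, y, n_boot = 200, seed = 3))
  expect_true(ci_rb[1] <= ci_rb[2])
  expect_true(all(ci_rb >= -1 & ci_rb <= 1))
})
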