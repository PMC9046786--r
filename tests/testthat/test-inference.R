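make_groups <- function(n_per, k = 3, seed = 1) {
  withr::with_seed(seed, data.frame(
    y = stats::rnorm(n_per * k),
    group = rep(letters[seq_len(k)], each = n_per),
    age = stats::runif(n_per * k, 20, 45),
    gender = sample(c("M", "F"), n_per * k, replace = TRUE),
    education = stats::runif(n_per * k, 6, 20)))
}

test_that("ANCOVA F reduces to one-way ANOVA without informative covariates", {
  for (seed in 1:5) {
    d <- make_groups(8, seed = seed)
    fit <- ancova_group_test(d, y, covariates = character())
    ref <- summary(stats::aov(y ~ group, data = d))[[1]]
    expect_equal(fit$statistic, ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(fit$p_raw, ref[["Pr(>F)"]][1], tolerance = 1e-10)
    # constant covariates are inert: F equals the one-way ANOVA F
    d$const <- 1
    expect_message(
      fitc <- ancova_group_test(d, y, covariates = "const"), "constant")
    expect_equal(fitc$statistic, ref[["F value"]][1], tolerance = 1e-10)
    fit2 <- ancova_group_test(d, y, covariates = c("age", "gender", "education"))
    ref2 <- stats::anova(stats::lm(y ~ age + gender + education, data = d),
                         stats::lm(y ~ age + gender + education + group, data = d))
    expect_equal(fit2$statistic, ref2$F[2], tolerance = 1e-10)
  }
})

test_that("a small worked dataset matches an independent normal-equations solve", {
  d <- data.frame(
    y = c(3.1, 2.7, 4.0, 3.3, 5.2, 4.8, 5.9, 5.1, 7.4, 6.6, 8.0, 7.1),
    group = rep(c("hc", "nm", "m"), each = 4),
    age = c(31, 44, 25, 38, 29, 41, 35, 22, 27, 40, 33, 36),
    education = c(12, 16, 10, 14, 13, 9, 15, 11, 12, 17, 8, 14))
  fit <- ancova_group_test(d, y, covariates = c("age", "education"))
  # normal equations, no qr: X'X beta = X'y for both nested models
  rss_of <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% d$y)
    sum((d$y - X %*% beta)^2)
  }
  X0 <- cbind(1, d$age, d$education)
  g <- stats::model.matrix(~ factor(d$group))[, -1]
  X1 <- cbind(X0, g)
  f_ref <- ((rss_of(X0) - rss_of(X1)) / 2) / (rss_of(X1) / (12 - 5))
  expect_equal(fit$statistic, f_ref, tolerance = 1e-8)
  expect_equal(fit$df1, 2)
  expect_equal(fit$df2, 7)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$n, 12)
})

test_that("pairwise contrasts are antisymmetric and null on identical groups", {
  d <- data.frame(y = rep(c(1.2, 3.4, 2.2, 5.0), 2),
                  group = rep(c("a", "b"), each = 4))
  fit <- posthoc_pairwise(d, y, covariates = character())
  expect_equal(fit$statistic, 0, tolerance = 1e-12)

  d2 <- make_groups(10, k = 2, seed = 3)
  f_ab <- posthoc_pairwise(d2, y, covariates = c("age", "education"))
  d2$group <- ifelse(d2$group == "a", "b", "a")
  f_ba <- posthoc_pairwise(d2, y, covariates = c("age", "education"))
  expect_equal(f_ab$statistic, -f_ba$statistic, tolerance = 1e-12)
  # matches lm's t for the group coefficient
  ref <- summary(stats::lm(y ~ age + education + group, data = d2))$coefficients
  expect_equal(abs(f_ab$statistic), abs(ref["groupb", "t value"]), tolerance = 1e-10)
})

test_that("a one-SD effect at 23 vs 59 is typically detected (power check)", {
  tstats <- vapply(1:300, function(i) {
    withr::with_seed(4000 + i, {
      d <- data.frame(y = c(stats::rnorm(59, 0), stats::rnorm(23, 1)),
                      group = rep(c("nm", "m"), c(59, 23)))
      posthoc_pairwise(d, y, covariates = character())$statistic
    })
  }, 0)
  # analytic noncentrality: 1 / sqrt(1/59 + 1/23) = 4.07 -> mean |T| well above 2
  expect_gt(mean(abs(tstats)), 2)
  expect_equal(abs(mean(tstats)), 1 / sqrt(1 / 59 + 1 / 23), tolerance = 0.1)
})

test_that("permutation p-values hit the boundary and match exhaustive enumeration", {
  # observed far beyond anything a permutation can reach -> p = 1/(B+1)
  d <- data.frame(y = c(rnorm(10, 0, 0.01), rnorm(10, 100, 0.01)),
                  group = rep(c("a", "b"), each = 10))
  p <- permutation_correct(d, y, statistic = "F", n_perm = 199, seed = 1)
  expect_equal(p, 1 / 200)

  # n = 6, two groups of 3: exhaustive enumeration over all 20 assignments
  withr::with_seed(9, {
    d6 <- data.frame(y = rnorm(6), group = rep(c("a", "b"), each = 3))
  })
  p_ex <- permutation_correct(d6, y, statistic = "F", exhaustive = TRUE)
  # independent oracle: recompute the F for every combn-assignment via aov
  f_of <- function(gidx) {
    gg <- factor(ifelse(seq_len(6) %in% gidx, "a", "b"))
    summary(stats::aov(d6$y ~ gg))[[1]][["F value"]][1]
  }
  obs <- f_of(1:3)
  all_f <- apply(utils::combn(6, 3), 2, f_of)
  expect_equal(length(all_f), 20)
  expect_equal(p_ex, mean(all_f >= obs - 1e-12))

  expect_error(permutation_correct(d, y, n_perm = 50),
               class = "melnet_parameter_error")
})

test_that("permutation and parametric p agree on Gaussian null data", {
  withr::with_seed(11, {
    d <- make_groups(12, seed = 77)
    fit <- ancova_group_test(d, y, covariates = c("age", "education"),
                             n_perm = 2000, seed = 5)
  })
  expect_lt(abs(fit$p_perm - fit$p_raw), 0.05)
})

test_that("BH adjustment follows the step-up rule and dominates Bonferroni", {
  res <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(res$reject))
  expect_equal(res$p_fdr, rep(0.04, 4))
  expect_false(any(bh_fdr(rep(1, 5))$reject))
  expect_equal(bh_fdr(0.04)$p_fdr, 0.04)
  expect_error(bh_fdr(c(0.5, 1.2)), class = "melnet_validation_error")
  expect_equal(nrow(bh_fdr(numeric())), 0)

  withr::with_seed(2, {
    p <- stats::runif(60)^2
    bh <- bh_fdr(p, 0.05)$reject
    bonf <- p <= 0.05 / length(p)
    expect_true(all(which(bonf) %in% which(bh)))
    # adjusted p monotone in the raw ordering
    expect_true(all(diff(sort(bh_fdr(p)$p_fdr)) >= 0))
  })
})

test_that("Pearson correlation matches hand computation and is affine-invariant", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_corr(x, -x)$r, -1)
  expect_equal(pearson_corr(x, c(2, 1, 4, 3))$r, 0.6)
  withr::with_seed(5, {
    a <- rnorm(20); b <- rnorm(20)
    expect_equal(pearson_corr(a, b)$r, pearson_corr(10 * a + 3, b)$r,
                 tolerance = 1e-12)
  })
  expect_error(pearson_corr(c(1, 1, 1), c(1, 2, 3)),
               class = "melnet_validation_error")
  expect_error(pearson_corr(c(1, 2), c(1, 2)), class = "melnet_parameter_error")
})

test_that("chi-square on contingency tables matches direct formulas", {
  res <- chisq_contingency(rbind(c(10, 0), c(0, 10)))
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)
  # a table proportional to its margins is exactly independent
  res0 <- chisq_contingency(rbind(c(20, 40), c(10, 20)))
  expect_equal(res0$statistic, 0)
  expect_error(chisq_contingency(rbind(c(0, 0), c(1, 2))),
               class = "melnet_validation_error")
  expect_error(chisq_contingency(matrix(1, 1, 2)),
               class = "melnet_parameter_error")
})

test_that("summary-statistic ANOVA and Welch t behave algebraically", {
  expect_equal(anova_from_summary(c(5, 5, 5), c(1, 2, 1), c(10, 10, 10))$statistic, 0)
  # two groups: F equals the squared pooled-variance t
  m <- c(10, 12); s <- c(2, 2.5); n <- c(16, 20)
  f2 <- anova_from_summary(m, s, n)
  sp2 <- ((n[1] - 1) * s[1]^2 + (n[2] - 1) * s[2]^2) / (sum(n) - 2)
  t_pooled <- (m[1] - m[2]) / sqrt(sp2 * (1 / n[1] + 1 / n[2]))
  expect_equal(f2$statistic, t_pooled^2, tolerance = 1e-12)
  expect_error(anova_from_summary(c(1, 2), c(1, 1), c(1, 5)),
               class = "melnet_parameter_error")

  wt <- welch_t(10, 2, 16, 12, 2, 16)
  expect_equal(wt$statistic, -2 * sqrt(2), tolerance = 1e-12)
  expect_equal(wt$df, 30)
  expect_equal(welch_t(5, 1, 10, 5, 1, 10)$statistic, 0)
  expect_equal(welch_t(3, 1, 9, 5, 2, 14)$statistic,
               -welch_t(5, 2, 14, 3, 1, 9)$statistic)
})

test_that("nodal batch inference agrees with per-node single fits", {
  withr::with_seed(31, {
    pheno <- tibble::tibble(
      subject_id = sprintf("s%02d", 1:24),
      group = factor(rep(c("HC", "NM", "M"), each = 8)),
      age = runif(24, 20, 45), gender = sample(c("M", "F"), 24, TRUE),
      education = runif(24, 8, 18))
    auc_tbl <- tidyr::expand_grid(subject_id = pheno$subject_id,
                                  node = paste0("n", 1:5), metric = "abc")
    auc_tbl$auc <- rnorm(nrow(auc_tbl))
  })
  res <- nodal_group_stats(auc_tbl, pheno)
  expect_equal(nrow(res), 5)
  one <- dplyr::left_join(dplyr::filter(auc_tbl, node == "n3"), pheno,
                          by = "subject_id")
  single <- ancova_group_test(one, auc)
  expect_equal(dplyr::filter(res, node == "n3")$statistic, single$statistic,
               tolerance = 1e-12)
  expect_equal(dplyr::filter(res, node == "n3")$p_raw, single$p_raw,
               tolerance = 1e-12)
  # pairwise batch against single posthoc fit
  sub <- dplyr::filter(pheno, group != "HC")
  sub$group <- droplevels(sub$group)
  resp <- nodal_posthoc(dplyr::filter(auc_tbl, subject_id %in% sub$subject_id),
                        sub, covariates = c("age", "education"))
  two <- dplyr::left_join(
    dplyr::filter(auc_tbl, node == "n2", subject_id %in% sub$subject_id),
    sub, by = "subject_id")
  single_t <- posthoc_pairwise(two, auc, covariates = c("age", "education"))
  expect_equal(dplyr::filter(resp, node == "n2")$statistic, single_t$statistic,
               tolerance = 1e-12)
})
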