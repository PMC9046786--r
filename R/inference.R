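# ---- design machinery ------------------------------------------------------

# covariate design matrix (intercept + covariates); constant covariates are
# inert (absorbed by the intercept) and dropped with a message
covariate_design <- function(data, covariates) {
  if (length(covariates) == 0) {
    return(matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)")))
  }
  miss <- setdiff(covariates, names(data))
  if (length(miss)) param_error(sprintf(
    "covariate(s) not in data: %s", paste(miss, collapse = ", ")))
  cov_df <- data[covariates]
  if (anyNA(cov_df)) validation_error("covariates contain missing values.")
  constant <- vapply(cov_df, function(x) length(unique(x)) == 1, TRUE)
  if (any(constant)) {
    inform(sprintf("dropping constant covariate(s): %s",
                   paste(covariates[constant], collapse = ", ")))
    cov_df <- cov_df[!constant]
    if (ncol(cov_df) == 0) {
      return(matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)")))
    }
  }
  stats::model.matrix(~ ., data = cov_df)
}

check_rank <- function(X, context) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    param_error(sprintf("rank-deficient %s design; collinear column(s): %s",
                        context, paste(dropped, collapse = ", ")))
  }
  q
}

# F statistics for the group factor, every column of Y at once
f_stats <- function(Y, q0, q1, df1, df2) {
  rss0 <- colSums(qr.resid(q0, Y)^2)
  rss1 <- colSums(qr.resid(q1, Y)^2)
  ((rss0 - rss1) / df1) / (rss1 / df2)
}

# t statistic for the (last) group-indicator coefficient, every column of Y
t_stats <- function(Y, q1, xtx_gg, df2) {
  beta <- qr.coef(q1, Y)
  k <- nrow(as.matrix(beta))
  bk <- if (is.matrix(beta)) beta[k, ] else beta[k]
  rss1 <- colSums(qr.resid(q1, Y)^2)
  bk / sqrt(rss1 / df2 * xtx_gg)
}

# Freedman-Lane residual permutation: permute reduced-model residuals,
# recompute the statistic on fitted0 + permuted residuals.
freedman_lane <- function(Y, X0, stat_fun, observed, n_perm, seed,
                          two_sided = FALSE) {
  q0 <- qr(X0)
  E <- qr.resid(q0, Y)
  fitted0 <- Y - E
  obs <- if (two_sided) abs(observed) else observed
  count <- rep(0, ncol(Y))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(nrow(Y))
      stat_b <- stat_fun(fitted0 + E[idx, , drop = FALSE])
      if (two_sided) stat_b <- abs(stat_b)
      count <- count + (stat_b >= obs - 1e-12)
    }
  })
  (1 + count) / (1 + n_perm)
}

# accept a bare column name or a string (possibly held in a variable)
resolve_col <- function(data, response) {
  q <- rlang::enquo(response)
  if (rlang::quo_is_symbol(q) && rlang::as_name(q) %in% names(data)) {
    return(rlang::as_name(q))
  }
  val <- tryCatch(rlang::eval_tidy(q), error = function(e) NULL)
  if (is.character(val) && length(val) == 1 && val %in% names(data)) {
    return(val)
  }
  param_error("`response` must name a column in `data`.")
}

group_design <- function(data, response, group, covariates) {
  y <- data[[response]]
  if (anyNA(y)) validation_error("response contains missing values.")
  g <- droplevels(as.factor(data[[group]]))
  if (nlevels(g) < 2) param_error("group factor needs at least 2 levels.")
  if (any(table(g) < 2)) param_error("each group needs at least 2 subjects.")
  X0 <- covariate_design(data, covariates)
  G <- stats::model.matrix(~ g)[, -1, drop = FALSE]
  colnames(G) <- paste0("group", levels(g)[-1])
  X1 <- cbind(X0, G)
  q1 <- check_rank(X1, "full")
  list(y = matrix(y, ncol = 1), g = g, X0 = X0, X1 = X1,
       q0 = qr(X0), q1 = q1,
       df1 = ncol(G), df2 = nrow(X1) - ncol(X1))
}

# ---- group tests -----------------------------------------------------------

#' Covariate-adjusted group test (ANCOVA F)
#'
#' Fits the ordinary least-squares model `response ~ covariates + group` and
#' tests the group factor by comparison with the covariates-only model. With
#' constant covariates this reduces exactly to one-way ANOVA. Optionally adds
#' a Freedman-Lane permutation p-value: residuals of the covariates-only
#' model are permuted and the F statistic recomputed, so the permutation
#' respects the covariate structure.
#'
#' @param data data frame of subjects.
#' @param response response column (bare name or string), e.g. a metric AUC.
#' @param group grouping column name (2 or 3 levels).
#' @param covariates character vector of covariate column names (possibly
#'   empty).
#' @param n_perm number of permutations (0 = parametric only; at least 100
#'   otherwise).
#' @param seed permutation seed.
#' @return Object of class `melnet_stat` with fields `term`, `statistic`,
#'   `df1`, `df2`, `p_raw`, `p_perm`; see [generics::tidy()].
#' @export
#' @examples
#' d <- data.frame(y = rnorm(30), group = rep(c("a", "b", "c"), 10),
#'                 age = runif(30, 20, 40))
#' ancova_group_test(d, y, covariates = "age")
ancova_group_test <- function(data, response, group = "group",
                              covariates = c("gender", "age", "education"),
                              n_perm = 0, seed = 1L) {
  response <- resolve_col(data, {{ response }})
  dd <- group_design(data, response, group, covariates)
  f_obs <- f_stats(dd$y, dd$q0, dd$q1, dd$df1, dd$df2)
  p_perm <- NA_real_
  if (n_perm > 0) {
    if (n_perm < 100) param_error("`n_perm` must be at least 100 (or 0 to skip).")
    p_perm <- freedman_lane(
      dd$y, dd$X0,
      function(Ys) f_stats(Ys, dd$q0, dd$q1, dd$df1, dd$df2),
      f_obs, n_perm, seed)
  }
  structure(
    list(term = group, statistic = unname(f_obs), stat_name = "F",
         df1 = dd$df1, df2 = dd$df2,
         p_raw = stats::pf(f_obs, dd$df1, dd$df2, lower.tail = FALSE),
         p_perm = p_perm, n_perm = n_perm,
         n = nrow(data), covariates = covariates,
         method = "ANCOVA model comparison"),
    class = "melnet_stat")
}

#' Covariate-adjusted pairwise contrast (post-hoc T)
#'
#' For exactly two groups, the t statistic of the group-indicator coefficient
#' in `response ~ covariates + group`. Swapping the group labels negates the
#' statistic. The melancholic-vs-non-melancholic contrast conventionally adds
#' the MADRS total score to the covariates; contrasts against controls (who
#' have no MADRS score) use the demographic covariates only.
#'
#' @inheritParams ancova_group_test
#' @return Object of class `melnet_stat` (two-sided `p_raw`).
#' @export
posthoc_pairwise <- function(data, response, group = "group",
                             covariates = c("gender", "age", "education"),
                             n_perm = 0, seed = 1L) {
  response <- resolve_col(data, {{ response }})
  g <- droplevels(as.factor(data[[group]]))
  if (nlevels(g) != 2) param_error("post-hoc contrast requires exactly 2 groups.")
  dd <- group_design(data, response, group, covariates)
  xtx_gg <- diag(solve(crossprod(dd$X1)))[ncol(dd$X1)]
  t_obs <- t_stats(dd$y, dd$q1, xtx_gg, dd$df2)
  p_perm <- NA_real_
  if (n_perm > 0) {
    if (n_perm < 100) param_error("`n_perm` must be at least 100 (or 0 to skip).")
    p_perm <- freedman_lane(
      dd$y, dd$X0,
      function(Ys) t_stats(Ys, dd$q1, xtx_gg, dd$df2),
      t_obs, n_perm, seed, two_sided = TRUE)
  }
  structure(
    list(term = paste(levels(g)[2], "vs", levels(g)[1]),
         statistic = unname(t_obs), stat_name = "T",
         df1 = 1, df2 = dd$df2,
         p_raw = 2 * stats::pt(abs(t_obs), dd$df2, lower.tail = FALSE),
         p_perm = p_perm, n_perm = n_perm,
         n = nrow(data), covariates = covariates,
         method = "covariate-adjusted two-group contrast"),
    class = "melnet_stat")
}

#' @export
print.melnet_stat <- function(x, ...) {
  cat(sprintf("<melnet_stat> %s: %s = %.4g (df %g, %g), p_raw = %.4g",
              x$term, x$stat_name, x$statistic, x$df1, x$df2, x$p_raw))
  if (!is.na(x$p_perm)) cat(sprintf(", p_perm = %.4g (%d perms)", x$p_perm, x$n_perm))
  cat("\n")
  invisible(x)
}

#' Permutation p-value for a group test
#'
#' Freedman-Lane residual permutation: residuals of the covariates-only model
#' are permuted and the group statistic recomputed; `p = (1 + #[stat* >=
#' stat]) / (1 + n_perm)`. With `exhaustive = TRUE` (two groups, no
#' covariates) all distinct label assignments are enumerated instead and
#' `p = #[stat* >= stat] / n_assignments` (the identity assignment included).
#'
#' @inheritParams ancova_group_test
#' @param statistic `"F"` (any number of groups) or `"T"` (two groups,
#'   two-sided).
#' @param exhaustive enumerate all label assignments (two groups, no
#'   covariates only).
#' @return The permutation p-value.
#' @export
permutation_correct <- function(data, response, group = "group",
                                covariates = character(),
                                statistic = c("F", "T"),
                                n_perm = 10000L, seed = 1L,
                                exhaustive = FALSE) {
  statistic <- match.arg(statistic)
  response <- resolve_col(data, {{ response }})
  if (exhaustive) {
    g <- droplevels(as.factor(data[[group]]))
    if (nlevels(g) != 2 || length(covariates) > 0) {
      param_error("exhaustive enumeration supports two groups without covariates.")
    }
    y <- data[[response]]
    n1 <- sum(g == levels(g)[1])
    combos <- utils::combn(length(y), n1)
    stat_of <- function(idx) {
      gg <- factor(ifelse(seq_along(y) %in% idx, levels(g)[1], levels(g)[2]),
                   levels = levels(g))
      d2 <- data.frame(y = y, group = gg)
      st <- if (statistic == "F") {
        ancova_group_test(d2, y, covariates = character())$statistic
      } else {
        posthoc_pairwise(d2, y, covariates = character())$statistic
      }
      if (statistic == "T") abs(st) else st
    }
    obs <- stat_of(which(g == levels(g)[1]))
    stats_all <- apply(combos, 2, stat_of)
    return(mean(stats_all >= obs - 1e-12))
  }
  if (n_perm < 100) param_error("`n_perm` must be at least 100.")
  fit <- if (statistic == "F") {
    ancova_group_test(data, response, group, covariates,
                      n_perm = n_perm, seed = seed)
  } else {
    posthoc_pairwise(data, response, group, covariates,
                     n_perm = n_perm, seed = seed)
  }
  fit$p_perm
}

# ---- multiplicity and correlation ------------------------------------------

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values with the rejection set at level `q`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return Tibble with columns `p`, `p_fdr`, `reject`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0) return(tibble(p = numeric(), p_fdr = numeric(),
                                    reject = logical()))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    validation_error("p-values must lie in [0, 1].")
  }
  adj <- stats::p.adjust(p, method = "BH")
  tibble(p = p, p_fdr = adj, reject = adj < q)
}

#' Pearson correlation between a nodal attribute and a clinical score
#'
#' @param x,y paired numeric vectors, `n >= 3`, non-degenerate.
#' @return Tibble with `r`, `statistic` (t), `df`, `p` (two-sided).
#' @export
#' @examples
#' pearson_corr(c(1, 2, 3, 4), c(2, 1, 4, 3))  # r = 0.6
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) param_error("`x` and `y` must be paired.")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) param_error("correlation needs at least 3 complete pairs.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    validation_error("zero variance: correlation undefined.")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), statistic = unname(ct$statistic),
         df = unname(ct$parameter), p = ct$p.value, n = length(x))
}

# ---- summary-statistic tests (demographic table) ---------------------------

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction, as used for e.g. a gender-by-group table.
#'
#' @param tab matrix of non-negative integer counts, at least 2 x 2.
#' @return Tibble with `statistic`, `df`, `p`.
#' @export
#' @examples
#' chisq_contingency(rbind(c(38, 43, 16), c(25, 16, 7)))
chisq_contingency <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) param_error("table must be at least 2 x 2.")
  if (any(tab < 0) || any(tab != round(tab))) {
    validation_error("counts must be non-negative integers.")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    validation_error("zero marginal in contingency table.")
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value)
}

#' One-way ANOVA from group summaries
#'
#' F statistic from per-group means, SDs and sizes (between-group mean square
#' over the pooled within-group mean square), for recomputing demographic
#' comparisons from printed summaries.
#'
#' @param means,sds,ns parallel numeric vectors, one entry per group.
#' @return Tibble with `statistic`, `df1`, `df2`, `p`.
#' @export
#' @examples
#' anova_from_summary(c(13.0, 11.7, 11.1), c(4.2, 4.5, 4.4), c(63, 59, 23))
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2 || length(sds) != k || length(ns) != k) {
    param_error("need parallel means/sds/ns for at least 2 groups.")
  }
  if (any(ns < 2)) param_error("each group needs n >= 2.")
  if (any(sds < 0)) validation_error("SDs must be non-negative.")
  grand <- sum(ns * means) / sum(ns)
  msb <- sum(ns * (means - grand)^2) / (k - 1)
  msw <- sum((ns - 1) * sds^2) / (sum(ns) - k)
  f <- msb / msw
  tibble(statistic = f, df1 = k - 1, df2 = sum(ns) - k,
         p = stats::pf(f, k - 1, sum(ns) - k, lower.tail = FALSE))
}

#' Welch two-sample t test from group summaries
#'
#' Welch statistic with Satterthwaite degrees of freedom, from printed
#' mean/SD/n summaries.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @return Tibble with `statistic`, `df`, `p` (two-sided).
#' @export
#' @examples
#' welch_t(10, 2, 16, 12, 2, 16)
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) param_error("each group needs n >= 2.")
  if (sd1 <= 0 || sd2 <= 0) validation_error("SDs must be positive.")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble(statistic = t, df = df,
         p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

# ---- nodal batch inference -------------------------------------------------

#' Per-subject nodal AUC table for a cohort
#'
#' Computes nodal metric curves for every subject and integrates them over
#' the grid.
#'
#' @param cohort a [generate_cohort()] result.
#' @inheritParams nodal_metric_curves
#' @return Tibble with columns `subject_id`, `node`, `metric`, `auc`.
#' @export
cohort_nodal_auc <- function(cohort, grid = sparsity_grid(),
                             metrics = c("abc", "adc", "acp", "aefficiency",
                                         "aeloc", "alp"),
                             distance_rule = c("inverse", "binary")) {
  stopifnot(inherits(cohort, "melnet_cohort"))
  distance_rule <- match.arg(distance_rule)
  bind_rows(imap(cohort$connectomes, function(conn, id) {
    curves <- nodal_metric_curves(conn, grid, distance_rule, metrics)
    mutate(nodal_auc(curves), subject_id = id, .before = 1)
  }))
}

nodal_y_matrix <- function(auc_tbl, pheno, metric) {
  wide <- pivot_wider(
    filter(auc_tbl, .data$metric == .env$metric),
    id_cols = "subject_id", names_from = "node", values_from = "auc")
  wide <- wide[match(pheno$subject_id, wide$subject_id), ]
  as.matrix(wide[, -1])
}

#' Nodal three-group ANCOVA with permutation and FDR correction
#'
#' For every node and metric: ANCOVA F for the group factor given the
#' covariates, an optional Freedman-Lane permutation p-value (computed for
#' all nodes simultaneously), and Benjamini-Hochberg adjustment across the
#' nodes within each metric (matching the per-metric presentation of nodal
#' results).
#'
#' @param auc_tbl per-subject nodal AUC table from [cohort_nodal_auc()].
#' @param phenotype subject table with `subject_id`, `group` and the
#'   covariates.
#' @inheritParams ancova_group_test
#' @param q FDR level.
#' @return Tibble: `metric`, `node`, `statistic`, `df1`, `df2`, `p_raw`,
#'   `p_perm`, `p_fdr`, `significant`. FDR is applied to the permutation
#'   p-values when `n_perm > 0`, otherwise to the parametric ones.
#' @export
nodal_group_stats <- function(auc_tbl, phenotype, group = "group",
                              covariates = c("gender", "age", "education"),
                              n_perm = 0, seed = 1L, q = 0.05) {
  run_nodal(auc_tbl, phenotype, group, covariates, n_perm, seed, q,
            statistic = "F")
}

#' Nodal pairwise post-hoc contrasts with permutation and FDR
#'
#' As [nodal_group_stats()] but for exactly two groups, testing the
#' covariate-adjusted group-indicator t statistic (two-sided).
#'
#' @inheritParams nodal_group_stats
#' @export
nodal_posthoc <- function(auc_tbl, phenotype, group = "group",
                          covariates = c("gender", "age", "education"),
                          n_perm = 0, seed = 1L, q = 0.05) {
  run_nodal(auc_tbl, phenotype, group, covariates, n_perm, seed, q,
            statistic = "T")
}

run_nodal <- function(auc_tbl, phenotype, group, covariates, n_perm, seed, q,
                      statistic) {
  pheno <- as_tibble(phenotype)
  g <- droplevels(as.factor(pheno[[group]]))
  if (statistic == "T" && nlevels(g) != 2) {
    param_error("post-hoc contrast requires exactly 2 groups.")
  }
  X0 <- covariate_design(pheno, covariates)
  G <- stats::model.matrix(~ g)[, -1, drop = FALSE]
  X1 <- cbind(X0, G)
  q0 <- qr(X0)
  q1 <- check_rank(X1, "full")
  df1 <- ncol(G)
  df2 <- nrow(X1) - ncol(X1)
  xtx_gg <- if (statistic == "T") diag(solve(crossprod(X1)))[ncol(X1)] else NULL
  out <- list()
  for (m in unique(auc_tbl$metric)) {
    Y <- nodal_y_matrix(auc_tbl, pheno, m)
    keep <- which(apply(Y, 2, function(col) all(is.finite(col))))
    Yk <- Y[, keep, drop = FALSE]
    stat_fun <- if (statistic == "F") {
      function(Ys) f_stats(Ys, q0, q1, df1, df2)
    } else {
      function(Ys) t_stats(Ys, q1, xtx_gg, df2)
    }
    obs <- stat_fun(Yk)
    p_raw <- if (statistic == "F") {
      stats::pf(obs, df1, df2, lower.tail = FALSE)
    } else {
      2 * stats::pt(abs(obs), df2, lower.tail = FALSE)
    }
    p_perm <- rep(NA_real_, length(obs))
    if (n_perm > 0) {
      if (n_perm < 100) param_error("`n_perm` must be at least 100 (or 0 to skip).")
      p_perm <- freedman_lane(Yk, X0, stat_fun, obs, n_perm,
                              derive_seed(seed, 17, match(m, unique(auc_tbl$metric))),
                              two_sided = statistic == "T")
    }
    p_base <- if (n_perm > 0) p_perm else p_raw
    fdr <- bh_fdr(p_base, q)
    out[[m]] <- tibble(
      metric = m, node = colnames(Y)[keep],
      statistic = unname(obs), df1 = df1, df2 = df2,
      p_raw = unname(p_raw), p_perm = unname(p_perm),
      p_fdr = fdr$p_fdr, significant = fdr$reject)
  }
  bind_rows(out)
}
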