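#' Pipeline configuration
#'
#' Validates every stage's settings before anything runs: the cohort design,
#' the sparsity grid, null-ensemble and permutation sizes, FDR level,
#' covariate sets and SVM settings. The master seed deterministically spawns
#' per-stage seeds, so identical configurations give identical reports.
#'
#' @param cohort a [cohort_spec()].
#' @param grid a [sparsity_grid()], or a list with `s_min`, `s_max`, `step`.
#' @param n_null nulls per threshold for small-world normalization.
#' @param n_perm Freedman-Lane permutations for the nodal tests (0 disables).
#' @param q FDR level.
#' @param ancova_covariates covariates for the three-group tests.
#' @param posthoc_covariates covariates for pairwise contrasts.
#' @param posthoc_madrs add the MADRS total score as covariate to the
#'   patient-vs-patient contrast (it is undefined for controls, so contrasts
#'   against controls never include it).
#' @param metrics nodal metrics to analyse.
#' @param distance_rule edge-length rule for path-based metrics.
#' @param svm list of SVM settings (`kernel`, `cost`, `gamma`).
#' @param seed master seed.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            grid = sparsity_grid(),
                            n_null = 100L, n_perm = 10000L, q = 0.05,
                            ancova_covariates = c("gender", "age", "education"),
                            posthoc_covariates = c("gender", "age", "education"),
                            posthoc_madrs = TRUE,
                            metrics = c("abc", "adc", "acp", "aefficiency",
                                        "aeloc", "alp"),
                            distance_rule = c("inverse", "binary"),
                            svm = list(kernel = "radial", cost = 1, gamma = NULL),
                            seed = 1L) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (!inherits(grid, "sparsity_grid")) {
    grid <- sparsity_grid(grid$s_min, grid$s_max, grid$step)
  }
  if (n_null < 1) validation_error("`n_null` must be at least 1.")
  if (n_perm != 0 && n_perm < 100) {
    validation_error("`n_perm` must be 0 or at least 100.")
  }
  assert_scalar_number(q, "q", 0, 1)
  distance_rule <- match.arg(distance_rule)
  metrics <- match.arg(metrics, several.ok = TRUE)
  structure(
    list(cohort = cohort, grid = grid, n_null = as.integer(n_null),
         n_perm = as.integer(n_perm), q = q,
         ancova_covariates = ancova_covariates,
         posthoc_covariates = posthoc_covariates,
         posthoc_madrs = isTRUE(posthoc_madrs),
         metrics = metrics, distance_rule = distance_rule,
         svm = svm, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `cohort` and
#' `grid` are given as nested maps of the [cohort_spec()] and
#' [sparsity_grid()] arguments.
#'
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @return A validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    format_error("config must be a .yaml/.yml or .json file.")
  }
  args <- raw
  if (!is.null(raw$cohort)) {
    ca <- raw$cohort
    if (!is.null(ca$group_sizes)) ca$group_sizes <- unlist(ca$group_sizes)
    args$cohort <- do.call(cohort_spec, ca)
  }
  if (!is.null(raw$grid)) {
    args$grid <- do.call(sparsity_grid, raw$grid)
  }
  do.call(pipeline_config, args)
}

stage_log <- function(log, stage, rows) {
  bind_rows(log, tibble(stage = stage, rows = rows, at = format(Sys.time())))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> small-world curves -> nodal metrics -> group
#' inference -> clinical correlation -> classification on a synthetic cohort,
#' in that order, each stage consuming the previous stage's output. The
#' report is a pure function of the configuration (including its seed).
#'
#' @param config a [pipeline_config()].
#' @return Object of class `melnet_report`: tibbles `demographics`,
#'   `sw_auc` (per subject), `sw_stats`, `nodal_stats`, `posthoc`,
#'   `correlations`, the `svm` glance row, plus `phenotype`, `log` and the
#'   `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- tibble(stage = character(), rows = integer(), at = character())

  cohort <- generate_cohort(config$cohort)
  pheno <- cohort$phenotype
  groups <- levels(pheno$group)
  log <- stage_log(log, "simulate", nrow(pheno))

  # demographic summary tests recomputed from the generated cohort
  gender_tab <- table(pheno$gender, pheno$group)
  by_group <- function(v) summarise(group_by(pheno, .data$group),
                                    m = mean(.data[[v]]), s = stats::sd(.data[[v]]),
                                    n = dplyr::n())
  ag <- by_group("age"); ed <- by_group("education")
  patients <- filter(pheno, .data$group != groups[1])
  pm <- summarise(group_by(patients, .data$group),
                  m = mean(.data$madrs_total), s = stats::sd(.data$madrs_total),
                  n = dplyr::n())
  demographics <- bind_rows(
    mutate(chisq_contingency(gender_tab), variable = "gender", test = "chi-square"),
    mutate(anova_from_summary(ag$m, ag$s, ag$n), variable = "age", test = "anova"),
    mutate(anova_from_summary(ed$m, ed$s, ed$n), variable = "education", test = "anova"),
    mutate(welch_t(pm$m[1], pm$s[1], pm$n[1], pm$m[2], pm$s[2], pm$n[2]),
           variable = "madrs_total", test = "welch-t"))
  log <- stage_log(log, "demographics", nrow(demographics))

  # global small-world stage
  sw_subject <- bind_rows(imap(cohort$connectomes, function(conn, id) {
    curve <- small_world_curve(conn, config$grid, config$n_null,
                               seed = derive_seed(config$seed, 23, match(id, names(cohort$connectomes))),
                               distance_rule = config$distance_rule)
    mutate(sw_auc(curve), subject_id = id, .before = 1)
  }))
  sw_wide <- pivot_wider(sw_subject, names_from = "metric", values_from = "auc")
  sw_data <- left_join(sw_wide, pheno, by = "subject_id")
  sw_stats <- bind_rows(lapply(
    c("cp", "lp", "eglob", "eloc", "gamma", "lambda", "sigma"),
    function(m) {
      fit <- ancova_group_test(sw_data, m, covariates = config$ancova_covariates)
      mutate(tidy(fit), metric = m, .before = 1)
    }))
  fdr <- bh_fdr(sw_stats$p_raw, config$q)
  sw_stats$p_fdr <- fdr$p_fdr
  sw_stats$significant <- fdr$reject
  log <- stage_log(log, "small_world", nrow(sw_stats))

  # nodal stage
  auc_tbl <- cohort_nodal_auc(cohort, config$grid, config$metrics,
                              config$distance_rule)
  nodal_stats <- nodal_group_stats(
    auc_tbl, pheno, covariates = config$ancova_covariates,
    n_perm = config$n_perm, seed = derive_seed(config$seed, 29), q = config$q)
  log <- stage_log(log, "nodal_ancova", nrow(nodal_stats))

  pairs <- utils::combn(groups, 2, simplify = FALSE)
  posthoc <- bind_rows(lapply(seq_along(pairs), function(pi) {
    pr <- pairs[[pi]]
    sub <- filter(pheno, .data$group %in% pr)
    sub$group <- droplevels(sub$group)
    covs <- config$posthoc_covariates
    if (config$posthoc_madrs && !groups[1] %in% pr) covs <- c(covs, "madrs_total")
    res <- nodal_posthoc(
      filter(auc_tbl, .data$subject_id %in% sub$subject_id), sub,
      covariates = covs, n_perm = config$n_perm,
      seed = derive_seed(config$seed, 31, pi), q = config$q)
    mutate(res, contrast = paste(pr, collapse = " vs "), .before = 1)
  }))
  log <- stage_log(log, "posthoc", nrow(posthoc))

  # clinical correlation stage: betweenness at implicated nodes vs HRSD items
  flagged <- filter(nodal_stats, .data$metric == "abc", .data$significant)
  flag_nodes <- flagged$node
  if (length(flag_nodes) == 0) {
    flag_nodes <- unique(config$cohort$effect_spec$node)
  }
  abc_wide <- pivot_wider(
    filter(auc_tbl, .data$metric == "abc", .data$node %in% flag_nodes),
    id_cols = "subject_id", names_from = "node", values_from = "auc")
  clin <- left_join(
    filter(pheno, .data$group != groups[1]), abc_wide, by = "subject_id")
  correlations <- bind_rows(lapply(flag_nodes, function(nd) {
    bind_rows(lapply(c("hrsd_total", "hrsd_7", "hrsd_12"), function(item) {
      mutate(pearson_corr(clin[[nd]], clin[[item]]),
             node = nd, item = item, .before = 1)
    }))
  }))
  if (nrow(correlations)) {
    cf <- bh_fdr(correlations$p, config$q)
    correlations$p_fdr <- cf$p_fdr
    correlations$significant <- cf$reject
  }
  log <- stage_log(log, "correlations", nrow(correlations))

  # classification stage: discriminate the two patient groups from aBC
  patient_groups <- if (length(groups) >= 3) groups[2:3] else groups
  svm_nodes <- utils::head(arrange(
    filter(posthoc, .data$metric == "abc",
           .data$contrast == paste(patient_groups, collapse = " vs ")),
    .data$p_raw)$node, 2)
  if (length(svm_nodes) == 0) svm_nodes <- flag_nodes[seq_len(min(2, length(flag_nodes)))]
  feat <- pivot_wider(
    filter(auc_tbl, .data$metric == "abc", .data$node %in% svm_nodes),
    id_cols = "subject_id", names_from = "node", values_from = "auc")
  feat <- left_join(feat, select(pheno, "subject_id", "group"), by = "subject_id")
  feat <- filter(feat, .data$group %in% patient_groups)
  feat$label <- droplevels(feat$group)
  feat$group <- NULL
  svm_fit <- loocv_svm(feat, label = "label", positive = patient_groups[2],
                       kernel = config$svm$kernel %||% "radial",
                       cost = config$svm$cost %||% 1,
                       gamma = config$svm$gamma,
                       seed = derive_seed(config$seed, 37))
  log <- stage_log(log, "classification", svm_fit$n)

  structure(
    list(demographics = demographics, sw_auc = sw_subject, sw_stats = sw_stats,
         nodal_auc = auc_tbl, nodal_stats = nodal_stats, posthoc = posthoc,
         correlations = correlations, svm = glance(svm_fit),
         svm_fit = svm_fit, phenotype = pheno, log = log, config = config),
    class = "melnet_report")
}

#' @export
print.melnet_report <- function(x, ...) {
  cat("<melnet_report>\n")
  cat(sprintf("  subjects: %d (%s)\n", nrow(x$phenotype),
              paste(levels(x$phenotype$group), table(x$phenotype$group),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  small-world metrics significant after FDR: %d of %d\n",
              sum(x$sw_stats$significant), nrow(x$sw_stats)))
  cat(sprintf("  nodal tests significant after FDR: %d of %d\n",
              sum(x$nodal_stats$significant), nrow(x$nodal_stats)))
  cat(sprintf("  SVM (%s): accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              x$svm$positive, 100 * x$svm$accuracy, 100 * x$svm$sensitivity,
              100 * x$svm$specificity))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Tidy CSV per result table plus a JSON summary (seeds, config, stage log).
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "melnet_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("demographics", "sw_auc", "sw_stats", "nodal_auc",
              "nodal_stats", "posthoc", "correlations", "phenotype", "log")
  for (tb in tables) {
    utils::write.csv(report[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  }
  summary <- list(
    seed = report$config$seed,
    svm = as.list(report$svm),
    stages = report$log$stage,
    n_subjects = nrow(report$phenotype))
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
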