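#' Specify a synthetic three-group connectome cohort
#'
#' Describes the study design emulated by [generate_cohort()]: group sizes,
#' the small-world base topology of every subject's white-matter network, the
#' edge-weight model (FA ~ Beta, FN ~ 1 + negative binomial, weight =
#' FA x FN), group-specific nodal manipulations, and per-group clinical score
#' distributions. Defaults mirror the three-group melancholic-depression
#' study design (63 controls, 59 non-melancholic, 23 melancholic patients)
#' and its printed demographic/clinical summaries.
#'
#' @param group_sizes named integer vector of subjects per group; names are
#'   the group labels (first label is treated as the healthy-control group).
#' @param n_nodes node count (atlas regions), default 90.
#' @param k ring-lattice neighbor count (even, `< n_nodes`), default 8.
#' @param p Watts-Strogatz rewiring probability in (0, 1), default 0.1.
#' @param fa_shape1,fa_shape2 Beta parameters for edge mean fractional
#'   anisotropy.
#' @param fn_size,fn_mu negative-binomial parameters for the streamline count
#'   (`fn = 1 + rnbinom(size, mu)` so present edges carry at least one
#'   streamline).
#' @param effect_spec tibble with columns `group`, `node`, `mode`
#'   (`"weight-scale"` or `"edge-rewire-toward-hub"`) and `magnitude`,
#'   applied by [inject_node_effect()] to every subject of the named group.
#'   The default plants betweenness-raising rewiring at the right orbital
#'   inferior frontal gyrus and right caudate and a weight reduction at the
#'   left orbital superior frontal gyrus in the melancholic group, with
#'   milder versions in the non-melancholic group.
#' @param score_model per-group score distributions; see
#'   [default_score_model()].
#' @param seed master seed; the cohort is a pure function of the spec.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(HC = 63L, `NM-MDD` = 59L, `M-MDD` = 23L),
                        n_nodes = 90L, k = 8L, p = 0.1,
                        fa_shape1 = 6, fa_shape2 = 6,
                        fn_size = 3, fn_mu = 30,
                        effect_spec = default_effect_spec(),
                        score_model = default_score_model(),
                        seed = 1L) {
  if (any(group_sizes <= 0) || is.null(names(group_sizes))) {
    param_error("`group_sizes` must be a named vector of positive counts.")
  }
  assert_scalar_number(p, "p", 0, 1)
  if (p <= 0 || p >= 1) param_error("rewiring probability `p` must lie strictly in (0, 1).")
  if (k %% 2 != 0 || k >= n_nodes || k < 2) {
    param_error("`k` must be even, >= 2 and < `n_nodes`.")
  }
  if (fa_shape1 <= 0 || fa_shape2 <= 0 || fn_size <= 0 || fn_mu <= 0) {
    param_error("distribution parameters must be positive.")
  }
  sm <- as_tibble(score_model)
  if (any(sm$sd < 0)) param_error("score-model SDs must be non-negative.")
  if (!all(names(group_sizes) %in% c(sm$group, names(group_sizes)[1]))) {
    param_error("score_model must cover every patient group.")
  }
  structure(
    list(group_sizes = group_sizes, n_nodes = as.integer(n_nodes),
         k = as.integer(k), p = p,
         fa_shape1 = fa_shape1, fa_shape2 = fa_shape2,
         fn_size = fn_size, fn_mu = fn_mu,
         effect_spec = as_tibble(effect_spec), score_model = sm,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Default group-specific nodal manipulations
#'
#' @return Tibble with columns `group`, `node`, `mode`, `magnitude`.
#' @export
default_effect_spec <- function() {
  tibble(
    group = c("M-MDD", "M-MDD", "M-MDD", "NM-MDD", "NM-MDD"),
    node = c("ORBinf.R", "CAU.R", "ORBsup.L", "ORBinf.R", "ORBsup.L"),
    mode = c("edge-rewire-toward-hub", "edge-rewire-toward-hub",
             "weight-scale", "edge-rewire-toward-hub", "weight-scale"),
    magnitude = c(0.25, 0.125, 0.5, 0.125, 0.7)
  )
}

#' Default clinical score model
#'
#' Long tibble of per-group truncated-normal score distributions: means and
#' SDs for age, years of education, illness duration (months), MADRS total and
#' items 1/2/8 (0-6 each), the HRSD-17 items used by the melancholic-features
#' rule (each truncated to its instrument range), the sum of the remaining
#' HRSD items (`hrsd_rest`), plus the per-group probability of male gender.
#' Printed demographic/clinical summaries fix the age, education, duration and
#' MADRS rows; HRSD item distributions are not printed and are set so that
#' melancholic patients typically satisfy the subtype rule and
#' non-melancholic patients typically do not.
#'
#' @return Tibble with columns `group`, `variable`, `mean`, `sd`.
#' @export
default_score_model <- function() {
  row <- function(group, variable, mean, sd) tibble(group = group, variable = variable,
                                                    mean = mean, sd = sd)
  bind_rows(
    row("HC", "age", 34.3, 10.4), row("HC", "education", 13.0, 4.2),
    row("HC", "p_male", 38 / 63, 0),
    row("NM-MDD", "age", 33.7, 10.3), row("NM-MDD", "education", 11.7, 4.5),
    row("NM-MDD", "p_male", 43 / 59, 0),
    row("NM-MDD", "duration", 12.0, 17.9),
    row("NM-MDD", "madrs_total", 28.1, 6.4),
    row("NM-MDD", "madrs_1", 3.0, 1.3), row("NM-MDD", "madrs_2", 3.0, 1.3),
    row("NM-MDD", "madrs_8", 3.3, 1.0),
    row("NM-MDD", "hrsd_1", 2.2, 0.9), row("NM-MDD", "hrsd_2", 1.2, 0.9),
    row("NM-MDD", "hrsd_6", 0.9, 0.7), row("NM-MDD", "hrsd_7", 2.2, 0.9),
    row("NM-MDD", "hrsd_8", 1.0, 0.9), row("NM-MDD", "hrsd_9", 0.8, 0.8),
    row("NM-MDD", "hrsd_12", 0.8, 0.6), row("NM-MDD", "hrsd_16", 0.7, 0.6),
    row("NM-MDD", "hrsd_rest", 9, 3),
    row("M-MDD", "age", 32.4, 11.2), row("M-MDD", "education", 11.1, 4.4),
    row("M-MDD", "p_male", 16 / 23, 0),
    row("M-MDD", "duration", 9.3, 12.9),
    row("M-MDD", "madrs_total", 37.5, 4.9),
    row("M-MDD", "madrs_1", 4.1, 1.1), row("M-MDD", "madrs_2", 4.1, 1.1),
    row("M-MDD", "madrs_8", 4.2, 0.42),
    row("M-MDD", "hrsd_1", 3.2, 0.7), row("M-MDD", "hrsd_2", 2.4, 0.9),
    row("M-MDD", "hrsd_6", 1.4, 0.6), row("M-MDD", "hrsd_7", 3.1, 0.7),
    row("M-MDD", "hrsd_8", 1.9, 0.9), row("M-MDD", "hrsd_9", 1.5, 1.0),
    row("M-MDD", "hrsd_12", 1.4, 0.6), row("M-MDD", "hrsd_16", 1.2, 0.6),
    row("M-MDD", "hrsd_rest", 11, 3)
  )
}

# instrument ranges for item truncation
.item_range <- list(
  madrs_1 = c(0, 6), madrs_2 = c(0, 6), madrs_8 = c(0, 6),
  hrsd_1 = c(0, 4), hrsd_2 = c(0, 4), hrsd_6 = c(0, 2), hrsd_7 = c(0, 4),
  hrsd_8 = c(0, 4), hrsd_9 = c(0, 4), hrsd_12 = c(0, 2), hrsd_16 = c(0, 2)
)

#' Generate a weighted small-world connectome
#'
#' Samples a Watts-Strogatz graph (ring lattice with `k` neighbors per node,
#' each edge rewired with probability `p`, edge count preserved at
#' `n_nodes * k / 2`) and weights each edge by `FA * FN` with FA drawn from a
#' Beta distribution and FN from a shifted negative binomial, so that control
#' subjects exhibit the small-world regime (normalized clustering gamma > 1,
#' normalized path length lambda near 1).
#'
#' @inheritParams cohort_spec
#' @param seed integer seed; identical arguments give bit-identical output.
#' @param labels node labels (AAL90 abbreviations when `n_nodes` is 90).
#' @return A [connectome()].
#' @export
#' @examples
#' conn <- synth_connectome(n_nodes = 30, k = 4, p = 0.1, seed = 7)
synth_connectome <- function(n_nodes = 90L, k = 8L, p = 0.1,
                             fa_shape1 = 6, fa_shape2 = 6,
                             fn_size = 3, fn_mu = 30,
                             seed = 1L, labels = NULL) {
  if (k %% 2 != 0) param_error("`k` must be even.")
  if (k >= n_nodes) param_error("`k` must be smaller than `n_nodes`.")
  if (p < 0 || p > 1) param_error("`p` must lie in [0, 1].")
  if (is.null(labels)) {
    labels <- if (n_nodes == 90) aal90()$abbrev else paste0("n", seq_len(n_nodes))
  }
  withr::with_seed(seed, {
    g <- igraph::sample_smallworld(1, n_nodes, k / 2, p,
                                   loops = FALSE, multiple = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    fa <- stats::rbeta(nrow(el), fa_shape1, fa_shape2)
    fn <- stats::rnbinom(nrow(el), size = fn_size, mu = fn_mu) + 1L
    w <- matrix(0, n_nodes, n_nodes)
    w[el] <- fa * fn
    w[el[, 2:1, drop = FALSE]] <- fa * fn
    connectome(w, labels)
  })
}

#' Inject a localized group effect at one node
#'
#' Two deterministic manipulations used to plant recoverable nodal effects:
#' `"weight-scale"` multiplies every edge weight incident to the target node
#' by `magnitude` (values < 1 weaken the node, 0 isolates it, 1 is the
#' identity); `"edge-rewire-toward-hub"` detaches the weakest
#' `round(magnitude * degree)` edges of the target node and reattaches them to
#' the highest-strength non-neighbor nodes, turning the target into a bridge
#' between well-connected regions and thereby raising its betweenness
#' centrality. The re-anchored bridge edges are given a strong weight (the
#' 90th percentile of the network's positive weights): under the inverse-
#' weight distance rule a weak edge is a long edge that shortest paths avoid,
#' so bridges must be strong to attract paths through the target. Only edges
#' incident to the target node are modified; symmetry and edge count are
#' preserved.
#'
#' @param conn a [connectome()].
#' @param node node label.
#' @param mode `"weight-scale"` or `"edge-rewire-toward-hub"`.
#' @param magnitude positive scalar (a scale factor, or the fraction of the
#'   node's edges to re-anchor).
#' @return A modified [connectome()].
#' @export
inject_node_effect <- function(conn, node,
                               mode = c("weight-scale", "edge-rewire-toward-hub"),
                               magnitude) {
  stopifnot(inherits(conn, "connectome"))
  mode <- match.arg(mode)
  if (!is.numeric(magnitude) || length(magnitude) != 1 || magnitude < 0) {
    param_error("`magnitude` must be a single non-negative number.")
  }
  v <- match(node, conn$labels)
  if (is.na(v)) lookup_error(sprintf("unknown node label '%s'.", node))
  w <- conn$w
  if (mode == "weight-scale") {
    w[v, ] <- w[v, ] * magnitude
    w[, v] <- w[, v] * magnitude
    return(connectome(w, conn$labels))
  }
  nbr <- which(w[v, ] > 0)
  n_move <- round(magnitude * length(nbr))
  if (n_move == 0) return(connectome(w, conn$labels))
  strength <- rowSums(w)
  candidates <- setdiff(order(strength, decreasing = TRUE), c(v, nbr))
  n_move <- min(n_move, length(nbr), length(candidates))
  # move the weakest incident edges onto the strongest non-neighbors,
  # giving the new bridges a strong weight so shortest paths will use them
  move <- nbr[order(w[v, nbr])][seq_len(n_move)]
  anchor <- candidates[seq_len(n_move)]
  bridge_w <- stats::quantile(w[w > 0], 0.9, names = FALSE)
  for (idx in seq_len(n_move)) {
    w[v, move[idx]] <- 0; w[move[idx], v] <- 0
    w[v, anchor[idx]] <- bridge_w; w[anchor[idx], v] <- bridge_w
  }
  connectome(w, conn$labels)
}

#' Flag melancholic-features depression from rating-scale items
#'
#' Applies the two-scale subtype rule: criterion A (MADRS) requires item 8
#' (inability to feel) >= 4, or item 1 or 2 (apparent/reported sadness) >= 6;
#' criterion B (HRSD-17) requires item 1 (depressed mood) or item 7 (work and
#' interest) >= 3 together with at least three of (i) item 6 >= 1 (delayed
#' insomnia), (ii) item 8 or 9 >= 2 (psychomotor retardation/agitation),
#' (iii) item 12 or 16 >= 2 (somatic anxiety or weight loss), (iv) item 2 >= 2
#' (guilt). A subject is melancholic iff both criteria hold. Diurnal mood
#' variation is not assessed by either scale and is omitted from the rule.
#'
#' @param scores data frame with integer item columns `madrs_1`, `madrs_2`,
#'   `madrs_8`, `hrsd_1`, `hrsd_2`, `hrsd_6`, `hrsd_7`, `hrsd_8`, `hrsd_9`,
#'   `hrsd_12`, `hrsd_16` (one row per patient). Missing columns or `NA`
#'   items raise a validation error rather than silently classifying.
#' @return The input as a tibble with a logical `melancholic` column added.
#' @export
#' @examples
#' assign_melancholic_subtype(tibble::tibble(
#'   madrs_1 = 3, madrs_2 = 3, madrs_8 = 4,
#'   hrsd_1 = 3, hrsd_2 = 2, hrsd_6 = 1, hrsd_7 = 2, hrsd_8 = 2,
#'   hrsd_9 = 0, hrsd_12 = 0, hrsd_16 = 0))
assign_melancholic_subtype <- function(scores) {
  scores <- as_tibble(scores)
  need <- names(.item_range)
  missing_cols <- setdiff(need, names(scores))
  if (length(missing_cols)) validation_error(sprintf(
    "missing required item column(s): %s", paste(missing_cols, collapse = ", ")))
  if (anyNA(scores[need])) validation_error("rating-scale items contain NA.")
  mutate(scores, melancholic = melancholic_flag(scores))
}

melancholic_flag <- function(s) {
  crit_a <- s$madrs_8 >= 4 | s$madrs_1 >= 6 | s$madrs_2 >= 6
  b_core <- s$hrsd_1 >= 3 | s$hrsd_7 >= 3
  b_count <- (s$hrsd_6 >= 1) + (s$hrsd_8 >= 2 | s$hrsd_9 >= 2) +
    (s$hrsd_12 >= 2 | s$hrsd_16 >= 2) + (s$hrsd_2 >= 2)
  crit_a & b_core & b_count >= 3
}

rtrunc_norm <- function(n, mean, sd, lower, upper, integer = FALSE) {
  x <- stats::rnorm(n, mean, sd)
  x <- pmin(pmax(x, lower), upper)
  if (integer) round(x) else x
}

# draw one group's phenotype rows; RNG state is managed by the caller
draw_scores <- function(group, n, sm, is_control) {
  pick <- function(var, default_mean = 0, default_sd = 0) {
    r <- sm[sm$group == group & sm$variable == var, ]
    if (nrow(r) == 0) c(default_mean, default_sd) else c(r$mean, r$sd)
  }
  p_male <- pick("p_male", 0.5)[1]
  age <- pick("age", 33, 10)
  edu <- pick("education", 12, 4)
  out <- tibble(
    group = group,
    age = rtrunc_norm(n, age[1], age[2], 18, 45),
    gender = ifelse(stats::runif(n) < p_male, "M", "F"),
    education = rtrunc_norm(n, edu[1], edu[2], 0, 25)
  )
  if (is_control) {
    clin <- c("duration", "madrs_total", "hrsd_total", names(.item_range))
    out[clin] <- NA_real_
    out$melancholic <- FALSE
    return(out)
  }
  dur <- pick("duration", 10, 12)
  mt <- pick("madrs_total", 30, 6)
  out$duration <- rtrunc_norm(n, dur[1], dur[2], 0.5, 120)
  out$madrs_total <- rtrunc_norm(n, mt[1], mt[2], 12, 60, integer = TRUE)
  for (item in names(.item_range)) {
    pr <- pick(item, 1, 1)
    rg <- .item_range[[item]]
    out[[item]] <- rtrunc_norm(n, pr[1], pr[2], rg[1], rg[2], integer = TRUE)
  }
  rest <- pick("hrsd_rest", 9, 3)
  hrsd_items <- rowSums(out[grep("^hrsd_", names(.item_range), value = TRUE)])
  out$hrsd_total <- pmax(17, round(hrsd_items + rtrunc_norm(n, rest[1], rest[2], 0, 30)))
  out
}

# force a drawn patient to match its group's subtype label with minimal edits
reconcile_subtype <- function(df, want_melancholic) {
  flag <- melancholic_flag(df)
  if (want_melancholic) {
    fix <- !flag
    df$madrs_8[fix] <- pmax(df$madrs_8[fix], 4)
    df$hrsd_1[fix] <- pmax(df$hrsd_1[fix], 3)
    df$hrsd_6[fix] <- pmax(df$hrsd_6[fix], 1)
    df$hrsd_8[fix] <- pmax(df$hrsd_8[fix], 2)
    df$hrsd_2[fix] <- pmax(df$hrsd_2[fix], 2)
  } else {
    fix <- flag
    df$madrs_8[fix] <- pmin(df$madrs_8[fix], 3)
    df$madrs_1[fix] <- pmin(df$madrs_1[fix], 5)
    df$madrs_2[fix] <- pmin(df$madrs_2[fix], 5)
  }
  df$melancholic <- melancholic_flag(df)
  df
}

#' Generate a reproducible synthetic cohort
#'
#' Draws one weighted small-world connectome and one phenotype record per
#' subject according to a [cohort_spec()]. Group effects from
#' `spec$effect_spec` are applied only to subjects of the targeted group.
#' Patient rating-scale items are drawn from the score model, truncated to
#' instrument ranges, and minimally adjusted so that every melancholic-group
#' subject satisfies the subtype rule and no non-melancholic subject does;
#' controls carry no clinical scores. Identical specs (including the seed)
#' give bit-identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `melnet_cohort`: `phenotype` (tibble, one row per
#'   subject) and `connectomes` (named list of [connectome()] objects,
#'   parallel to `phenotype$subject_id`), plus the generating `spec`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(
#'   group_sizes = c(HC = 3, `NM-MDD` = 3, `M-MDD` = 2),
#'   n_nodes = 30, k = 4, seed = 1))
#' cohort$phenotype
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- names(spec$group_sizes)
  control <- groups[1]
  pheno <- list()
  conns <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n <- spec$group_sizes[[gi]]
    ids <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", g), seq_len(n))
    scores <- withr::with_seed(derive_seed(spec$seed, 7, gi), {
      df <- draw_scores(g, n, spec$score_model, is_control = g == control)
      if (g != control) df <- reconcile_subtype(df, want_melancholic = g == "M-MDD")
      df
    })
    scores <- bind_cols(tibble(subject_id = ids), scores)
    eff <- spec$effect_spec[spec$effect_spec$group == g, , drop = FALSE]
    for (si in seq_len(n)) {
      conn <- synth_connectome(
        n_nodes = spec$n_nodes, k = spec$k, p = spec$p,
        fa_shape1 = spec$fa_shape1, fa_shape2 = spec$fa_shape2,
        fn_size = spec$fn_size, fn_mu = spec$fn_mu,
        seed = derive_seed(spec$seed, 11, gi, si))
      for (ei in seq_len(nrow(eff))) {
        conn <- inject_node_effect(conn, eff$node[ei], eff$mode[ei], eff$magnitude[ei])
      }
      conns[[ids[si]]] <- conn
    }
    pheno[[gi]] <- scores
  }
  phenotype <- bind_rows(pheno)
  phenotype$group <- factor(phenotype$group, levels = groups)
  structure(list(phenotype = phenotype, connectomes = conns, spec = spec),
            class = "melnet_cohort")
}

#' @export
print.melnet_cohort <- function(x, ...) {
  sizes <- table(x$phenotype$group)
  cat("<melnet_cohort>", paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "),
      sprintf("| %d-node connectomes | seed %d\n", x$spec$n_nodes, x$spec$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Per-subject adjacency matrices as headerless CSV (`<subject_id>.csv`), the
#' phenotype table as `phenotype.csv`, and a JSON manifest recording the seed
#' and full generating spec.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "melnet_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$connectomes)) {
    write_adjacency(cohort$connectomes[[id]], file.path(dir, paste0(id, ".csv")))
  }
  utils::write.csv(cohort$phenotype, file.path(dir, "phenotype.csv"), row.names = FALSE)
  spec <- cohort$spec
  manifest <- list(seed = spec$seed, n_subjects = nrow(cohort$phenotype),
                   spec = unclass(spec))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
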