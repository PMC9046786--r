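test_that("generator is deterministic and respects the base topology", {
  a <- synth_connectome(n_nodes = 40, k = 6, p = 0.1, seed = 11)
  b <- synth_connectome(n_nodes = 40, k = 6, p = 0.1, seed = 11)
  expect_identical(a$w, b$w)
  expect_equal(a$V, 40 * 6 / 2)

  # p = 0: exact ring lattice, every degree k
  rl <- synth_connectome(n_nodes = 30, k = 4, p = 0, seed = 2)
  expect_true(all(rowSums(rl$w > 0) == 4))

  # p = 1: edge count (hence degree-sum) conserved under rewiring
  rw <- synth_connectome(n_nodes = 30, k = 4, p = 1, seed = 2)
  expect_equal(sum(rowSums(rw$w > 0)), 30 * 4)

  # mild rewiring keeps more clustering than full rewiring
  cp <- function(conn) global_metrics(conn, eloc = FALSE)$cp
  expect_gt(cp(synth_connectome(n_nodes = 90, k = 8, p = 0.1, seed = 5)),
            cp(synth_connectome(n_nodes = 90, k = 8, p = 1, seed = 5)))

  expect_error(synth_connectome(n_nodes = 10, k = 5, seed = 1),
               class = "melnet_parameter_error")
  expect_error(synth_connectome(n_nodes = 10, k = 12, seed = 1),
               class = "melnet_parameter_error")
})

test_that("node effects are local, directionally correct, and identity at 1", {
  conn <- synth_connectome(seed = 9)
  same <- inject_node_effect(conn, "ORBinf.R", "weight-scale", 1)
  expect_identical(same$w, conn$w)

  iso <- inject_node_effect(conn, "ORBinf.R", "weight-scale", 0)
  v <- match("ORBinf.R", conn$labels)
  expect_equal(sum(iso$w[v, ]), 0)
  expect_equal(suppressMessages(node_metrics(iso, metrics = "adc"))$adc[v], 0)

  # weight-scale leaves the submatrix excluding the target row/col unchanged
  half <- inject_node_effect(conn, "ORBsup.L", "weight-scale", 0.5)
  u <- match("ORBsup.L", conn$labels)
  expect_identical(half$w[-u, -u], conn$w[-u, -u])
  expect_equal(half$w[u, ], conn$w[u, ] * 0.5)

  expect_error(inject_node_effect(conn, "NOPE", "weight-scale", 1),
               class = "melnet_lookup_error")
})

test_that("hub-bridge rewiring raises the target's betweenness in most draws", {
  abc_at <- function(conn, node) {
    cen <- path_census(conn)
    bc <- node_betweenness(cen)
    bc$abc[bc$node == node]
  }
  hits <- 0
  n_rep <- 30
  for (i in seq_len(n_rep)) {
    conn <- synth_connectome(seed = 700 + i)
    bumped <- inject_node_effect(conn, "CAU.R", "edge-rewire-toward-hub", 0.5)
    # only the target's row/column may change
    v <- match("CAU.R", conn$labels)
    expect_identical(bumped$w[-v, -v], conn$w[-v, -v])
    expect_equal(sum(bumped$w > 0), sum(conn$w > 0))  # edge count preserved
    if (abc_at(bumped, "CAU.R") > abc_at(conn, "CAU.R")) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("melancholic subtype rule follows both scale criteria", {
  base <- tibble::tibble(madrs_1 = 0, madrs_2 = 0, madrs_8 = 0,
                         hrsd_1 = 0, hrsd_2 = 0, hrsd_6 = 0, hrsd_7 = 0,
                         hrsd_8 = 0, hrsd_9 = 0, hrsd_12 = 0, hrsd_16 = 0)
  # A via item 8, B core via HRSD 1 with three subcriteria
  yes <- dplyr::mutate(base, madrs_8 = 4, hrsd_1 = 3, hrsd_6 = 1,
                       hrsd_8 = 2, hrsd_2 = 2)
  expect_true(assign_melancholic_subtype(yes)$melancholic)
  # criterion A fails (items 1/2 below 6, item 8 below 4) whatever HRSD says
  no_a <- dplyr::mutate(yes, madrs_8 = 3, madrs_1 = 5, madrs_2 = 5)
  expect_false(assign_melancholic_subtype(no_a)$melancholic)
  # only two B subcriteria met
  two_b <- dplyr::mutate(base, madrs_1 = 6, hrsd_7 = 3, hrsd_6 = 1, hrsd_9 = 2)
  expect_false(assign_melancholic_subtype(two_b)$melancholic)
  # boundary: A via item 1 = 6 alone
  a1 <- dplyr::mutate(yes, madrs_8 = 0, madrs_1 = 6)
  expect_true(assign_melancholic_subtype(a1)$melancholic)

  # rule is a pure function of the items: column order irrelevant
  shuffled <- yes[, sample(names(yes))]
  expect_identical(assign_melancholic_subtype(shuffled)$melancholic,
                   assign_melancholic_subtype(yes)$melancholic)

  # missing items fail loudly rather than classifying
  expect_error(assign_melancholic_subtype(dplyr::select(yes, -hrsd_6)),
               class = "melnet_validation_error")
  expect_error(assign_melancholic_subtype(dplyr::mutate(yes, hrsd_1 = NA)),
               class = "melnet_validation_error")

  # total on a lattice of valid item combinations
  grid <- tidyr::expand_grid(madrs_8 = c(0, 4), madrs_1 = c(5, 6),
                             hrsd_1 = c(0, 3), hrsd_6 = c(0, 1),
                             hrsd_2 = c(0, 2))
  grid <- dplyr::bind_cols(grid, base[setdiff(names(base), names(grid))])
  out <- assign_melancholic_subtype(grid)
  expect_false(anyNA(out$melancholic))
})

test_that("generated cohorts honor sizes, ranges, groups, and determinism", {
  eff <- tibble::tibble(group = "M-MDD", node = "n5",
                        mode = "edge-rewire-toward-hub", magnitude = 0.25)
  spec <- cohort_spec(group_sizes = c(HC = 6, `NM-MDD` = 5, `M-MDD` = 4),
                      n_nodes = 40, k = 6, effect_spec = eff, seed = 21)
  cohort <- generate_cohort(spec)
  expect_equal(nrow(cohort$phenotype), 15)
  expect_length(cohort$connectomes, 15)
  expect_equal(as.vector(table(cohort$phenotype$group)), c(6, 5, 4))

  # determinism: a fresh run of the same spec is byte-identical
  again <- generate_cohort(spec)
  expect_identical(cohort$phenotype, again$phenotype)
  expect_identical(
    lapply(cohort$connectomes, `[[`, "w"),
    lapply(again$connectomes, `[[`, "w"))

  ph <- cohort$phenotype
  hc <- dplyr::filter(ph, group == "HC")
  pat <- dplyr::filter(ph, group != "HC")
  # controls carry no clinical scores
  expect_true(all(is.na(hc$madrs_total)))
  # patients meet inclusion thresholds and item ranges
  expect_true(all(pat$madrs_total >= 12))
  expect_true(all(pat$hrsd_total >= 17))
  expect_true(all(pat$madrs_8 >= 0 & pat$madrs_8 <= 6))
  expect_true(all(pat$hrsd_7 >= 0 & pat$hrsd_7 <= 4))
  expect_true(all(pat$hrsd_12 >= 0 & pat$hrsd_12 <= 2))
  # subtype flags match group membership
  expect_true(all(dplyr::filter(ph, group == "M-MDD")$melancholic))
  expect_false(any(dplyr::filter(ph, group == "NM-MDD")$melancholic))
  # the flag agrees with an independent application of the rule
  expect_identical(pat$melancholic,
                   assign_melancholic_subtype(dplyr::select(pat, -melancholic))$melancholic)
})

test_that("group effects apply only to the targeted group", {
  eff <- tibble::tibble(group = "M-MDD", node = "n5", mode = "weight-scale",
                        magnitude = 0.2)
  spec <- cohort_spec(group_sizes = c(HC = 8, `NM-MDD` = 3, `M-MDD` = 8),
                      n_nodes = 40, k = 6, effect_spec = eff, seed = 33)
  cohort <- generate_cohort(spec)
  ph <- cohort$phenotype
  strength_n5 <- vapply(cohort$connectomes, function(cn) {
    sum(cn$w[match("n5", cn$labels), ])
  }, 0)
  m_mean <- mean(strength_n5[ph$group == "M-MDD"])
  hc_mean <- mean(strength_n5[ph$group == "HC"])
  expect_lt(m_mean, hc_mean * 0.5)
})

test_that("the default design yields the full three-group study cohort", {
  cohort <- generate_cohort(cohort_spec(seed = 1))
  expect_equal(nrow(cohort$phenotype), 145)
  expect_length(cohort$connectomes, 145)
  expect_equal(as.vector(table(cohort$phenotype$group)), c(63, 59, 23))
  expect_true(all(vapply(cohort$connectomes, function(cn) cn$N, 0L) == 90))
})

test_that("cohort specs reject invalid designs", {
  expect_error(cohort_spec(group_sizes = c(HC = 0, M = 3)),
               class = "melnet_parameter_error")
  expect_error(cohort_spec(k = 7), class = "melnet_parameter_error")
  expect_error(cohort_spec(p = 0), class = "melnet_parameter_error")
  expect_error(cohort_spec(fa_shape1 = -1), class = "melnet_parameter_error")
})

test_that("a cohort round-trips through its on-disk layout", {
  eff <- tibble::tibble(group = "M-MDD", node = "n3",
                        mode = "weight-scale", magnitude = 0.5)
  spec <- cohort_spec(group_sizes = c(HC = 2, `NM-MDD` = 2, `M-MDD` = 2),
                      n_nodes = 30, k = 4, effect_spec = eff, seed = 8)
  cohort <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "phenotype.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  id <- cohort$phenotype$subject_id[1]
  back <- read_adjacency(file.path(dir, paste0(id, ".csv")),
                         labels = cohort$connectomes[[id]]$labels)
  expect_equal(back$w, cohort$connectomes[[id]]$w, tolerance = 1e-9)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 8)
})
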