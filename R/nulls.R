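#' Degree-preserving random null ensemble
#'
#' Generates random reference networks with the same node count, edge count
#' and degree sequence as the input, by Maslov-Sneppen double-edge swaps
#' (10 x V attempted swaps per null). The original edge-weight multiset is
#' preserved: after rewiring, the input's weights are reassigned to the new
#' edge set by a seeded permutation. Graphs admitting no swap (e.g. complete
#' graphs) come back as copies, with a message.
#'
#' @param g a `thresholded_graph` or [connectome()].
#' @param n_null ensemble size (the small-world reference conventionally uses
#'   100).
#' @param seed integer seed; the ensemble is reproducible.
#' @return List of objects of the same class as `g`.
#' @export
generate_null_networks <- function(g, n_null = 100L, seed = 1L) {
  if (n_null < 1) param_error("`n_null` must be at least 1.")
  w <- wadj(g)
  ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected", weighted = TRUE)
  wts <- igraph::E(ig)$weight
  v <- igraph::ecount(ig)
  n <- nrow(w)
  if (v >= n * (n - 1) / 2) inform(
    "graph is complete: no degree-preserving swap exists; returning copies.")
  withr::with_seed(seed, {
    lapply(seq_len(n_null), function(b) {
      gn <- igraph::rewire(ig, igraph::keeping_degseq(niter = 10 * v))
      igraph::E(gn)$weight <- sample(wts)
      wn <- igraph::as_adjacency_matrix(gn, attr = "weight", sparse = FALSE)
      dimnames(wn) <- dimnames(w)
      out <- g
      out$w <- wn
      out
    })
  })
}

#' Small-world indices
#'
#' Normalizes a network's clustering coefficient and characteristic path
#' length by the means of a matched random ensemble: `gamma = Cp / Cp_rand`,
#' `lambda = Lp / Lp_rand`, `sigma = gamma / lambda`. A small-world network
#' has `gamma > 1` with `lambda` near 1, i.e. `sigma > 1`.
#'
#' @param real one-row tibble from [global_metrics()] for the observed
#'   network.
#' @param nulls tibble of [global_metrics()] rows (or list of such rows) for
#'   the null ensemble.
#' @return One-row tibble: `gamma`, `lambda`, `sigma`, `cp_rand`, `lp_rand`,
#'   `n_null`.
#' @export
#' @examples
#' real <- tibble::tibble(cp = 0.5, lp = 2.2)
#' nulls <- tibble::tibble(cp = 0.25, lp = 2.0)
#' small_world_indices(real, nulls)  # gamma 2, lambda 1.1, sigma 1.818...
small_world_indices <- function(real, nulls) {
  if (is.list(nulls) && !is.data.frame(nulls)) nulls <- bind_rows(nulls)
  if (nrow(nulls) < 1) param_error("null ensemble is empty.")
  cp_rand <- mean(nulls$cp)
  lp_rand <- mean(nulls$lp)
  if (!is.finite(cp_rand) || cp_rand <= 0) abort(sprintf(
    "null ensemble mean clustering is %.3g; gamma is undefined (did thresholding leave a forest?).",
    cp_rand), class = "melnet_parameter_error")
  if (!is.finite(lp_rand) || lp_rand <= 0) param_error(
    "null ensemble mean path length is not positive.")
  gamma <- real$cp / cp_rand
  lambda <- real$lp / lp_rand
  tibble(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
         cp_rand = cp_rand, lp_rand = lp_rand, n_null = nrow(nulls))
}

#' Small-world curve across the sparsity grid
#'
#' For each threshold: global metrics of the thresholded network, a
#' degree-preserving null ensemble, and the normalized indices.
#'
#' @inheritParams nodal_metric_curves
#' @param n_null nulls per threshold.
#' @param seed master seed; each threshold draws its ensemble from a derived
#'   child seed.
#' @return Tibble of class `sw_curve`: one row per threshold with `sparsity`,
#'   `cp`, `lp`, `eglob`, `eloc`, `cp_rand`, `lp_rand`, `gamma`, `lambda`,
#'   `sigma`.
#' @export
small_world_curve <- function(conn, grid = sparsity_grid(), n_null = 100L,
                              seed = 1L,
                              distance_rule = c("inverse", "binary")) {
  distance_rule <- match.arg(distance_rule)
  rows <- vector("list", length(grid))
  for (j in seq_along(grid)) {
    tg <- threshold_by_sparsity(conn, grid[j])
    gm <- global_metrics(tg, distance_rule = distance_rule, eloc = TRUE)
    nulls <- generate_null_networks(tg, n_null, derive_seed(seed, 13, j))
    ngm <- bind_rows(lapply(nulls, global_metrics,
                            distance_rule = distance_rule, eloc = FALSE))
    sw <- small_world_indices(gm, ngm)
    rows[[j]] <- bind_cols(tibble(sparsity = as.numeric(grid[j])), gm,
                           sw[, c("cp_rand", "lp_rand", "gamma", "lambda", "sigma")])
  }
  structure(bind_rows(rows), class = c("sw_curve", "tbl_df", "tbl", "data.frame"),
            grid = as.numeric(grid))
}

#' Area under the small-world curves
#'
#' @param curve a [small_world_curve()] result.
#' @param normalize divide by the grid span so the value is the mean level of
#'   the metric over the sparsity range rather than a raw integral.
#' @return Tibble with columns `metric` and `auc`.
#' @export
sw_auc <- function(curve, normalize = FALSE) {
  grid <- attr(curve, "grid")
  if (is.null(grid)) param_error("`curve` must come from small_world_curve().")
  span <- diff(range(grid))
  mets <- c("cp", "lp", "eglob", "eloc", "gamma", "lambda", "sigma")
  tibble(
    metric = mets,
    auc = vapply(mets, function(m) {
      a <- auc_over_grid(curve[[m]], grid)
      if (normalize) a / span else a
    }, 0)
  )
}
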