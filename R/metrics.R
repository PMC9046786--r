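#' Sparsity grid for thresholded network analysis
#'
#' The analysis is repeated over a range of sparsity thresholds (fraction of
#' all possible node pairs kept as edges) to avoid dependence on a single
#' threshold, and metric curves are integrated over the grid. The default
#' covers 5% to 45% in steps of 5%, i.e. the open interval between 5% and 50%
#' sampled on a 0.05 lattice.
#'
#' @param s_min,s_max,step grid bounds and spacing.
#' @return Numeric vector of thresholds with class `sparsity_grid`.
#' @export
#' @examples
#' sparsity_grid()
sparsity_grid <- function(s_min = 0.05, s_max = 0.45, step = 0.05) {
  assert_scalar_number(s_min, "s_min", 0, 1)
  assert_scalar_number(s_max, "s_max", 0, 1)
  if (s_min <= 0 || s_max >= 1 || s_min > s_max || step <= 0) {
    param_error("require 0 < s_min <= s_max < 1 and step > 0.")
  }
  structure(seq(s_min, s_max, by = step), class = "sparsity_grid")
}

#' Threshold a connectome at a given sparsity
#'
#' Keeps the `floor(s * N * (N - 1) / 2)` largest-weight edges (capped at the
#' number of positive edges); ties in weight are broken deterministically by
#' node-index order. Surviving edges keep their weights.
#'
#' @param conn a [connectome()].
#' @param s sparsity in (0, 1).
#' @return An object of class `thresholded_graph` with elements `w`, `labels`,
#'   `N`, `V` (retained edge count), `sparsity` and `parent_V`.
#' @export
#' @examples
#' conn <- synth_connectome(n_nodes = 30, k = 4, seed = 1)
#' threshold_by_sparsity(conn, 0.05)
threshold_by_sparsity <- function(conn, s) {
  stopifnot(inherits(conn, "connectome"))
  assert_scalar_number(s, "s")
  if (s <= 0 || s >= 1) param_error("sparsity `s` must lie strictly in (0, 1).")
  n <- conn$N
  m <- floor(s * n * (n - 1) / 2)
  iu <- which(upper.tri(conn$w) & conn$w > 0, arr.ind = TRUE)
  wv <- conn$w[iu]
  w2 <- matrix(0, n, n, dimnames = dimnames(conn$w))
  if (m < length(wv)) {
    keep <- iu[order(-wv, iu[, 1], iu[, 2])[seq_len(m)], , drop = FALSE]
  } else {
    keep <- iu
  }
  w2[keep] <- conn$w[keep]
  w2[keep[, c(2, 1), drop = FALSE]] <- conn$w[keep]
  structure(list(w = w2, labels = conn$labels, N = n, V = nrow(keep),
                 sparsity = s, parent_V = conn$V),
            class = "thresholded_graph")
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat(sprintf("<thresholded_graph> s = %.2f, %d of %d edges retained\n",
              x$sparsity, x$V, x$parent_V))
  invisible(x)
}

# distance matrix on a weight matrix under a distance rule
dist_matrix <- function(w, distance_rule = c("inverse", "binary")) {
  distance_rule <- match.arg(distance_rule)
  dw <- matrix(0, nrow(w), ncol(w))
  e <- w > 0
  dw[e] <- if (distance_rule == "inverse") 1 / w[e] else 1
  ig <- igraph::graph_from_adjacency_matrix(dw, mode = "undirected", weighted = TRUE)
  igraph::distances(ig, weights = igraph::E(ig)$weight)
}

#' Census of shortest paths
#'
#' For every ordered node pair `(h, j)` computes the shortest-path distance
#' `d_hj` and the number of distinct shortest paths `rho_hj` under the chosen
#' edge-length rule (`"inverse"`: length `1/w_ij`, the standard choice for
#' FA x FN weights; `"binary"`: unit lengths). Unreachable pairs have infinite
#' distance and a path count of zero. The census underlies betweenness:
#' [pass_through_counts()] gives, for an interior node `i`, the number
#' `rho_hj(i)` of those paths passing through `i`.
#'
#' @param g a `thresholded_graph` or [connectome()].
#' @param distance_rule `"inverse"` or `"binary"`.
#' @return Object of class `path_census`: list with the `N x N` matrices `d`
#'   (distances) and `rho` (shortest-path counts, `rho[h, j]`), plus `labels`
#'   and bookkeeping for path reconstruction.
#' @export
path_census <- function(g, distance_rule = c("inverse", "binary")) {
  distance_rule <- match.arg(distance_rule)
  w <- wadj(g)
  n <- nrow(w)
  e <- w > 0
  dwm <- matrix(Inf, n, n)
  dwm[e] <- if (distance_rule == "inverse") 1 / w[e] else 1
  d <- dist_matrix(w, distance_rule)
  nb <- lapply(seq_len(n), function(v) which(e[, v]))
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    ds <- d[s, ]
    sig <- numeric(n)
    sig[s] <- 1
    for (v in order(ds)) {
      if (v == s || !is.finite(ds[v])) next
      u <- nb[[v]]
      pred <- u[abs(ds[u] + dwm[u, v] - ds[v]) <= .melnet_path_tol * (1 + ds[v])]
      sig[v] <- sum(sig[pred])
    }
    sigma[s, ] <- sig
  }
  structure(list(d = d, rho = sigma, dwm = dwm,
                 labels = if (!is.null(g$labels)) g$labels else rownames(w) %||%
                   paste0("n", seq_len(n)),
                 N = n, distance_rule = distance_rule),
            class = "path_census")
}

#' @param census a [path_census()].
#' @param i interior node (index or label).
#' @return `pass_through_counts()`: an `N x N` matrix whose `(h, j)` entry is
#'   `rho_hj(i)`, the number of shortest `h -> j` paths passing through `i`
#'   (zero on the diagonal and whenever `h` or `j` equals `i`).
#' @rdname path_census
#' @export
pass_through_counts <- function(census, i) {
  stopifnot(inherits(census, "path_census"))
  if (is.character(i)) {
    ii <- match(i, census$labels)
    if (is.na(ii)) lookup_error(sprintf("unknown node label '%s'.", i))
    i <- ii
  }
  d <- census$d; sig <- census$rho
  via <- outer(d[, i], d[i, ], "+")
  on_path <- is.finite(via) & abs(via - d) <= .melnet_path_tol * (1 + d)
  cnt <- outer(sig[, i], sig[i, ]) * on_path
  cnt[i, ] <- 0; cnt[, i] <- 0; diag(cnt) <- 0
  cnt
}

#' Normalized node betweenness centrality
#'
#' How often a node acts as the shortest bridge between the other nodes:
#' `aBC(i) = (1 / ((N - 1)(N - 2))) * sum over ordered pairs h != j (both
#' != i) of rho_hj(i) / rho_hj`. The normalization bounds the value in
#' `[0, 1]`; pairs with no connecting path contribute zero.
#'
#' @param census a [path_census()].
#' @return Tibble with columns `node` and `abc`.
#' @export
node_betweenness <- function(census) {
  stopifnot(inherits(census, "path_census"))
  n <- census$N
  if (n < 3) param_error("betweenness is undefined for fewer than 3 nodes.")
  rho <- census$rho
  bc <- vapply(seq_len(n), function(i) {
    cnt <- pass_through_counts(census, i)
    pos <- cnt > 0
    sum(cnt[pos] / rho[pos])
  }, 0)
  tibble(node = census$labels, abc = bc / ((n - 1) * (n - 2)))
}

# Onnela-style weighted clustering per node: geometric mean of triangle
# weights rescaled by the graph-wide maximum; zero where degree < 2.
onnela_clustering <- function(w) {
  k <- rowSums(w > 0)
  mx <- max(w)
  if (mx == 0) return(numeric(nrow(w)))
  wh <- (w / mx)^(1 / 3)
  cyc <- diag(wh %*% wh %*% wh)
  unname(ifelse(k >= 2, cyc / (k * (k - 1)), 0))
}

# all-pairs shortest paths by Floyd-Warshall; fast for the small
# neighbor-induced subgraphs local efficiency works on
dist_small <- function(w, distance_rule) {
  k <- nrow(w)
  d <- matrix(Inf, k, k)
  e <- w > 0
  d[e] <- if (distance_rule == "inverse") 1 / w[e] else 1
  diag(d) <- 0
  for (m in seq_len(k)) d <- pmin(d, outer(d[, m], d[m, ], "+"))
  d
}

# efficiency of the subgraph induced by a node's neighbors
local_efficiency <- function(w, distance_rule) {
  n <- nrow(w)
  vapply(seq_len(n), function(i) {
    nbr <- which(w[i, ] > 0)
    if (length(nbr) < 2) return(0)
    dsub <- dist_small(w[nbr, nbr, drop = FALSE], distance_rule)
    inv <- 1 / dsub
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    sum(inv) / (length(nbr) * (length(nbr) - 1))
  }, 0)
}

#' Global network metrics
#'
#' Characteristic path length `Lp` (mean of finite pairwise distances over
#' connected ordered pairs), global efficiency `Eglob` (mean of `1/d` over all
#' ordered pairs, zero for unreachable ones), clustering coefficient `Cp`
#' (mean of the weighted per-node clustering with triangle weights rescaled by
#' the network maximum), and local efficiency `Eloc` (mean over nodes of the
#' global efficiency of the neighbor-induced subgraph).
#'
#' @param g a `thresholded_graph` or [connectome()].
#' @param census optional precomputed [path_census()] (must use the same
#'   distance rule); distances are recomputed if absent.
#' @param distance_rule `"inverse"` or `"binary"` edge lengths.
#' @param eloc set `FALSE` to skip the (comparatively expensive) local
#'   efficiency, e.g. for null ensembles where only `Cp` and `Lp` are needed.
#' @return One-row tibble with columns `cp`, `lp`, `eglob`, `eloc`.
#' @export
global_metrics <- function(g, census = NULL,
                           distance_rule = c("inverse", "binary"),
                           eloc = TRUE) {
  distance_rule <- match.arg(distance_rule)
  w <- wadj(g)
  if (sum(w > 0) == 0) param_error("graph has no edges.")
  d <- if (!is.null(census)) {
    stopifnot(inherits(census, "path_census"))
    if (census$distance_rule != distance_rule) {
      param_error("census distance rule does not match `distance_rule`.")
    }
    census$d
  } else {
    dist_matrix(w, distance_rule)
  }
  off <- !diag(nrow(d))
  fin <- off & is.finite(d)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  tibble(
    cp = mean(onnela_clustering(w)),
    lp = mean(d[fin]),
    eglob = sum(inv) / sum(off),
    eloc = if (eloc) mean(local_efficiency(w, distance_rule)) else NA_real_
  )
}

#' Nodal metric table
#'
#' Six per-node attributes of a (thresholded) weighted network: betweenness
#' `abc` (see [node_betweenness()]), strength/degree centrality `adc` (sum of
#' incident weights), clustering `acp`, efficiency `aefficiency` (mean inverse
#' distance to the other nodes, unreachable = 0), local efficiency `aeloc`
#' (efficiency of the neighbor subgraph) and mean shortest path length `alp`
#' (mean finite distance to the other nodes; `NA` sentinel for isolated
#' nodes, reported with a message).
#'
#' @inheritParams global_metrics
#' @param metrics subset of the six metric names to compute.
#' @return Tibble with column `node` plus one column per requested metric.
#' @export
node_metrics <- function(g, census = NULL,
                         distance_rule = c("inverse", "binary"),
                         metrics = c("abc", "adc", "acp", "aefficiency",
                                     "aeloc", "alp")) {
  distance_rule <- match.arg(distance_rule)
  metrics <- match.arg(metrics, several.ok = TRUE)
  w <- wadj(g)
  n <- nrow(w)
  labels <- if (!is.null(g$labels)) g$labels else paste0("n", seq_len(n))
  need_census <- "abc" %in% metrics
  need_d <- any(c("aefficiency", "alp") %in% metrics)
  if (is.null(census) && (need_census || need_d)) {
    census <- path_census(g, distance_rule)
  }
  out <- tibble(node = labels)
  if ("abc" %in% metrics) out$abc <- node_betweenness(census)$abc
  if ("adc" %in% metrics) out$adc <- unname(rowSums(w))
  if ("acp" %in% metrics) out$acp <- onnela_clustering(w)
  if (need_d) {
    d <- census$d
    diag(d) <- Inf
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0
    if ("aefficiency" %in% metrics) out$aefficiency <- unname(rowSums(inv) / (n - 1))
    if ("alp" %in% metrics) {
      alp <- unname(apply(d, 1, function(r) {
        f <- r[is.finite(r)]
        if (length(f) == 0) NA_real_ else mean(f)
      }))
      if (anyNA(alp)) inform(sprintf(
        "%d isolated node(s): `alp` recorded as NA sentinel.", sum(is.na(alp))))
      out$alp <- alp
    }
  }
  if ("aeloc" %in% metrics) out$aeloc <- local_efficiency(w, distance_rule)
  out
}

#' Integrate a metric curve over the sparsity grid
#'
#' Trapezoidal integral of one metric value per grid point, the standard way
#' to summarize a thresholded-network metric over the whole sparsity range.
#'
#' @param values numeric vector, one finite value per grid point.
#' @param grid a [sparsity_grid()] (or increasing numeric vector) of the same
#'   length.
#' @return The scalar area under the curve.
#' @export
#' @examples
#' auc_over_grid(rep(2, 9), sparsity_grid())  # 2 * 0.40 = 0.8
auc_over_grid <- function(values, grid) {
  grid <- as.numeric(grid)
  if (length(grid) < 2) param_error("AUC needs at least two grid points.")
  if (length(values) != length(grid)) {
    param_error("`values` must have one entry per grid point.")
  }
  if (any(diff(grid) <= 0)) param_error("`grid` must be strictly increasing.")
  bad <- which(!is.finite(values))
  if (length(bad)) param_error(sprintf(
    "non-finite metric value at threshold(s): %s",
    paste(format(grid[bad]), collapse = ", ")))
  sum(diff(grid) * (values[-1] + values[-length(values)]) / 2)
}

#' Nodal metric curves across the sparsity grid
#'
#' Thresholds a connectome at every grid sparsity and computes the requested
#' nodal metrics at each, returning a long table. When consecutive thresholds
#' retain the identical edge count (the cap at the parent's edge count makes
#' sparse graphs saturate), the computed table is reused rather than
#' recomputed.
#'
#' @inheritParams node_metrics
#' @param conn a [connectome()].
#' @param grid a [sparsity_grid()].
#' @return Tibble of class `nodal_curve` with columns `sparsity`, `node`,
#'   `metric`, `value`.
#' @export
nodal_metric_curves <- function(conn, grid = sparsity_grid(),
                                distance_rule = c("inverse", "binary"),
                                metrics = c("abc", "adc", "acp",
                                            "aefficiency", "aeloc", "alp")) {
  distance_rule <- match.arg(distance_rule)
  rows <- vector("list", length(grid))
  last_v <- -1L
  last_tbl <- NULL
  for (j in seq_along(grid)) {
    tg <- threshold_by_sparsity(conn, grid[j])
    if (tg$V != last_v) {
      last_tbl <- node_metrics(tg, distance_rule = distance_rule, metrics = metrics)
      last_v <- tg$V
    }
    rows[[j]] <- mutate(
      pivot_longer(last_tbl, -"node", names_to = "metric", values_to = "value"),
      sparsity = grid[j], .before = 1)
  }
  structure(bind_rows(rows), class = c("nodal_curve", "tbl_df", "tbl", "data.frame"),
            grid = as.numeric(grid))
}

#' Area under each nodal metric curve
#'
#' @param curves a [nodal_metric_curves()] result.
#' @return Tibble with columns `node`, `metric`, `auc`. Curves containing a
#'   non-finite value (isolated-node sentinel) yield `NA` with a message.
#' @export
nodal_auc <- function(curves) {
  grid <- attr(curves, "grid")
  if (is.null(grid)) param_error("`curves` must come from nodal_metric_curves().")
  out <- summarise(
    group_by(as_tibble(curves), .data$node, .data$metric),
    auc = if (all(is.finite(.data$value))) {
      auc_over_grid(.data$value, .env$grid)
    } else NA_real_,
    .groups = "drop")
  if (anyNA(out$auc)) inform(sprintf(
    "%d node/metric curve(s) contain sentinel values; AUC set to NA.",
    sum(is.na(out$auc))))
  out
}
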