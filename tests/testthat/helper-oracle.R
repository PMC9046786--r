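# Brute-force reference implementations used as independent oracles.
# All shortest-path quantities are obtained by exhaustive enumeration of
# simple paths (depth-first), never by the package's Dijkstra-based census.

oracle_tol <- 1e-9

# enumerate all simple paths between every ordered pair; returns distances,
# shortest-path counts and the per-interior-node pass-through array
oracle_census <- function(w, rule = "inverse") {
  n <- nrow(w)
  len <- matrix(Inf, n, n)
  len[w > 0] <- if (rule == "inverse") 1 / w[w > 0] else 1
  d <- matrix(Inf, n, n); diag(d) <- 0
  rho <- matrix(0, n, n); diag(rho) <- 1
  through <- array(0, c(n, n, n))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      paths <- list()
      rec <- function(v, visited, dist, path) {
        if (v == b) {
          paths[[length(paths) + 1]] <<- list(dist = dist, path = path)
          return()
        }
        for (u in which(w[v, ] > 0)) {
          if (!visited[u]) {
            visited[u] <- TRUE
            rec(u, visited, dist + len[v, u], c(path, u))
            visited[u] <- FALSE
          }
        }
      }
      vis <- rep(FALSE, n); vis[a] <- TRUE
      rec(a, vis, 0, a)
      if (!length(paths)) next
      dists <- vapply(paths, `[[`, 0, "dist")
      dmin <- min(dists)
      sel <- which(dists <= dmin + oracle_tol * (1 + dmin))
      d[a, b] <- dmin
      rho[a, b] <- length(sel)
      for (s in sel) {
        interior <- setdiff(paths[[s]]$path, c(a, b))
        through[a, b, interior] <- through[a, b, interior] + 1
      }
    }
  }
  list(d = d, rho = rho, through = through)
}

oracle_abc <- function(oc) {
  n <- nrow(oc$d)
  vapply(seq_len(n), function(i) {
    tot <- 0
    for (h in seq_len(n)) {
      for (j in seq_len(n)) {
        if (h == j || h == i || j == i || oc$rho[h, j] == 0) next
        tot <- tot + oc$through[h, j, i] / oc$rho[h, j]
      }
    }
    tot / ((n - 1) * (n - 2))
  }, 0)
}

# naive (triple-loop / enumeration) versions of all nodal and global metrics
oracle_metrics <- function(w, rule = "inverse") {
  n <- nrow(w)
  oc <- oracle_census(w, rule)
  d <- oc$d
  mx <- max(w)
  acp <- vapply(seq_len(n), function(i) {
    k <- sum(w[i, ] > 0)
    if (k < 2) return(0)
    tot <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j == i || h == i || j == h) next
        if (w[i, j] > 0 && w[i, h] > 0 && w[j, h] > 0) {
          tot <- tot + (w[i, j] * w[i, h] * w[j, h] / mx^3)^(1 / 3)
        }
      }
    }
    tot / (k * (k - 1))
  }, 0)
  aeff <- vapply(seq_len(n), function(i) {
    x <- d[i, -i]
    sum(ifelse(is.finite(x) & x > 0, 1 / x, 0)) / (n - 1)
  }, 0)
  alp <- vapply(seq_len(n), function(i) {
    x <- d[i, -i]; x <- x[is.finite(x)]
    if (!length(x)) NA_real_ else mean(x)
  }, 0)
  aeloc <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    ds <- oracle_census(w[nb, nb, drop = FALSE], rule)$d
    iv <- 1 / ds; diag(iv) <- 0; iv[!is.finite(iv)] <- 0
    sum(iv) / (length(nb) * (length(nb) - 1))
  }, 0)
  off <- !diag(n)
  fin <- off & is.finite(d)
  inv <- 1 / d; inv[!is.finite(inv)] <- 0; diag(inv) <- 0
  list(abc = if (n >= 3) oracle_abc(oc) else NULL,
       adc = rowSums(w), acp = acp, aefficiency = aeff, aeloc = aeloc,
       alp = alp,
       cp = mean(acp), lp = mean(d[fin]), eglob = sum(inv) / sum(off),
       eloc = mean(aeloc))
}

bfs_connected <- function(w) {
  n <- nrow(w)
  visited <- rep(FALSE, n)
  stack <- 1L
  visited[1] <- TRUE
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    nb <- which(w[v, ] > 0 & !visited)
    visited[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(visited)
}

rand_weighted_graph <- function(n, p_edge, seed) {
  withr::with_seed(seed, {
    repeat {
      w <- matrix(0, n, n)
      iu <- which(upper.tri(w), arr.ind = TRUE)
      on <- stats::runif(nrow(iu)) < p_edge
      w[iu[on, , drop = FALSE]] <- stats::runif(sum(on), 0.2, 5)
      w <- w + t(w)
      if (sum(on) >= n - 1 && bfs_connected(w)) return(w)
    }
  })
}

# all labeled connected graphs on n nodes (edge sets by bitmask), with
# deterministic non-unit weights attached
enumerate_connected_graphs <- function(n, weighted = TRUE) {
  iu <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(iu)
  out <- list()
  for (mask in seq_len(2^m) - 1L) {
    on <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1)))
    if (sum(on) < n - 1) next
    w <- matrix(0, n, n)
    wts <- if (weighted) 0.5 + 0.37 * seq_len(sum(on)) else rep(1, sum(on))
    w[iu[on, , drop = FALSE]] <- wts
    w <- w + t(w)
    if (bfs_connected(w)) out[[length(out) + 1]] <- w
  }
  out
}

# unit-weight ring lattice (each node joined to its k nearest neighbors)
ring_lattice <- function(n, k) {
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (step in seq_len(k / 2)) {
      j <- ((i - 1 + step) %% n) + 1
      w[i, j] <- 1; w[j, i] <- 1
    }
  }
  w
}

expect_metrics_match <- function(w, rule = "inverse", tol = 1e-9) {
  conn <- connectome(w)
  oc <- oracle_metrics(w, rule)
  nm <- suppressMessages(node_metrics(conn, distance_rule = rule))
  gm <- global_metrics(conn, distance_rule = rule)
  expect_equal(nm$abc, oc$abc, tolerance = tol)
  expect_equal(nm$adc, oc$adc, tolerance = tol)
  expect_equal(nm$acp, oc$acp, tolerance = tol)
  expect_equal(nm$aefficiency, oc$aefficiency, tolerance = tol)
  expect_equal(nm$aeloc, oc$aeloc, tolerance = tol)
  expect_equal(nm$alp, oc$alp, tolerance = tol)
  expect_equal(gm$cp, oc$cp, tolerance = tol)
  expect_equal(gm$lp, oc$lp, tolerance = tol)
  expect_equal(gm$eglob, oc$eglob, tolerance = tol)
  expect_equal(gm$eloc, oc$eloc, tolerance = tol)
}

# independent reference for larger graphs where DFS enumeration is infeasible:
# distances/betweenness from igraph, clustering and efficiencies from naive loops
oracle_metrics_ig <- function(w, rule = "inverse") {
  n <- nrow(w)
  ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected", weighted = TRUE)
  dw <- if (rule == "inverse") 1 / igraph::E(ig)$weight else rep(1, igraph::ecount(ig))
  d <- unname(igraph::distances(ig, weights = dw))
  abc <- unname(igraph::betweenness(ig, weights = dw)) * 2 / ((n - 1) * (n - 2))
  mx <- max(w)
  acp <- vapply(seq_len(n), function(i) {
    k <- sum(w[i, ] > 0)
    if (k < 2) return(0)
    tot <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j == i || h == i || j == h) next
        if (w[i, j] > 0 && w[i, h] > 0 && w[j, h] > 0) {
          tot <- tot + (w[i, j] * w[i, h] * w[j, h] / mx^3)^(1 / 3)
        }
      }
    }
    tot / (k * (k - 1))
  }, 0)
  aeff <- vapply(seq_len(n), function(i) {
    x <- d[i, -i]
    sum(ifelse(is.finite(x) & x > 0, 1 / x, 0)) / (n - 1)
  }, 0)
  alp <- vapply(seq_len(n), function(i) {
    x <- d[i, -i]; x <- x[is.finite(x)]
    if (!length(x)) NA_real_ else mean(x)
  }, 0)
  aeloc <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    sg <- igraph::graph_from_adjacency_matrix(w[nb, nb, drop = FALSE],
                                              mode = "undirected", weighted = TRUE)
    dwn <- if (rule == "inverse") 1 / igraph::E(sg)$weight else
      rep(1, igraph::ecount(sg))
    ds <- unname(igraph::distances(sg, weights = dwn))
    iv <- 1 / ds; diag(iv) <- 0; iv[!is.finite(iv)] <- 0
    sum(iv) / (length(nb) * (length(nb) - 1))
  }, 0)
  off <- !diag(n)
  fin <- off & is.finite(d)
  inv <- 1 / d; inv[!is.finite(inv)] <- 0; diag(inv) <- 0
  list(abc = abc, adc = rowSums(w), acp = acp, aefficiency = aeff,
       aeloc = aeloc, alp = alp,
       cp = mean(acp), lp = mean(d[fin]), eglob = sum(inv) / sum(off),
       eloc = mean(aeloc))
}
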