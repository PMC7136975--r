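# shared fixtures built in code

# deterministic random raster
rand_raster <- function(nr = 16, nc = 16, seed = 1, cell_size = 1) {
  set.seed(seed)
  raster_grid(matrix(rnorm(nr * nc), nr, nc), cell_size = cell_size)
}

# site set on a grid of cell centres
grid_sites <- function(r, rows, cols) {
  xy <- cell_centers(r, rows, cols)
  site_set(sprintf("S%02d", seq_along(rows)), xy[, 1], xy[, 2])
}

# random site set in a box
rand_sites <- function(n, seed = 1, extent = 1e4) {
  set.seed(seed)
  site_set(sprintf("S%02d", 1:n), runif(n) * extent, runif(n) * extent)
}

# direct dense multivariate-normal log-likelihood of the MLPE model,
# independent of the profiled-likelihood fitting route
mvn_mlpe_loglik <- function(y, Xf, sites, beta, sigma_u2, sigma_e2) {
  Z <- pairscape:::mlpe_incidence(sites)
  V <- sigma_e2 * diag(length(y)) + sigma_u2 * tcrossprod(Z)
  r <- y - Xf %*% beta
  as.numeric(-0.5 * (length(y) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       t(r) %*% solve(V, r)))
}

# expected commute time between two nodes of a conductance-weighted
# graph via first-step analysis: solves the hitting-time linear system
# in both directions and sums them
commute_oracle <- function(g, i, j) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$conductance
  W <- matrix(0, n, n)
  W[el] <- W[el] + w
  W[el[, 2:1, drop = FALSE]] <- W[el[, 2:1, drop = FALSE]] + w
  P <- W / rowSums(W)
  hit <- function(target) {
    # h[k] = 1 + sum_l P[k,l] h[l], h[target] = 0
    keep <- setdiff(seq_len(n), target)
    A <- diag(length(keep)) - P[keep, keep, drop = FALSE]
    h <- solve(A, rep(1, length(keep)))
    out <- numeric(n)
    out[keep] <- h
    out
  }
  hit(j)[i] + hit(i)[j]
}

# random connected conductance-weighted graph on <= nmax nodes
rand_graph <- function(seed, nmax = 25) {
  set.seed(seed)
  n <- sample(3:nmax, 1)
  repeat {
    g <- igraph::sample_gnp(n, p = min(1, 2.5 / n))
    if (igraph::is_connected(g)) break
  }
  igraph::E(g)$conductance <- runif(igraph::ecount(g), 0.2, 5)
  g
}

# exhaustive simple-path least-cost oracle (DFS over all simple paths)
lcp_oracle <- function(g, from, to) {
  res <- 1 / igraph::E(g)$conductance
  adj <- igraph::as_adj_list(g)
  best <- Inf
  visit <- function(v, cost, seen) {
    if (cost >= best) return(invisible())
    if (v == to) { best <<- cost; return(invisible()) }
    for (u in as.integer(adj[[v]])) {
      if (!seen[u]) {
        eid <- igraph::get_edge_ids(g, c(v, u))
        seen[u] <- TRUE
        visit(u, cost + res[eid], seen)
        seen[u] <- FALSE
      }
    }
  }
  seen <- rep(FALSE, igraph::vcount(g))
  seen[from] <- TRUE
  visit(from, 0, seen)
  best
}
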