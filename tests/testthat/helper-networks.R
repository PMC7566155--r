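# Shared fixtures: the two-node worked example and seeded random
# generators for interval specs and small credal networks.

toy_ab_network <- function() {
  credal_network(
    list(A = c("a1", "a2"), B = c("b1", "b2")),
    parents = list(B = "A"),
    tables = list(
      A = list(credal_set(c(0.4, 0.4), c(0.6, 0.6))),
      B = list(credal_set(c(0.7, 0.1), c(0.9, 0.3)),
               credal_set(c(0.1, 0.7), c(0.3, 0.9)))))
}

toy_chain_bn <- function() {
  credal_network(
    list(A = c("a1", "a2"), B = c("b1", "b2")),
    parents = list(B = "A"),
    tables = list(
      A = list(credal_set(c(0.5, 0.5), c(0.5, 0.5))),
      B = list(credal_set(c(0.8, 0.2), c(0.8, 0.2)),
               credal_set(c(0.2, 0.8), c(0.2, 0.8)))))
}

## A coherent random interval spec around a random simplex point.
random_interval_spec <- function(k) {
  p <- runif(k); p <- p / sum(p)
  l <- pmax(0, p - runif(k, 0, 0.4))
  u <- pmin(1, p + runif(k, 0, 0.4))
  list(l = l, u = u)
}

## Random small credal network: `n_nodes` nodes in topological order,
## each with up to `max_parents` earlier nodes as parents; a share of
## the tables is interval-valued (narrow enough to keep vertex counts
## small), the rest point-valued.
random_small_network <- function(n_nodes = 4, max_states = 3,
                                 max_parents = 2, p_interval = 0.4,
                                 width = 0.2) {
  nm <- paste0("V", seq_len(n_nodes))
  vars <- lapply(seq_len(n_nodes), function(i)
    paste0("s", seq_len(sample(2:max_states, 1))))
  names(vars) <- nm
  parents <- list()
  for (i in seq_len(n_nodes)[-1]) {
    np <- sample(0:min(max_parents, i - 1L), 1)
    if (np > 0) parents[[nm[i]]] <- sample(nm[seq_len(i - 1L)], np)
  }
  net0 <- credal_network(vars, parents, tables = list())
  tables <- lapply(nm, function(v) {
    m <- credalpod:::n_parent_configs(net0, v)
    k <- length(vars[[v]])
    lapply(seq_len(m), function(j) {
      p <- runif(k); p <- p / sum(p)
      if (runif(1) < p_interval) {
        l <- pmax(0, p - runif(k, 0, width))
        u <- pmin(1, p + runif(k, 0, width))
        credal_set(l, u, states = vars[[v]])
      } else credal_set(p, p, states = vars[[v]])
    })
  })
  names(tables) <- nm
  credal_network(vars, parents, tables)
}

## Point-valued version of any credal network (one fixed vertex each).
pointify_network <- function(net, rule = "first") {
  verts <- lapply(net$tables, function(tab) lapply(tab, enumerate_vertices))
  for (v in names(net$tables))
    net$tables[[v]] <- lapply(seq_along(net$tables[[v]]), function(j) {
      p <- verts[[v]][[j]][1L, ]
      credal_set(p, p, states = net$variables[[v]])
    })
  net
}

## CPT list (k x n_cfg matrices) from a point network, for the oracles.
point_cpts <- function(net) {
  verts <- lapply(net$tables, function(tab) lapply(tab, enumerate_vertices))
  out <- lapply(names(net$variables), function(v) {
    m <- length(verts[[v]])
    k <- length(net$variables[[v]])
    cp <- matrix(0, k, m)
    for (j in seq_len(m)) cp[, j] <- verts[[v]][[j]][1L, ]
    cp
  })
  names(out) <- names(net$variables)
  out
}

## Random vertex selection as CPT list, for containment checks.
random_vertex_cpts <- function(verts, vars) {
  out <- lapply(names(vars), function(v) {
    m <- length(verts[[v]])
    k <- length(vars[[v]])
    cp <- matrix(0, k, m)
    for (j in seq_len(m)) {
      V <- verts[[v]][[j]]
      cp[, j] <- V[sample.int(nrow(V), 1L), ]
    }
    cp
  })
  names(out) <- names(vars)
  out
}
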