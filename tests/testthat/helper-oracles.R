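# Independent oracles used to cross-check the implementation.  These
# deliberately use different algorithms from the package code paths:
# bound-assignment enumeration instead of active-set search for
# vertices, and full joint-outcome enumeration instead of variable
# elimination for posteriors.

## Vertices of {p : sum(p) = 1, l <= p <= u} (no orderings): every
## vertex has at most one coordinate strictly between its bounds, so
## enumerate all bound assignments with one free coordinate.
oracle_interval_vertices <- function(l, u, tol = 1e-9) {
  k <- length(l)
  out <- matrix(numeric(0), 0, k)
  add <- function(p) {
    if (any(p < l - tol) || any(p > u + tol)) return()
    if (nrow(out) == 0L ||
        all(apply(abs(out - matrix(p, nrow(out), k, byrow = TRUE)), 1, max) > tol))
      out <<- rbind(out, p)
  }
  for (free in seq_len(k)) {
    others <- setdiff(seq_len(k), free)
    grid <- expand.grid(rep(list(c(1L, 2L)), k - 1L))
    for (r in seq_len(nrow(grid))) {
      p <- numeric(k)
      for (j in seq_along(others)) {
        i <- others[j]
        p[i] <- if (grid[r, j] == 1L) l[i] else u[i]
      }
      p[free] <- 1 - sum(p[others])
      add(p)
    }
  }
  rownames(out) <- NULL
  out
}

## Sort vertex rows lexicographically so sets can be compared.
sort_vertices <- function(V, digits = 7) {
  if (nrow(V) == 0L) return(V)
  Vr <- round(V, digits)
  V[do.call(order, as.data.frame(Vr)), , drop = FALSE]
}

expect_same_vertex_set <- function(A, B, tol = 1e-7) {
  expect_equal(nrow(A), nrow(B))
  A <- sort_vertices(A); B <- sort_vertices(B)
  expect_lt(max(abs(unname(A) - unname(B))), tol)
}

## Fast full-joint evaluator for small networks: precomputes, for each
## variable, the linear index into its flattened CPT matrix for every
## joint outcome; a joint probability vector is then a product of
## gathered columns.  Completely independent of the package's
## elimination engine (only the canonical first-parent-fastest
## configuration order is shared convention).
oracle_joint_indexer <- function(vars, parents) {
  ks <- vapply(vars, length, 1L)
  outcomes <- expand.grid(lapply(vars, seq_along), KEEP.OUT.ATTRS = FALSE)
  names(outcomes) <- names(vars)
  idx <- lapply(names(vars), function(v) {
    p <- parents[[v]]
    cfg <- rep(1L, nrow(outcomes))
    if (length(p)) {
      mult <- 1L
      for (pp in p) {
        cfg <- cfg + (outcomes[[pp]] - 1L) * mult
        mult <- mult * ks[[pp]]
      }
    }
    ## linear index into k x n_cfg matrix, column-major
    (cfg - 1L) * ks[[v]] + outcomes[[v]]
  })
  names(idx) <- names(vars)
  list(outcomes = outcomes, idx = idx)
}

oracle_joint_probs <- function(indexer, cpts) {
  p <- rep(1, nrow(indexer$outcomes))
  for (v in names(indexer$idx)) p <- p * cpts[[v]][indexer$idx[[v]]]
  p
}

## P(target = state | evidence) by joint enumeration; NA if P(evidence)=0.
oracle_posterior <- function(indexer, cpts, target_var, target_idx,
                             evidence_idx = list()) {
  p <- oracle_joint_probs(indexer, cpts)
  keep <- rep(TRUE, length(p))
  for (v in names(evidence_idx))
    keep <- keep & indexer$outcomes[[v]] == evidence_idx[[v]]
  pe <- sum(p[keep])
  if (pe <= 0) return(NA_real_)
  sum(p[keep & indexer$outcomes[[target_var]] == target_idx]) / pe
}

## Brute-force strong-extension bounds: enumerate every combination of
## one vertex per (variable, parent configuration) and min/max the
## oracle posterior over combinations with positive evidence probability.
oracle_bounds <- function(net, target, evidence = NULL, do = NULL) {
  if (length(do)) net <- mutilate(net, do)
  vars <- net$variables
  indexer <- oracle_joint_indexer(vars, net$parents)
  verts <- lapply(net$tables, function(tab)
    lapply(tab, enumerate_vertices))
  tv <- names(target)
  tidx <- match(target[[1L]], vars[[tv]])
  eidx <- list()
  fixed <- c(evidence, do)
  for (v in names(fixed)) eidx[[v]] <- match(fixed[[v]], vars[[v]])
  slots <- list()
  for (v in names(vars)) for (j in seq_along(verts[[v]]))
    slots[[length(slots) + 1L]] <- list(var = v, cfg = j,
                                        n = nrow(verts[[v]][[j]]))
  radix <- vapply(slots, `[[`, 1L, "n")
  sel <- rep(1L, length(radix))
  lo <- Inf; hi <- -Inf; any_zero <- FALSE
  repeat {
    cpts <- lapply(names(vars), function(v) {
      k <- length(vars[[v]])
      m <- length(verts[[v]])
      out <- matrix(0, k, m)
      for (j in seq_len(m)) out[, j] <- verts[[v]][[j]][1L, ]
      out
    })
    names(cpts) <- names(vars)
    for (s in seq_along(slots))
      cpts[[slots[[s]]$var]][, slots[[s]]$cfg] <-
        verts[[slots[[s]]$var]][[slots[[s]]$cfg]][sel[s], ]
    p <- if (tv %in% names(eidx)) {
      pe_keep <- rep(TRUE, nrow(indexer$outcomes))
      pr <- oracle_joint_probs(indexer, cpts)
      for (v in names(eidx))
        pe_keep <- pe_keep & indexer$outcomes[[v]] == eidx[[v]]
      if (sum(pr[pe_keep]) <= 0) NA_real_
      else as.numeric(eidx[[tv]] == tidx)
    } else oracle_posterior(indexer, cpts, tv, tidx, eidx)
    if (is.na(p)) any_zero <- TRUE
    else { lo <- min(lo, p); hi <- max(hi, p) }
    i <- 1L
    while (i <= length(radix)) {
      sel[i] <- sel[i] + 1L
      if (sel[i] <= radix[i]) break
      sel[i] <- 1L; i <- i + 1L
    }
    if (length(radix) == 0L || i > length(radix)) break
  }
  if (!is.finite(lo)) return(NULL)
  list(lower = lo, upper = hi, any_zero = any_zero)
}
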