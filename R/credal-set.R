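#' Credal sets over one variable: intervals plus qualitative orderings
#'
#' A `credal_set` describes the convex set of probability mass functions
#' an expert is willing to commit to for one variable (given one parent
#' configuration): per-state probability intervals, optionally sharpened
#' by pairwise comparative judgments of the form "state a is at least as
#' probable as state b".  Geometrically it is a bounded polytope inside
#' the probability simplex; inference optimises over its finitely many
#' extreme points (see [enumerate_vertices()]).
#'
#' @param lower numeric vector of lower bounds, or an
#'   [interval_distribution()] (then `upper` is ignored).
#' @param upper numeric vector of upper bounds.
#' @param orderings list of length-2 vectors `c(a, b)` meaning
#'   `p[a] >= p[b]`; states may be given by label (when `states` is
#'   supplied) or by index.
#' @param states optional character vector of state labels.
#' @return Object of class `credal_set` with fields `base`
#'   (the interval distribution) and `orderings` (integer matrix with
#'   columns `greater`, `less`).
#' @examples
#' cs <- credal_set(c(0.2, 0.4), c(0.6, 0.8), orderings = list(c(1, 2)))
#' enumerate_vertices(cs)
#' @export
credal_set <- function(lower, upper = NULL, orderings = NULL, states = NULL) {
  base <- if (inherits(lower, "interval_distribution")) lower
  else interval_distribution(lower, upper, states = states)
  states <- base$states
  k <- length(base$lower)
  ord <- matrix(integer(0), ncol = 2L,
                dimnames = list(NULL, c("greater", "less")))
  if (length(orderings)) {
    rows <- lapply(orderings, function(o) {
      if (length(o) != 2L)
        stop_credal("credalpod_structural_error",
                    "each ordering must name exactly two states")
      idx <- if (is.character(o)) {
        if (is.null(states))
          stop_credal("credalpod_structural_error",
                      "state labels used in orderings but no states given")
        m <- match(o, states)
        if (anyNA(m))
          stop_credal("credalpod_structural_error",
                      "unknown state '%s' in ordering", o[is.na(m)][1L])
        m
      } else as.integer(o)
      if (any(idx < 1L | idx > k) || idx[1L] == idx[2L])
        stop_credal("credalpod_structural_error",
                    "invalid ordering indices (%s)", paste(idx, collapse = ","))
      idx
    })
    ord <- do.call(rbind, rows)
    colnames(ord) <- c("greater", "less")
  }
  structure(list(base = base, orderings = ord), class = "credal_set")
}

#' @export
print.credal_set <- function(x, ...) {
  print(x$base, ...)
  if (nrow(x$orderings)) {
    lab <- x$base$states %||% paste0("s", seq_along(x$base$lower))
    for (i in seq_len(nrow(x$orderings)))
      cat(sprintf("  p(%s) >= p(%s)\n",
                  lab[x$orderings[i, 1L]], lab[x$orderings[i, 2L]]))
  }
  invisible(x)
}

as_credal_set <- function(x) {
  if (inherits(x, "credal_set")) return(x)
  if (inherits(x, "interval_distribution")) return(credal_set(x))
  stop_credal("credalpod_structural_error",
              "cannot interpret object of class '%s' as a credal set",
              class(x)[1L])
}

## Half-space representation of the credal-set polytope on the hyperplane
## sum(p) = 1: rows of G p >= h cover l <= p, p <= u and orderings.
credal_halfspaces <- function(spec) {
  k <- length(spec$base$lower)
  G <- rbind(diag(k), -diag(k))
  h <- c(spec$base$lower, -spec$base$upper)
  if (nrow(spec$orderings)) {
    Go <- matrix(0, nrow(spec$orderings), k)
    for (i in seq_len(nrow(spec$orderings))) {
      Go[i, spec$orderings[i, 1L]] <- 1
      Go[i, spec$orderings[i, 2L]] <- -1
    }
    G <- rbind(G, Go)
    h <- c(h, rep(0, nrow(spec$orderings)))
  }
  list(G = G, h = h)
}

#' Enumerate the extreme points of a credal set
#'
#' Performs exact vertex enumeration of the polytope
#' `{p : sum(p) = 1, l <= p <= u, orderings}` by exhausting active
#' constraint sets: every vertex lies on `k - 1` linearly independent
#' facets in addition to the simplex hyperplane, so all `k-1`-subsets of
#' the half-space rows are solved and feasibility-filtered.  Complexity is
#' combinatorial in the number of states, hence the explicit cap: credal
#' tables here are small by design and exceeding the cap is an error
#' rather than a silent truncation.
#'
#' @param spec a [credal_set()] (or [interval_distribution()]).
#' @param cap maximum number of states accepted (default 6).
#' @param tol vertex deduplication / feasibility tolerance (default 1e-9;
#'   adequate for double precision at these dimensions).
#' @return Numeric matrix, one row per vertex (each a valid probability
#'   distribution), columns named by state when labels are available.
#'   Signals a feasibility error when the polytope is empty.
#' @examples
#' enumerate_vertices(credal_set(c(0.2, 0.4), c(0.6, 0.8)))
#' @export
enumerate_vertices <- function(spec, cap = 6L, tol = 1e-9) {
  spec <- as_credal_set(spec)
  k <- length(spec$base$lower)
  if (k > cap)
    stop_credal("credalpod_size_error",
                "%d states exceed the enumeration cap of %d", k, cap)
  if (!is_coherent(spec$base))
    stop_credal("credalpod_feasibility_error",
                "credal set is empty: %s",
                paste(check_coherence(spec$base)$violations, collapse = "; "))
  hs <- credal_halfspaces(spec)
  G <- hs$G; h <- hs$h
  m <- nrow(G)
  verts <- matrix(numeric(0), 0L, k)
  sel <- utils::combn(m, k - 1L)
  ones <- rep(1, k)
  for (j in seq_len(ncol(sel))) {
    A <- rbind(G[sel[, j], , drop = FALSE], ones)
    b <- c(h[sel[, j]], 1)
    qa <- qr(A)
    if (qa$rank < k) next
    p <- tryCatch(qr.coef(qa, b), error = function(e) NULL)
    if (is.null(p) || anyNA(p)) next
    if (any(G %*% p < h - tol)) next
    if (nrow(verts) == 0L ||
        all(apply(abs(verts - matrix(p, nrow(verts), k, byrow = TRUE)), 1L,
                  max) > tol))
      verts <- rbind(verts, p)
  }
  if (nrow(verts) == 0L)
    stop_credal("credalpod_feasibility_error",
                "credal set is empty (interval and ordering constraints are contradictory)")
  ## snap coordinates within tol of 0/1 (active-set solve noise),
  ## clamp and renormalise exactly
  verts[abs(verts) < tol] <- 0
  verts[abs(verts - 1) < tol] <- 1
  verts <- pmin(pmax(verts, 0), 1)
  verts <- verts / rowSums(verts)
  rownames(verts) <- NULL
  colnames(verts) <- spec$base$states %||% paste0("s", seq_len(k))
  verts
}

## TRUE iff the credal set is non-empty (exact: a non-empty bounded
## polytope always has a vertex, which exhaustive enumeration finds).
credal_feasible <- function(spec, cap = 6L, tol = 1e-9) {
  spec <- as_credal_set(spec)
  if (!is_coherent(spec$base)) return(FALSE)
  if (nrow(spec$orderings) == 0L) return(TRUE)
  !inherits(tryCatch(enumerate_vertices(spec, cap = cap, tol = tol),
                     credalpod_feasibility_error = function(e) e),
            "credalpod_feasibility_error")
}

## Tighten a credal set to its reachable hull: per-coordinate min/max over
## the vertex set (equivalent to the closed form when there are no
## orderings, and exact in general for this constraint family).
tighten_credal_set <- function(spec, cap = 6L, tol = 1e-9) {
  spec <- as_credal_set(spec)
  if (nrow(spec$orderings) == 0L)
    return(credal_set(normalize_reachable(spec$base)))
  V <- enumerate_vertices(spec, cap = cap, tol = tol)
  credal_set(interval_distribution(apply(V, 2L, min), apply(V, 2L, max),
                                   states = spec$base$states),
             orderings = apply(spec$orderings, 1L, identity, simplify = FALSE))
}

## Single-vertex test used to detect point (Bayesian) tables.
is_point_set <- function(spec, tol = 1e-12) {
  spec <- as_credal_set(spec)
  all(spec$base$upper - spec$base$lower <= tol)
}
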