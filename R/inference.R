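#' Exact posterior in a point-valued (Bayesian) network
#'
#' Computes `P(target | evidence)` by exact variable elimination.  This is
#' the probabilistic core everything else reduces to: the credal bounds in
#' [posterior_bounds()] are min/max of this quantity over the vertex
#' combinations of the network's credal sets.
#'
#' @param net a point-valued [credal_network()] (every interval has
#'   `l == u`).
#' @param target named character vector of length one, `c(variable = state)`.
#' @param evidence optional named character vector of observed states.
#' @return The posterior probability (scalar).  Signals a conditioning
#'   error when the evidence has probability zero.
#' @examples
#' net <- credal_network(
#'   list(A = c("a1", "a2"), B = c("b1", "b2")),
#'   parents = list(B = "A"),
#'   tables = list(
#'     A = list(credal_set(c(0.5, 0.5), c(0.5, 0.5))),
#'     B = list(credal_set(c(0.8, 0.2), c(0.8, 0.2)),
#'              credal_set(c(0.2, 0.8), c(0.2, 0.8)))))
#' bayesian_posterior(net, c(A = "a1"), c(B = "b1"))  # 0.8
#' @export
bayesian_posterior <- function(net, target, evidence = NULL) {
  if (!is_point_network(net))
    stop_credal("credalpod_structural_error",
                "bayesian_posterior requires a point-valued network; use posterior_bounds")
  q <- parse_query(net, target, evidence)
  verts <- network_vertices(net)
  cpts <- lapply(names(net$variables), function(v)
    assemble_cpt(verts[[v]], rep(1L, length(verts[[v]]))))
  names(cpts) <- names(net$variables)
  p <- bn_posterior_value(net, cpts, q$target_var, q$target_idx,
                          q$evidence_idx)
  if (is.na(p))
    stop_credal("credalpod_conditioning_error",
                "evidence has probability zero; cannot condition")
  p
}

parse_query <- function(net, target, evidence) {
  if (length(target) != 1L || is.null(names(target)))
    stop_credal("credalpod_validation_error",
                "target must be a single named element c(variable = state)")
  check_assignment(net, target, "target")
  check_assignment(net, evidence, "evidence")
  tv <- names(target)
  eidx <- if (length(evidence))
    stats::setNames(lapply(names(evidence), function(v)
      match(evidence[[v]], net$variables[[v]])), names(evidence))
  else list()
  list(target_var = tv,
       target_idx = match(target[[tv]], net$variables[[tv]]),
       evidence_idx = eidx)
}

#' Control parameters for credal inference
#'
#' @param exact_budget maximum number of vertex combinations enumerated
#'   exhaustively; beyond it the engine switches to seeded multi-restart
#'   local search and flags the result as inexact.
#' @param restarts number of local-search restarts (each from a random
#'   vertex selection).
#' @param seed integer seed driving every random choice in the search.
#' @param vertex_cap per-table state cap passed to [enumerate_vertices()].
#' @param max_passes cap on steepest-descent sweeps per restart.
#' @return A list of class `bounds_control`.
#' @export
bounds_control <- function(exact_budget = 10000, restarts = 8L, seed = 1L,
                           vertex_cap = 6L, max_passes = 50L) {
  structure(list(exact_budget = exact_budget, restarts = as.integer(restarts),
                 seed = as.integer(seed), vertex_cap = as.integer(vertex_cap),
                 max_passes = as.integer(max_passes)),
            class = "bounds_control")
}

#' Lower and upper posterior probabilities under the strong extension
#'
#' Computes bounds on `P(target | evidence, do(...))` over the strong
#' extension of a credal network: every (variable, parent configuration)
#' independently picks one distribution from its credal set, and the
#' reported interval is the min/max of the resulting Bayesian posterior.
#' Because the posterior is a ratio of forms that are multilinear in each
#' table's choice, the extrema are attained at credal-set vertices, so
#' optimisation runs over one vertex per table.  Interventions are
#' handled by graph mutilation (see [mutilate()]) before any
#' conditioning.
#'
#' When the number of vertex combinations exceeds `control$exact_budget`
#' the engine falls back to seeded multi-restart steepest-descent over
#' single-vertex swaps; the result is then flagged `exact = FALSE` and is
#' conservative-inward (an inner approximation of the true interval).
#'
#' Evidence that has zero probability under *some* vertex combinations
#' but not all is handled in the regular-extension sense: the bounds are
#' taken over combinations giving the evidence positive probability, and
#' the result is flagged `regular_extension = TRUE`.  Evidence with zero
#' upper probability is a conditioning error.
#'
#' @inheritParams bayesian_posterior
#' @param net a validated [credal_network()].
#' @param do optional named character vector of interventions
#'   `c(variable = state)`; must be disjoint from `evidence`.
#' @param control a [bounds_control()] list.
#' @param bound which bounds to compute: `"both"`, `"lower"` or
#'   `"upper"` (lower-only is cheaper and is all the impact statistic
#'   needs).
#' @return Object of class `bound_result`: fields `lower`, `upper`,
#'   `exact`, `n_extreme_combinations`, `regular_extension`.
#' @examples
#' net <- credal_network(
#'   list(A = c("a1", "a2"), B = c("b1", "b2")),
#'   parents = list(B = "A"),
#'   tables = list(
#'     A = list(credal_set(c(0.4, 0.4), c(0.6, 0.6))),
#'     B = list(credal_set(c(0.7, 0.1), c(0.9, 0.3)),
#'              credal_set(c(0.1, 0.7), c(0.3, 0.9)))))
#' posterior_bounds(net, c(B = "b1"))                    # [0.34, 0.66]
#' posterior_bounds(net, c(B = "b1"), do = c(A = "a1"))  # [0.70, 0.90]
#' @export
posterior_bounds <- function(net, target, evidence = NULL, do = NULL,
                             control = bounds_control(), bound = "both") {
  bound <- match.arg(bound, c("both", "lower", "upper"))
  if (length(do)) {
    check_assignment(net, do, "do-assignment")
    if (length(evidence) && length(intersect(names(do), names(evidence))))
      stop_credal("credalpod_validation_error",
                  "do-assignment and evidence overlap on: %s",
                  paste(intersect(names(do), names(evidence)), collapse = ", "))
    net <- mutilate(net, do)
  }
  q <- parse_query(net, target, evidence)
  ## trivial case: target determined by evidence or intervention
  fixed <- c(evidence, do)
  if (q$target_var %in% names(fixed)) {
    p <- as.numeric(fixed[[q$target_var]] == target[[1L]])
    return(new_bound_result(p, p, TRUE, 1, FALSE, target, evidence, do))
  }
  net <- prune_to_ancestors(net, unique(c(q$target_var, names(q$evidence_idx))))
  verts <- network_vertices(net, cap = control$vertex_cap)
  nv <- lapply(verts, function(tab) vapply(tab, nrow, 1L))
  combos <- prod(unlist(nv))
  evalr <- make_bounds_evaluator(net, verts, q)
  if (combos <= control$exact_budget)
    res <- bounds_exact(evalr, nv)
  else
    res <- bounds_search(evalr, nv, control, bound)
  if (is.null(res$lower) && is.null(res$upper))
    stop_credal("credalpod_conditioning_error",
                "evidence has probability zero for every vertex combination")
  new_bound_result(res$lower, res$upper, res$exact, combos,
                   res$regular_extension, target, evidence, do)
}

new_bound_result <- function(lower, upper, exact, combos, regular,
                             target, evidence, do) {
  structure(list(lower = lower, upper = upper, exact = exact,
                 n_extreme_combinations = combos,
                 regular_extension = regular,
                 target = target, evidence = evidence, do = do),
            class = "bound_result")
}

#' @export
print.bound_result <- function(x, digits = 4, ...) {
  lab <- sprintf("P(%s = %s%s%s)", names(x$target), x$target[[1L]],
                 if (length(x$evidence))
                   paste0(" | ", paste(names(x$evidence), x$evidence,
                                       sep = "=", collapse = ", ")) else "",
                 if (length(x$do))
                   paste0(if (length(x$evidence)) ", " else " | ",
                          paste0("do(", names(x$do), "=", x$do, ")",
                                 collapse = ", ")) else "")
  cat(sprintf("%s in [%.*f, %.*f]%s%s\n", lab,
              digits, x$lower %||% NA_real_, digits, x$upper %||% NA_real_,
              if (x$exact) " (exact)" else " (inner approximation)",
              if (isTRUE(x$regular_extension)) " [regular extension]" else ""))
  invisible(x)
}

## Closure evaluating the posterior for one vertex-selection vector,
## using the compiled elimination schedule.  The selection indexes the
## flattened list of (variable, parent config) coordinates with more
## than one vertex; single-vertex tables are fixed, and coordinates
## whose parent configuration contradicts an evidence- or do-fixed
## parent are dropped (their CPT column is sliced away and can never
## influence the query).
make_bounds_evaluator <- function(net, verts, q) {
  vars <- names(net$variables)
  fixed_idx <- q$evidence_idx
  coords <- list()
  for (v in vars) {
    grid <- parent_config_grid(net, v)
    relevant_cfg <- rep(TRUE, nrow(grid))
    for (pp in intersect(names(grid), names(fixed_idx)))
      relevant_cfg <- relevant_cfg &
        grid[[pp]] == net$variables[[pp]][fixed_idx[[pp]]]
    for (j in seq_along(verts[[v]]))
      if (relevant_cfg[j] && nrow(verts[[v]][[j]]) > 1L)
        coords[[length(coords) + 1L]] <- list(var = v, cfg = j)
  }
  plan <- compile_ve(net, q$target_var, q$evidence_idx)
  base_cpts <- stats::setNames(lapply(vars, function(v)
    assemble_cpt(verts[[v]], rep(1L, length(verts[[v]])))), vars)
  list(
    coords = coords,
    n_choices = vapply(coords, function(co) nrow(verts[[co$var]][[co$cfg]]),
                       1L),
    eval = function(sel) {
      cpts <- base_cpts
      for (i in seq_along(coords)) {
        co <- coords[[i]]
        cpts[[co$var]][, co$cfg] <- verts[[co$var]][[co$cfg]][sel[i], ]
      }
      vals <- run_compiled_ve(plan, cpts)
      norm <- sum(vals)
      if (norm <= 0) return(NA_real_)
      vals[q$target_idx] / norm
    })
}

bounds_exact <- function(evalr, nv) {
  radix <- evalr$n_choices
  d <- length(radix)
  sel <- rep(1L, d)
  lo <- Inf; hi <- -Inf; any_zero <- FALSE; any_valid <- FALSE
  repeat {
    p <- evalr$eval(sel)
    if (is.na(p)) any_zero <- TRUE
    else {
      any_valid <- TRUE
      if (p < lo) lo <- p
      if (p > hi) hi <- p
    }
    if (d == 0L) break
    i <- 1L
    while (i <= d) {
      sel[i] <- sel[i] + 1L
      if (sel[i] <= radix[i]) break
      sel[i] <- 1L
      i <- i + 1L
    }
    if (i > d) break
  }
  if (!any_valid) return(list(lower = NULL, upper = NULL, exact = TRUE,
                              regular_extension = FALSE))
  list(lower = lo, upper = hi, exact = TRUE,
       regular_extension = any_zero)
}

## Steepest-descent local search over single-vertex swaps, with seeded
## random restarts.  Minimises (sign = +1) or maximises (sign = -1).
search_one <- function(evalr, nv, control, sign) {
  radix <- evalr$n_choices
  d <- length(radix)
  best <- Inf; any_zero <- FALSE
  with_seed(control$seed + if (sign > 0) 0L else 10007L, {
    for (r in seq_len(control$restarts)) {
      sel <- vapply(radix, function(k) sample.int(k, 1L), 1L)
      cur <- sign * (evalr$eval(sel) %||% NA_real_)
      tries <- 0L
      while (is.na(cur) && tries < 20L) {
        any_zero <- TRUE
        sel <- vapply(radix, function(k) sample.int(k, 1L), 1L)
        cur <- sign * evalr$eval(sel)
        tries <- tries + 1L
      }
      if (is.na(cur)) next
      for (pass in seq_len(control$max_passes)) {
        improved <- FALSE
        for (i in seq_len(d)) {
          ## best single-vertex swap at this coordinate, accepted greedily
          best_v <- sel[i]; best_val <- cur
          for (vtx in seq_len(radix[i])) {
            if (vtx == sel[i]) next
            cand <- sel; cand[i] <- vtx
            val <- sign * evalr$eval(cand)
            if (is.na(val)) { any_zero <- TRUE; next }
            if (val < best_val - 1e-15) { best_val <- val; best_v <- vtx }
          }
          if (best_v != sel[i]) {
            sel[i] <- best_v; cur <- best_val; improved <- TRUE
          }
        }
        if (!improved) break
      }
      if (cur < best) best <- cur
    }
  })
  list(value = if (is.finite(best)) sign * best else NULL,
       any_zero = any_zero)
}

bounds_search <- function(evalr, nv, control, bound) {
  lo <- hi <- NULL; rz <- FALSE
  if (bound %in% c("both", "lower")) {
    s <- search_one(evalr, nv, control, +1)
    lo <- s$value; rz <- rz || s$any_zero
  }
  if (bound %in% c("both", "upper")) {
    s <- search_one(evalr, nv, control, -1)
    hi <- s$value; rz <- rz || s$any_zero
  }
  list(lower = lo, upper = hi, exact = FALSE, regular_extension = rz)
}

#' Impact of a manipulated variable on a target state
#'
#' The effect measure used throughout the place-of-death analysis: for
#' every ordered pair of states `(a, a')` of the manipulated variable,
#' the difference in the *lower* posterior probability of the target
#' state, `lower P(target | A = a) - lower P(target | A = a')` (lower
#' bounds are used because a higher prevalence is attributed to
#' variations in the lower value).  The headline impact is the maximum
#' absolute difference, reported in percentage points.
#'
#' @inheritParams posterior_bounds
#' @param variable name of the manipulated variable (must not be the
#'   target variable).
#' @param mode `"do"` (interventional: graph mutilation) or `"observe"`
#'   (plain conditioning).
#' @param evidence optional background evidence held fixed in every
#'   sub-query.
#' @return Object of class `impact_result`: `lowers` (named vector of
#'   lower bounds per state), `breakdown` (matrix of pairwise
#'   differences), `impact` (headline, percentage points, full
#'   precision) and `impact_display` (rounded to the nearest point).
#' @examples
#' net <- credal_network(
#'   list(A = c("a1", "a2"), B = c("b1", "b2")),
#'   parents = list(B = "A"),
#'   tables = list(
#'     A = list(credal_set(c(0.4, 0.4), c(0.6, 0.6))),
#'     B = list(credal_set(c(0.7, 0.1), c(0.9, 0.3)),
#'              credal_set(c(0.1, 0.7), c(0.3, 0.9)))))
#' impact(net, c(B = "b1"), "A", mode = "do")  # 60 percentage points
#' @export
impact <- function(net, target, variable, mode = c("do", "observe"),
                   evidence = NULL, control = bounds_control()) {
  mode <- match.arg(mode)
  if (!variable %in% names(net$variables))
    stop_credal("credalpod_validation_error", "unknown variable '%s'", variable)
  if (identical(variable, names(target)))
    stop_credal("credalpod_validation_error",
                "manipulated variable cannot be the target variable")
  if (variable %in% names(evidence))
    stop_credal("credalpod_validation_error",
                "manipulated variable '%s' already fixed by evidence", variable)
  states <- net$variables[[variable]]
  lowers <- vapply(states, function(s) {
    asg <- stats::setNames(s, variable)
    b <- if (mode == "do")
      posterior_bounds(net, target, evidence = evidence, do = asg,
                       control = control, bound = "lower")
    else
      posterior_bounds(net, target,
                       evidence = c(evidence, asg), control = control,
                       bound = "lower")
    b$lower
  }, 1)
  breakdown <- outer(lowers, lowers, `-`)
  dimnames(breakdown) <- list(states, states)
  headline <- max(abs(breakdown)) * 100
  structure(list(target = target, variable = variable, mode = mode,
                 evidence = evidence, lowers = lowers,
                 breakdown = breakdown, impact = headline,
                 impact_display = round(headline)),
            class = "impact_result")
}

#' @export
print.impact_result <- function(x, ...) {
  cat(sprintf("Impact of %s on P(%s = %s) [%s mode]: %d percentage points\n",
              x$variable, names(x$target), x$target[[1L]], x$mode,
              x$impact_display))
  cat("lower bounds by state:\n")
  for (s in names(x$lowers)) cat(sprintf("  %-16s %.4f\n", s, x$lowers[[s]]))
  invisible(x)
}
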