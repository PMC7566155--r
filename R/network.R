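#' Discrete credal networks
#'
#' A credal network is a directed acyclic graph over discrete variables
#' in which every (variable, parent configuration) carries a credal set
#' rather than a single conditional distribution.  A Bayesian network is
#' the degenerate case where every interval collapses to a point; all
#' inference then reduces to standard exact inference.
#'
#' Parent configurations are indexed canonically: the cross product of
#' the parents' state spaces in declared parent order, with the *first*
#' parent varying fastest (column-major, as in [expand.grid()]).
#'
#' @param variables list of [state_space()] objects, or a named list
#'   mapping variable name to its character vector of states.
#' @param parents named list mapping each variable to the character
#'   vector of its parents (omitted or `character(0)` for roots).
#' @param tables named list mapping each variable to a list of
#'   [credal_set()] objects, one per parent configuration in canonical
#'   order.  A variable with `m` parent configurations must supply
#'   exactly `m` credal sets.
#' @return Object of class `credal_network`.
#' @seealso [validate_network()], [posterior_bounds()], [read_network()]
#' @export
credal_network <- function(variables, parents = list(), tables = list()) {
  if (length(variables) == 0L)
    stop_credal("credalpod_structural_error", "a network needs at least one variable")
  if (inherits(variables[[1L]], "state_space")) {
    vars <- stats::setNames(
      lapply(variables, function(v) v$states),
      vapply(variables, function(v) v$variable_name, ""))
  } else vars <- lapply(variables, as.character)
  if (is.null(names(vars)) || any(!nzchar(names(vars))) ||
      anyDuplicated(names(vars)))
    stop_credal("credalpod_structural_error",
                "variables must have unique non-empty names")
  for (v in names(vars))
    if (length(vars[[v]]) < 2L || anyDuplicated(vars[[v]]))
      stop_credal("credalpod_structural_error",
                  "variable '%s' needs >= 2 unique states", v)
  par <- stats::setNames(vector("list", length(vars)), names(vars))
  for (v in names(vars)) par[[v]] <- character(0)
  for (v in names(parents)) {
    if (!v %in% names(vars))
      stop_credal("credalpod_structural_error", "unknown child variable '%s'", v)
    p <- as.character(parents[[v]])
    if (any(!p %in% names(vars)))
      stop_credal("credalpod_structural_error",
                  "unknown parent '%s' of '%s'", setdiff(p, names(vars))[1L], v)
    if (anyDuplicated(p) || v %in% p)
      stop_credal("credalpod_structural_error",
                  "invalid parent set for '%s'", v)
    par[[v]] <- p
  }
  net <- structure(list(variables = vars, parents = par, tables = tables),
                   class = "credal_network")
  net
}

#' @export
print.credal_network <- function(x, ...) {
  cat("Credal network:", length(x$variables), "variables,",
      sum(lengths(x$parents)), "arcs,",
      sum(vapply(x$tables, length, 1L)), "conditional credal sets\n")
  pt <- is_point_network(x)
  cat(if (pt) "Point-valued (Bayesian network special case)\n"
      else "Interval-valued tables present\n")
  invisible(x)
}

n_states <- function(net, var) length(net$variables[[var]])

## Canonical parent-configuration grid (first parent fastest).
parent_config_grid <- function(net, var) {
  p <- net$parents[[var]]
  if (length(p) == 0L)
    return(structure(data.frame(row.names = 1L), names = character(0)))
  g <- expand.grid(lapply(net$variables[p], as.character),
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  names(g) <- p
  g
}

n_parent_configs <- function(net, var) {
  p <- net$parents[[var]]
  if (length(p) == 0L) 1L else prod(vapply(net$variables[p], length, 1L))
}

## Linear index of one full parent assignment (named character vector).
parent_config_index <- function(net, var, assignment) {
  p <- net$parents[[var]]
  if (length(p) == 0L) return(1L)
  idx <- vapply(p, function(pp) {
    m <- match(assignment[[pp]], net$variables[[pp]])
    if (is.na(m))
      stop_credal("credalpod_structural_error",
                  "invalid state '%s' for parent '%s'", assignment[[pp]], pp)
    m
  }, 1L)
  ks <- vapply(net$variables[p], length, 1L)
  1L + sum((idx - 1L) * cumprod(c(1L, ks[-length(ks)])))
}

network_graph <- function(net) {
  edges <- do.call(rbind, lapply(names(net$parents), function(v) {
    p <- net$parents[[v]]
    if (length(p)) cbind(p, v) else NULL
  }))
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(net$variables),
                            name = names(net$variables))
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  g
}

is_dag_network <- function(net) igraph::is_dag(network_graph(net))

topo_order <- function(net) {
  names(igraph::topo_sort(network_graph(net), mode = "out"))
}

#' Validate a credal network
#'
#' Checks acyclicity of the parent graph, completeness of the conditional
#' tables (exactly one credal set per variable and parent configuration),
#' and coherence plus feasibility of every credal set.  Always returns a
#' report rather than signalling, so broken model files can be diagnosed
#' in full.
#'
#' @param net a [credal_network()].
#' @return List of class `network_validation` with `ok` and a data frame
#'   `issues` (columns `address`, `problem`).
#' @export
validate_network <- function(net) {
  issues <- data.frame(address = character(0), problem = character(0),
                       stringsAsFactors = FALSE)
  add <- function(address, problem)
    issues <<- rbind(issues, data.frame(address = address, problem = problem,
                                        stringsAsFactors = FALSE))
  if (!is_dag_network(net)) {
    comp <- igraph::components(network_graph(net), mode = "strong")
    cyc <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1L)]
    add("<graph>", sprintf("directed cycle involving: %s",
                           paste(sort(cyc), collapse = ", ")))
  }
  for (v in names(net$variables)) {
    m <- n_parent_configs(net, v)
    tab <- net$tables[[v]]
    if (is.null(tab)) { add(v, "missing conditional table"); next }
    if (length(tab) != m) {
      add(v, sprintf("expected %d parent-configuration credal sets, found %d",
                     m, length(tab)))
      next
    }
    grid <- parent_config_grid(net, v)
    for (j in seq_len(m)) {
      addr <- if (ncol(grid)) sprintf("%s | %s", v,
        paste(names(grid), unlist(grid[j, , drop = TRUE]), sep = "=",
              collapse = ", ")) else v
      cs <- tryCatch(as_credal_set(tab[[j]]), error = function(e) NULL)
      if (is.null(cs)) { add(addr, "not a credal set"); next }
      if (length(cs$base$lower) != n_states(net, v)) {
        add(addr, sprintf("credal set has %d states, variable has %d",
                          length(cs$base$lower), n_states(net, v)))
        next
      }
      cr <- check_coherence(cs$base)
      if (!cr$ok) {
        add(addr, paste("incoherent intervals:",
                        paste(cr$violations, collapse = "; ")))
        next
      }
      if (!credal_feasible(cs)) add(addr, "empty credal set (contradictory constraints)")
    }
  }
  structure(list(ok = nrow(issues) == 0L, issues = issues),
            class = "network_validation")
}

#' @export
print.network_validation <- function(x, ...) {
  if (x$ok) cat("network valid\n") else {
    cat("network invalid:\n")
    for (i in seq_len(nrow(x$issues)))
      cat(sprintf("  [%s] %s\n", x$issues$address[i], x$issues$problem[i]))
  }
  invisible(x)
}

#' Test whether a credal network is point-valued (a Bayesian network)
#'
#' @param net a [credal_network()].
#' @param tol tolerance on `upper - lower`.
#' @return TRUE when every interval in every table has `l == u`.
#' @export
is_point_network <- function(net, tol = 1e-12) {
  all(vapply(net$tables, function(tab)
    all(vapply(tab, function(cs) is_point_set(cs, tol), TRUE)), TRUE))
}

#' Graph mutilation for interventional queries
#'
#' Implements the do-operator on a discrete network: each intervened
#' variable loses its incoming arcs and its conditional table is replaced
#' by a point mass on the imposed state, so that downstream probabilities
#' reflect a policy action rather than an observation.
#'
#' @param net a [credal_network()].
#' @param do named character vector, `c(variable = state)`.
#' @return The mutilated [credal_network()].
#' @export
mutilate <- function(net, do) {
  if (length(do) == 0L) return(net)
  check_assignment(net, do, what = "do-assignment")
  for (v in names(do)) {
    states <- net$variables[[v]]
    point <- as.numeric(states == do[[v]])
    net$parents[[v]] <- character(0)
    net$tables[[v]] <- list(credal_set(point, point, states = states))
  }
  net
}

## Validate a (partial) assignment of states against the network.
check_assignment <- function(net, assignment, what = "assignment") {
  if (length(assignment) == 0L) return(invisible(NULL))
  nm <- names(assignment)
  if (is.null(nm) || any(!nzchar(nm)))
    stop_credal("credalpod_validation_error", "%s must be a named vector", what)
  if (anyDuplicated(nm))
    stop_credal("credalpod_validation_error",
                "%s assigns variable '%s' more than once", what,
                nm[duplicated(nm)][1L])
  for (v in nm) {
    if (!v %in% names(net$variables))
      stop_credal("credalpod_validation_error",
                  "%s refers to unknown variable '%s'", what, v)
    if (!assignment[[v]] %in% net$variables[[v]])
      stop_credal("credalpod_validation_error",
                  "%s: '%s' is not a state of '%s' (states: %s)", what,
                  assignment[[v]], v,
                  paste(net$variables[[v]], collapse = ", "))
  }
  invisible(NULL)
}

## Ancestral pruning: restrict the network to ancestors of the given
## variables (inclusive).  Barren descendants integrate out to 1 and can
## never influence the query.
prune_to_ancestors <- function(net, keep_vars) {
  g <- network_graph(net)
  anc <- unique(unlist(lapply(keep_vars, function(v)
    names(igraph::subcomponent(g, v, mode = "in")))))
  net$variables <- net$variables[names(net$variables) %in% anc]
  net$parents <- net$parents[names(net$parents) %in% anc]
  net$tables <- net$tables[names(net$tables) %in% anc]
  net
}

## Per-table vertex lists, computed lazily and memoised on the object.
network_vertices <- function(net, cap = 6L, tol = 1e-9) {
  if (!is.null(attr(net, "vertex_cache"))) return(attr(net, "vertex_cache"))
  lapply(net$tables, function(tab) lapply(tab, enumerate_vertices,
                                          cap = cap, tol = tol))
}
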