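#' Probability-interval distributions
#'
#' An `interval_distribution` stores, for each state of one discrete
#' variable, elicited lower and upper bounds on that state's probability.
#' It is the quantitative half of an expert judgment: the credal set it
#' induces is the set of all probability mass functions `p` on the simplex
#' with `lower <= p <= upper`.
#'
#' @param lower numeric vector of per-state lower probabilities.
#' @param upper numeric vector of per-state upper probabilities, same
#'   length as `lower`.
#' @param states optional character vector of state labels (canonical
#'   order; defines indexing and tie-breaking everywhere downstream).
#' @return An object of class `interval_distribution`.
#' @examples
#' d <- interval_distribution(c(0.2, 0.3), c(0.5, 0.6))
#' check_coherence(d)$ok
#' @seealso [check_coherence()], [normalize_reachable()], [credal_set()]
#' @export
interval_distribution <- function(lower, upper, states = NULL) {
  if (!is.numeric(lower) || !is.numeric(upper))
    stop_credal("credalpod_structural_error", "lower and upper must be numeric")
  if (length(lower) != length(upper))
    stop_credal("credalpod_structural_error",
                "lower (%d) and upper (%d) differ in length",
                length(lower), length(upper))
  if (length(lower) < 2L)
    stop_credal("credalpod_structural_error",
                "an interval distribution needs at least 2 states")
  if (!is.null(states)) {
    states <- as.character(states)
    if (length(states) != length(lower) || anyDuplicated(states))
      stop_credal("credalpod_structural_error",
                  "state labels must be unique and match the vector length")
    names(lower) <- names(upper) <- states
  }
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 states = states),
            class = "interval_distribution")
}

#' @export
print.interval_distribution <- function(x, digits = 4, ...) {
  k <- length(x$lower)
  lab <- x$states %||% paste0("s", seq_len(k))
  cat("Interval distribution over", k, "states\n")
  for (i in seq_len(k))
    cat(sprintf("  %-14s [%.*f, %.*f]\n", lab[i],
                digits, x$lower[i], digits, x$upper[i]))
  invisible(x)
}

as_interval_distribution <- function(x) {
  if (inherits(x, "interval_distribution")) return(x)
  if (inherits(x, "credal_set")) return(x$base)
  stop_credal("credalpod_structural_error",
              "cannot interpret object of class '%s' as interval distribution",
              class(x)[1L])
}

#' Check coherence of a probability-interval distribution
#'
#' A set of probability intervals is *coherent* when at least one
#' probability mass function satisfies all of them, i.e. when
#' `0 <= l_i <= u_i <= 1` for every state and `sum(l) <= 1 <= sum(u)`.
#' Incoherent intervals describe an empty credal set and usually indicate
#' an elicitation slip.
#'
#' @param dist an [interval_distribution()] (or [credal_set()], whose base
#'   intervals are checked).
#' @param tol numerical slack on each inequality.
#' @return A list of class `coherence_report` with elements `ok` (logical)
#'   and `violations` (character vector describing each failed inequality).
#' @examples
#' check_coherence(interval_distribution(c(0.6, 0.5), c(0.7, 0.6)))
#' @export
check_coherence <- function(dist, tol = 1e-12) {
  d <- as_interval_distribution(dist)
  l <- d$lower; u <- d$upper
  v <- character(0)
  if (any(bad <- l < -tol))
    v <- c(v, sprintf("l[%d] = %g < 0", which(bad), l[bad]))
  if (any(bad <- u > 1 + tol))
    v <- c(v, sprintf("u[%d] = %g > 1", which(bad), u[bad]))
  if (any(bad <- l > u + tol))
    v <- c(v, sprintf("l[%d] = %g > u[%d] = %g",
                      which(bad), l[bad], which(bad), u[bad]))
  if (sum(l) > 1 + tol)
    v <- c(v, sprintf("sum(l) = %g > 1 (no distribution can satisfy all lower bounds)", sum(l)))
  if (sum(u) < 1 - tol)
    v <- c(v, sprintf("sum(u) = %g < 1 (upper bounds cannot reach the simplex)", sum(u)))
  structure(list(ok = length(v) == 0L, violations = v),
            class = "coherence_report")
}

#' @export
print.coherence_report <- function(x, ...) {
  if (x$ok) cat("coherent\n") else {
    cat("incoherent:\n")
    for (v in x$violations) cat("  -", v, "\n")
  }
  invisible(x)
}

is_coherent <- function(dist, tol = 1e-12) check_coherence(dist, tol)$ok

#' Tighten probability intervals to their reachable envelope
#'
#' Elicited interval bounds are often looser than the credal set they
#' describe: a lower bound may be unattainable because the *other* states'
#' upper bounds already force more mass onto this state.  Tightening
#' replaces each bound by the actual min/max of `p_i` over the polytope,
#' `l_i' = max(l_i, 1 - sum(u[-i]))` and `u_i' = min(u_i, 1 - sum(l[-i]))`,
#' which leaves the credal set unchanged, is idempotent, and guarantees
#' every bound is attained by some member distribution.
#'
#' @inheritParams check_coherence
#' @return A tightened [interval_distribution()].
#' @examples
#' normalize_reachable(interval_distribution(c(0.3, 0.2), c(0.9, 0.6)))
#' @export
normalize_reachable <- function(dist, tol = 1e-12) {
  d <- as_interval_distribution(dist)
  rep_ <- check_coherence(d, tol)
  if (!rep_$ok)
    stop_credal("credalpod_coherence_error",
                "cannot tighten incoherent intervals: %s",
                paste(rep_$violations, collapse = "; "))
  l <- d$lower; u <- d$upper
  l2 <- pmax(l, 1 - (sum(u) - u))
  u2 <- pmin(u, 1 - (sum(l) - l))
  interval_distribution(pmin(l2, u2), u2, states = d$states)
}

#' Discrete variable state spaces
#'
#' @param variable_name variable identifier.
#' @param states ordered character vector of at least two unique state
#'   labels; the order is canonical and fixes vector indexing and
#'   tie-breaking throughout the package.
#' @return Object of class `state_space`.
#' @export
state_space <- function(variable_name, states) {
  states <- as.character(states)
  if (!is.character(variable_name) || length(variable_name) != 1L ||
      !nzchar(variable_name))
    stop_credal("credalpod_structural_error", "variable_name must be a single string")
  if (length(states) < 2L)
    stop_credal("credalpod_structural_error",
                "variable '%s' needs at least 2 states", variable_name)
  if (anyDuplicated(states))
    stop_credal("credalpod_structural_error",
                "duplicate state labels for variable '%s'", variable_name)
  structure(list(variable_name = variable_name, states = states),
            class = "state_space")
}
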