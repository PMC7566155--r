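#' Verbal probability scales
#'
#' Experts often cannot commit to a number but can say that an event is
#' "probable" or "very probable".  A verbal scale maps each such term to
#' a probability interval; the package default (shipped as an editable
#' JSON config, `verbal-scale.json`) has seven symmetric, overlapping
#' terms from "impossible" `[0, 0]` to "certain" `[1, 1]`.  The scale is
#' data, not code, so an alternative calibration can be swapped in
#' without touching the model logic.
#'
#' @param terms character vector of unique terms.
#' @param lower,upper numeric vectors of interval endpoints in `[0, 1]`.
#' @return Object of class `verbal_scale`.
#' @seealso [verbal_to_interval()], [compile_judgments()]
#' @export
verbal_scale <- function(terms, lower, upper) {
  if (anyDuplicated(terms))
    stop_credal("credalpod_structural_error", "verbal terms must be unique")
  if (length(terms) != length(lower) || length(terms) != length(upper))
    stop_credal("credalpod_structural_error", "terms/lower/upper length mismatch")
  if (any(lower < 0 | upper > 1 | lower > upper))
    stop_credal("credalpod_structural_error",
                "verbal intervals must satisfy 0 <= lower <= upper <= 1")
  structure(list(terms = as.character(terms), lower = as.numeric(lower),
                 upper = as.numeric(upper)),
            class = "verbal_scale")
}

#' @export
print.verbal_scale <- function(x, ...) {
  cat("Verbal probability scale:\n")
  for (i in seq_along(x$terms))
    cat(sprintf("  %-18s [%.2f, %.2f]\n", x$terms[i], x$lower[i], x$upper[i]))
  invisible(x)
}

#' @rdname verbal_scale
#' @param path path to a scale JSON file (array of objects with keys
#'   `term`, `lower`, `upper`).
#' @export
read_verbal_scale <- function(path) {
  if (!file.exists(path))
    stop_credal("credalpod_io_error", "verbal scale file not found: %s", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  verbal_scale(raw$term, raw$lower, raw$upper)
}

#' @rdname verbal_scale
#' @export
default_verbal_scale <- function() {
  read_verbal_scale(system.file("extdata", "verbal-scale.json",
                                package = "credalpod", mustWork = TRUE))
}

#' Translate a verbal probability term into an interval
#'
#' @param term a term present in the scale.
#' @param scale a [verbal_scale()]; defaults to the packaged scale.
#' @return Numeric vector `c(lower, upper)`, the scale's interval verbatim.
#' @examples
#' \dontrun{verbal_to_interval("very probable")}
#' @export
verbal_to_interval <- function(term, scale = default_verbal_scale()) {
  i <- match(term, scale$terms)
  if (is.na(i))
    stop_credal("credalpod_lookup_error",
                "unknown verbal term '%s'; valid terms: %s", term,
                paste(scale$terms, collapse = ", "))
  c(lower = scale$lower[i], upper = scale$upper[i])
}

#' Expert judgments about one variable's distribution
#'
#' Three kinds of judgment are supported: a numeric probability interval
#' for a state, a verbal term for a state (resolved through a
#' [verbal_scale()]), and a comparative statement "state a is at least as
#' probable as state b".
#'
#' @param state,greater,less state labels.
#' @param lower,upper interval endpoints.
#' @param term verbal term.
#' @return Object of class `judgment`.
#' @export
judgment_interval <- function(state, lower, upper) {
  if (lower < 0 || upper > 1 || lower > upper)
    stop_credal("credalpod_structural_error",
                "judgment interval must satisfy 0 <= lower <= upper <= 1")
  structure(list(kind = "interval", state = state,
                 lower = lower, upper = upper), class = "judgment")
}

#' @rdname judgment_interval
#' @export
judgment_verbal <- function(state, term)
  structure(list(kind = "verbal", state = state, term = term),
            class = "judgment")

#' @rdname judgment_interval
#' @export
judgment_comparative <- function(greater, less)
  structure(list(kind = "comparative", greater = greater, less = less),
            class = "judgment")

#' Compile expert judgments into a credal set
#'
#' Combines per-state interval and verbal judgments with comparative
#' statements into one [credal_set()].  States without any judgment get
#' the vacuous interval `[0, 1]` — imprecision rather than invented
#' precision — and the result is tightened to its reachable envelope.
#' Contradictory judgments (an empty polytope) are rejected with a
#' feasibility error.
#'
#' @param judgments list of [judgment_interval()] / [judgment_verbal()] /
#'   [judgment_comparative()] objects.
#' @param states character vector of the variable's states (canonical
#'   order), or a [state_space()].
#' @param scale [verbal_scale()] used to resolve verbal judgments.
#' @return A tightened, feasible [credal_set()].
#' @examples
#' \dontrun{
#' compile_judgments(list(judgment_verbal("h", "very probable")),
#'                   c("h", "o"))
#' }
#' @export
compile_judgments <- function(judgments, states,
                              scale = default_verbal_scale()) {
  if (inherits(states, "state_space")) states <- states$states
  k <- length(states)
  lower <- rep(0, k); upper <- rep(1, k)
  seen <- character(0)
  orderings <- list()
  for (j in judgments) {
    if (!inherits(j, "judgment"))
      stop_credal("credalpod_structural_error", "not a judgment object")
    if (j$kind == "comparative") {
      if (!all(c(j$greater, j$less) %in% states))
        stop_credal("credalpod_structural_error",
                    "comparative judgment references unknown state")
      orderings[[length(orderings) + 1L]] <- c(j$greater, j$less)
      next
    }
    if (!j$state %in% states)
      stop_credal("credalpod_structural_error",
                  "judgment references unknown state '%s'", j$state)
    if (j$state %in% seen)
      stop_credal("credalpod_structural_error",
                  "more than one interval-type judgment for state '%s'",
                  j$state)
    seen <- c(seen, j$state)
    iv <- if (j$kind == "verbal") verbal_to_interval(j$term, scale)
    else c(j$lower, j$upper)
    i <- match(j$state, states)
    lower[i] <- iv[[1L]]; upper[i] <- iv[[2L]]
  }
  spec <- credal_set(lower, upper, orderings = orderings, states = states)
  if (!is_coherent(spec$base))
    stop_credal("credalpod_feasibility_error",
                "contradictory judgments: %s",
                paste(check_coherence(spec$base)$violations, collapse = "; "))
  if (!credal_feasible(spec))
    stop_credal("credalpod_feasibility_error",
                "contradictory judgments: interval bounds and orderings (%s) describe an empty set",
                paste(vapply(orderings, function(o)
                  sprintf("p(%s)>=p(%s)", o[1L], o[2L]), ""), collapse = ", "))
  tighten_credal_set(spec)
}
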