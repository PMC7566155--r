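#' Read a credal network from its JSON description
#'
#' The network dialect (schema notes shipped in
#' `inst/extdata/network-schema.md`) has top-level keys:
#' \describe{
#'   \item{variables}{array of `{name, states[]}`; state order is
#'     canonical.}
#'   \item{arcs}{array of `{child, parents[]}`.}
#'   \item{tables}{array of `{variable, provenance, rows[]}`.  Each row
#'     holds a `parent_config` map (state per parent; may be *partial*,
#'     acting as a default for every matching configuration — the last
#'     matching row wins), and either explicit `lower[]`/`upper[]`
#'     vectors with optional `orderings` (pairs `[state_a, state_b]`
#'     meaning `p(a) >= p(b)`), or a `judgments[]` array compiled through
#'     the verbal scale.}
#' }
#' Parsing expands partial rows to every parent configuration;
#' [write_network()] writes the expanded form, so a parse/serialize round
#' trip is semantically loss-free.
#'
#' @param path path to the JSON file.
#' @param scale [verbal_scale()] used for embedded judgments.
#' @return A [credal_network()] with a `provenance` attribute (one label
#'   per variable's table).
#' @export
read_network <- function(path, scale = NULL) {
  if (!file.exists(path))
    stop_credal("credalpod_io_error", "network file not found: %s", path)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop_credal("credalpod_parse_error",
                                "cannot parse %s: %s", path,
                                conditionMessage(e)))
  parse_network_list(raw, scale = scale, source = path)
}

parse_network_list <- function(raw, scale = NULL, source = "<network>") {
  perr <- function(ptr, msg, ...)
    stop_credal("credalpod_parse_error", "%s at %s: %s", source, ptr,
                sprintf(msg, ...))
  if (is.null(raw$variables)) perr("/variables", "missing")
  vars <- list()
  for (i in seq_along(raw$variables)) {
    v <- raw$variables[[i]]
    if (is.null(v$name) || is.null(v$states))
      perr(sprintf("/variables/%d", i - 1L), "needs name and states")
    vars[[v$name]] <- as.character(unlist(v$states))
  }
  parents <- list()
  for (i in seq_along(raw$arcs)) {
    a <- raw$arcs[[i]]
    if (is.null(a$child))
      perr(sprintf("/arcs/%d", i - 1L), "needs child")
    parents[[a$child]] <- as.character(unlist(a$parents))
  }
  net <- credal_network(vars, parents, tables = list())
  if (!is_dag_network(net))
    perr("/arcs", "graph has a directed cycle")

  provenance <- list()
  for (ti in seq_along(raw$tables)) {
    t <- raw$tables[[ti]]
    ptr <- sprintf("/tables/%d", ti - 1L)
    v <- t$variable
    if (is.null(v) || !v %in% names(vars)) perr(ptr, "unknown variable")
    states <- vars[[v]]
    grid <- parent_config_grid(net, v)
    m <- nrow(grid)
    assigned <- vector("list", m)
    if (length(t$rows) == 0L) perr(ptr, "no rows")
    for (ri in seq_along(t$rows)) {
      row <- t$rows[[ri]]
      rptr <- sprintf("%s/rows/%d", ptr, ri - 1L)
      pc <- row$parent_config %||% list()
      if (any(!names(pc) %in% names(grid)))
        perr(rptr, "parent_config names a non-parent '%s'",
             setdiff(names(pc), names(grid))[1L])
      match_rows <- rep(TRUE, m)
      for (pp in names(pc)) {
        if (!pc[[pp]] %in% vars[[pp]])
          perr(rptr, "'%s' is not a state of parent '%s'", pc[[pp]], pp)
        match_rows <- match_rows & grid[[pp]] == pc[[pp]]
      }
      cs <- parse_table_row(row, states, scale, rptr, perr)
      for (j in which(match_rows)) assigned[[j]] <- cs
    }
    uncovered <- which(vapply(assigned, is.null, TRUE))
    if (length(uncovered))
      perr(ptr, "parent configuration %d not covered by any row",
           uncovered[1L])
    net$tables[[v]] <- assigned
    provenance[[v]] <- t$provenance %||% NA_character_
  }
  attr(net, "provenance") <- provenance[intersect(names(net$variables),
                                                  names(provenance))]
  attr(net, "name") <- raw$name %||% NA_character_
  attr(net, "description") <- raw$description %||% NA_character_
  net
}

parse_table_row <- function(row, states, scale, rptr, perr) {
  has_iv <- !is.null(row$lower) || !is.null(row$upper)
  has_j <- !is.null(row$judgments)
  if (has_iv && has_j)
    perr(rptr, "give either lower/upper or judgments, not both")
  if (has_j) {
    js <- lapply(row$judgments, function(j) {
      switch(j$kind %||% "",
             interval = judgment_interval(j$state, j$lower, j$upper),
             verbal = judgment_verbal(j$state, j$term),
             comparative = judgment_comparative(j$greater, j$less),
             perr(rptr, "unknown judgment kind '%s'", j$kind %||% "?"))
    })
    return(compile_judgments(js, states,
                             scale = scale %||% default_verbal_scale()))
  }
  if (is.null(row$lower) || is.null(row$upper))
    perr(rptr, "needs lower and upper")
  l <- as.numeric(unlist(row$lower)); u <- as.numeric(unlist(row$upper))
  if (length(l) != length(states) || length(u) != length(states))
    perr(rptr, "lower/upper length differs from the number of states (%d)",
         length(states))
  ords <- lapply(row$orderings %||% list(), function(o) as.character(unlist(o)))
  credal_set(l, u, orderings = ords, states = states)
}

#' Write a credal network to JSON
#'
#' Writes the fully expanded form of the dialect read by
#' [read_network()]: one row per parent configuration with explicit
#' lower/upper vectors and orderings, plus provenance labels and a
#' content hash for reproducibility.
#'
#' @param net a [credal_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  prov <- attr(net, "provenance") %||% list()
  tables <- lapply(names(net$variables), function(v) {
    grid <- parent_config_grid(net, v)
    rows <- lapply(seq_along(net$tables[[v]]), function(j) {
      cs <- as_credal_set(net$tables[[v]][[j]])
      pc <- if (ncol(grid))
        as.list(stats::setNames(unlist(lapply(grid[j, , drop = FALSE],
                                              as.character)),
                                names(grid)))
      else stats::setNames(list(), character(0))
      row <- list(parent_config = pc,
                  lower = cs$base$lower, upper = cs$base$upper)
      if (nrow(cs$orderings)) {
        states <- net$variables[[v]]
        row$orderings <- lapply(seq_len(nrow(cs$orderings)), function(i)
          c(states[cs$orderings[i, 1L]], states[cs$orderings[i, 2L]]))
      }
      row
    })
    out <- list(variable = v, rows = rows)
    if (!is.null(prov[[v]]) && !is.na(prov[[v]]))
      out$provenance <- prov[[v]]
    out
  })
  obj <- list(
    name = attr(net, "name") %||% "credal-network",
    description = attr(net, "description") %||% NULL,
    variables = lapply(names(net$variables), function(v)
      list(name = v, states = net$variables[[v]])),
    arcs = Filter(Negate(is.null), lapply(names(net$parents), function(v)
      if (length(net$parents[[v]]))
        list(child = v, parents = net$parents[[v]]) else NULL)),
    tables = tables)
  obj$content_hash <- content_hash(obj["tables"])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read and write cohort CSV files
#'
#' Cohorts are stored as plain CSV, one row per patient, with the
#' missing marker as an empty field / `NA` and provenance metadata in
#' `#`-prefixed comment lines at the top of the file.
#'
#' @param cohort a cohort data frame.
#' @param path file path.
#' @return `read_cohort` returns a `pod_cohort` data frame;
#'   `write_cohort` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  md <- attr(cohort, "metadata") %||% list()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# credalpod cohort",
               sprintf("# %s: %s", names(md),
                       vapply(md, function(x) paste(x, collapse = ","), ""))),
             con)
  utils::write.csv(as.data.frame(cohort), con, row.names = FALSE,
                   quote = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop_credal("credalpod_io_error", "cohort file not found: %s", path)
  cohort <- utils::read.csv(path, comment.char = "#",
                            stringsAsFactors = FALSE, na.strings = "NA")
  class(cohort) <- c("pod_cohort", "data.frame")
  cohort
}

#' Serialize a naive Bayes model to JSON and back
#'
#' @param model an [fit_naive_bayes()] model.
#' @param path file path.
#' @return `read_nb_model` returns the `nb_model`; `write_nb_model`
#'   returns `path` invisibly.
#' @export
write_nb_model <- function(model, path) {
  obj <- list(class_variable = model$class_variable,
              class_levels = model$class_levels,
              prior = as.list(model$prior),
              alpha = model$alpha,
              missing_values = model$missing_values,
              n = model$n,
              dropped_features = model$dropped_features,
              cond = lapply(model$cond, function(m)
                list(levels = rownames(m),
                     table = apply(m, 1L, as.numeric, simplify = FALSE))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_nb_model
#' @export
read_nb_model <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cls <- as.character(unlist(raw$class_levels))
  cond <- lapply(raw$cond, function(cc) {
    lv <- as.character(unlist(cc$levels))
    m <- do.call(rbind, lapply(cc$table, function(r) as.numeric(unlist(r))))
    dimnames(m) <- list(lv, cls)
    m
  })
  structure(list(class_variable = raw$class_variable, class_levels = cls,
                 prior = stats::setNames(as.numeric(unlist(raw$prior)), cls),
                 cond = cond,
                 feature_levels = lapply(cond, rownames),
                 alpha = raw$alpha,
                 missing_values = as.character(unlist(raw$missing_values)),
                 n = raw$n,
                 dropped_features = as.character(unlist(raw$dropped_features))),
            class = "nb_model")
}

#' Run configuration
#'
#' Bundles every tunable of the pipeline — seed, exact-enumeration
#' budget, local-search restarts, verbal-scale path, discretization
#' bins, output directory and log level — with documented defaults, and
#' round-trips through JSON so a run can be reproduced from its config
#' file alone.
#'
#' @param seed integer seed for all randomness.
#' @param exact_budget see [bounds_control()].
#' @param restarts see [bounds_control()].
#' @param vertex_cap see [enumerate_vertices()].
#' @param verbal_scale path to a verbal-scale JSON, or `NULL` for the
#'   packaged default.
#' @param discretization day-count binning rules
#'   ([default_discretization()]).
#' @param out_dir output directory.
#' @param log_level one of "debug", "info", "warn".
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, exact_budget = 10000, restarts = 8L,
                       vertex_cap = 6L, verbal_scale = NULL,
                       discretization = default_discretization(),
                       out_dir = ".", log_level = "info") {
  structure(list(seed = as.integer(seed), exact_budget = exact_budget,
                 restarts = as.integer(restarts),
                 vertex_cap = as.integer(vertex_cap),
                 verbal_scale = verbal_scale,
                 discretization = discretization,
                 out_dir = out_dir,
                 log_level = match.arg(log_level, c("debug", "info", "warn"))),
            class = "run_config")
}

#' @rdname run_config
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  disc <- lapply(raw$discretization, function(rule)
    list(new_name = rule$new_name,
         breaks = if (identical(rule$breaks, "tertiles")) "tertiles"
         else as.numeric(unlist(rule$breaks)),
         labels = as.character(unlist(rule$labels))))
  run_config(seed = raw$seed, exact_budget = raw$exact_budget,
             restarts = raw$restarts, vertex_cap = raw$vertex_cap,
             verbal_scale = raw$verbal_scale,
             discretization = disc,
             out_dir = raw$out_dir, log_level = raw$log_level)
}

bounds_control_from_config <- function(config) {
  bounds_control(exact_budget = config$exact_budget,
                 restarts = config$restarts, seed = config$seed,
                 vertex_cap = config$vertex_cap)
}
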