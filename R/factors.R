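# Discrete factor algebra and variable elimination.  Internal: the
# engine behind bayesian_posterior() and the strong-extension bounds.
# A factor is list(vars = character(), tab = numeric array) with tab's
# dimensions following vars; a scalar factor has vars = character(0).

make_factor <- function(vars, tab) list(vars = vars, tab = tab)

## Conditional probability table of `var` as a factor over (var, parents):
## dim order c(var, parents), column-major matching the canonical
## parent-configuration index.
cpt_factor <- function(net, var, cpt_matrix) {
  p <- net$parents[[var]]
  dims <- c(n_states(net, var), vapply(net$variables[p], length, 1L))
  make_factor(c(var, p), array(cpt_matrix, dim = dims))
}

## Assemble the CPT matrix (k x n_configs) of `var` from one chosen
## vertex per parent configuration.
assemble_cpt <- function(verts_var, choice) {
  k <- ncol(verts_var[[1L]])
  m <- length(verts_var)
  out <- matrix(0, k, m)
  for (j in seq_len(m)) out[, j] <- verts_var[[j]][choice[j], ]
  out
}

## Restrict a factor to var = state index, dropping the dimension.
factor_reduce <- function(f, var, idx) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  d <- dim(f$tab) %||% length(f$tab)
  args <- rep(list(quote(expr = )), length(d))
  args[[i]] <- idx
  tab <- do.call(`[`, c(list(f$tab), args, list(drop = FALSE)))
  newd <- d[-i]
  tab <- if (length(newd)) array(tab, dim = newd) else as.numeric(tab)
  make_factor(f$vars[-i], tab)
}

factor_product <- function(f, g, var_dims) {
  if (length(f$vars) == 0L) return(make_factor(g$vars, g$tab * as.numeric(f$tab)))
  if (length(g$vars) == 0L) return(make_factor(f$vars, f$tab * as.numeric(g$tab)))
  uvars <- union(f$vars, g$vars)
  udims <- var_dims[uvars]
  expand <- function(x) {
    miss <- setdiff(uvars, x$vars)
    tab <- x$tab
    if (length(miss))
      tab <- array(tab, dim = c(var_dims[x$vars], var_dims[miss]))
    ord <- match(uvars, c(x$vars, miss))
    if (!all(ord == seq_along(ord))) tab <- aperm(tab, ord)
    tab
  }
  make_factor(uvars, array(expand(f) * expand(g), dim = udims))
}

factor_marginalize <- function(f, var, var_dims) {
  i <- match(var, f$vars)
  n <- length(f$vars)
  if (n == 1L) return(make_factor(character(0), sum(f$tab)))
  perm <- c(seq_len(n)[-i], i)
  tab <- aperm(f$tab, perm)
  tab <- rowSums(array(tab, dim = c(prod(dim(tab)[-n]), dim(tab)[n])))
  make_factor(f$vars[-i], array(tab, dim = var_dims[f$vars[-i]]))
}

## Exact inference by variable elimination with a greedy min-neighbour
## ordering.  Returns the unnormalised value vector over `target` plus
## the evidence probability (its sum).
ve_query <- function(factors, var_dims, target, evidence_idx) {
  if (length(evidence_idx))
    for (v in names(evidence_idx))
      factors <- lapply(factors, factor_reduce, var = v,
                        idx = evidence_idx[[v]])
  hidden <- setdiff(unique(unlist(lapply(factors, `[[`, "vars"))),
                    target %||% character(0))
  while (length(hidden)) {
    ## greedy: eliminate the variable whose combined factor is smallest
    sizes <- vapply(hidden, function(v) {
      sc <- unique(unlist(lapply(factors,
                                 function(f) if (v %in% f$vars) f$vars)))
      prod(var_dims[sc])
    }, 1)
    v <- hidden[which.min(sizes)]
    hidden <- setdiff(hidden, v)
    inv <- vapply(factors, function(f) v %in% f$vars, TRUE)
    prod_f <- Reduce(function(a, b) factor_product(a, b, var_dims),
                     factors[inv])
    factors <- c(factors[!inv],
                 list(factor_marginalize(prod_f, v, var_dims)))
  }
  res <- Reduce(function(a, b) factor_product(a, b, var_dims), factors)
  vals <- as.numeric(res$tab)
  if (is.null(target)) return(list(values = prod(vals), norm = prod(vals)))
  list(values = vals, norm = sum(vals))
}

## Posterior P(target_var = target_idx | evidence) for a fully assembled
## Bayesian network given as a list of CPT matrices (k x n_configs).
## Returns NA when the evidence has probability zero.
bn_posterior_value <- function(net, cpts, target_var, target_idx,
                               evidence_idx) {
  var_dims <- vapply(net$variables, length, 1L)
  factors <- lapply(names(net$variables), function(v)
    cpt_factor(net, v, cpts[[v]]))
  if (target_var %in% names(evidence_idx)) {
    q <- ve_query(factors, var_dims, NULL, evidence_idx)
    if (q$norm <= 0) return(NA_real_)
    return(as.numeric(evidence_idx[[target_var]] == target_idx))
  }
  q <- ve_query(factors, var_dims, target_var, evidence_idx)
  if (q$norm <= 0) return(NA_real_)
  q$values[target_idx] / q$norm
}
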