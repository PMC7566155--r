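# Compiled variable elimination.  For repeated posterior evaluations on
# the same query (the inner loop of the strong-extension optimiser) the
# elimination schedule is compiled once into integer gather-index
# vectors; each evaluation is then pure vectorised arithmetic over small
# arrays, with no structural work.

## Column-major strides for a dimension vector.
cm_strides <- function(dims) {
  if (length(dims) == 0L) return(integer(0))
  cumprod(c(1L, dims[-length(dims)]))
}

## Gather map: linear indices into a factor with scope `sc` (dims `dims_of`)
## for every cell of an output layout with scope `out_sc` / dims `out_dims`.
gather_map <- function(out_sc, out_dims, sc, dims_of) {
  n <- prod(out_dims)
  if (n == 0L) return(integer(0))
  if (length(sc) == 0L) return(rep(1L, n))
  ostr <- cm_strides(out_dims)
  idx <- rep(0, n)
  str_in <- cm_strides(dims_of)
  cells <- 0:(n - 1)
  for (j in seq_along(sc)) {
    p <- match(sc[j], out_sc)
    coord <- (cells %/% ostr[p]) %% out_dims[p]
    idx <- idx + coord * str_in[j]
  }
  as.integer(idx + 1)
}

## Compile the query: returns a schedule plus slot bookkeeping.  Leaf
## factors are the per-variable CPTs sliced on the evidence; hidden
## variables are eliminated greedily by smallest combined scope.
compile_ve <- function(net, target_var, evidence_idx) {
  vars <- names(net$variables)
  kdim <- vapply(net$variables, length, 1L)
  ev <- names(evidence_idx)

  slots <- list()     # symbolic: list(scope, dims)
  steps <- list()
  new_slot <- function(scope, dims) {
    slots[[length(slots) + 1L]] <<- list(scope = scope, dims = dims)
    length(slots)
  }
  ## leaves: slice each CPT on observed scope variables
  live <- integer(0)
  for (v in vars) {
    scope <- c(v, net$parents[[v]])
    dims <- kdim[scope]
    red <- setdiff(scope, ev)
    rdims <- kdim[red]
    n <- prod(rdims)
    str_in <- cm_strides(dims)
    idx <- rep(0, max(n, 1L))
    cells <- 0:(max(n, 1L) - 1L)
    rstr <- cm_strides(rdims)
    for (j in seq_along(scope)) {
      sv <- scope[j]
      if (sv %in% ev) idx <- idx + (evidence_idx[[sv]] - 1L) * str_in[j]
      else {
        p <- match(sv, red)
        idx <- idx + ((cells %/% rstr[p]) %% rdims[p]) * str_in[j]
      }
    }
    s <- new_slot(red, rdims)
    steps[[length(steps) + 1L]] <- list(type = "leaf", var = v,
                                        idx = as.integer(idx + 1), out = s)
    live <- c(live, s)
  }
  scope_of <- function(s) slots[[s]]$scope
  dims_of <- function(s) slots[[s]]$dims

  compile_product <- function(a, b) {
    u <- union(scope_of(a), scope_of(b))
    ud <- kdim[u]
    s <- new_slot(u, ud)
    steps[[length(steps) + 1L]] <<- list(
      type = "prod",
      a = a, b = b,
      ia = gather_map(u, ud, scope_of(a), dims_of(a)),
      ib = gather_map(u, ud, scope_of(b), dims_of(b)),
      out = s)
    s
  }
  compile_marg <- function(a, v) {
    sc <- scope_of(a)
    keep <- setdiff(sc, v)
    neword <- c(keep, v)
    pm <- gather_map(neword, kdim[neword], sc, dims_of(a))
    s <- new_slot(keep, kdim[keep])
    steps[[length(steps) + 1L]] <<- list(
      type = "marg", a = a, pm = pm,
      nrest = as.integer(prod(kdim[keep])), k = kdim[[v]], out = s)
    s
  }

  hidden <- setdiff(setdiff(vars, ev), target_var %||% character(0))
  while (length(hidden)) {
    csize <- vapply(hidden, function(v) {
      sc <- unique(unlist(lapply(live, function(s)
        if (v %in% scope_of(s)) scope_of(s))))
      prod(kdim[sc])
    }, 1)
    v <- hidden[which.min(csize)]
    hidden <- setdiff(hidden, v)
    inv <- live[vapply(live, function(s) v %in% scope_of(s), TRUE)]
    acc <- inv[1L]
    for (s in inv[-1L]) acc <- compile_product(acc, s)
    live <- c(setdiff(live, inv), compile_marg(acc, v))
  }
  acc <- live[1L]
  for (s in live[-1L]) acc <- compile_product(acc, s)
  list(steps = steps, final = acc, n_slots = length(slots),
       final_scope = scope_of(acc))
}

## Execute a compiled schedule for one assembled CPT list (matrices
## k x n_configs, column-major over parent configurations).
run_compiled_ve <- function(plan, cpts) {
  slots <- vector("list", plan$n_slots)
  for (st in plan$steps) {
    slots[[st$out]] <- switch(
      st$type,
      leaf = cpts[[st$var]][st$idx],
      prod = slots[[st$a]][st$ia] * slots[[st$b]][st$ib],
      marg = rowSums(matrix(slots[[st$a]][st$pm], st$nrest, st$k)))
  }
  slots[[plan$final]]
}
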