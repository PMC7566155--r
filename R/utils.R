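# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

## Error signalling with typed condition classes so callers (and tests)
## can distinguish structural problems from numerical ones.
stop_credal <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "credalpod_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic content hash (FNV-1a, 32 bit) of a JSON-serialisable object.
## Used for provenance metadata; stability across platforms matters more
## than cryptographic strength.
content_hash <- function(x) {
  txt <- if (is.character(x) && length(x) == 1L) x else
    as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

## Parse "var=state" command-line style assignments into a named vector.
parse_assignments <- function(x) {
  if (length(x) == 0L) return(NULL)
  parts <- strsplit(x, "=", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad))
    stop_credal("credalpod_usage_error",
                "malformed assignment '%s' (expected var=state)", x[bad][1L])
  stats::setNames(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && abs(x - round(x)) < 1e-9
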