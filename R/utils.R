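# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never clobber the
# global stream.  seed = NULL means "use the current RNG as-is".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dims <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# coerce data.frame / Matrix input to a plain numeric matrix, keeping dimnames
as_dense_matrix <- function(x, what = "matrix") {
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop_dims("`%s` must be a numeric matrix", what)
  storage.mode(x) <- "double"
  x
}

# Atomic-ish file write: materialise under a ".partial" name, rename on success
# so an interrupted run never leaves a complete-looking output behind.
write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".partial")
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move ", tmp, " to ", path, call. = FALSE)
  invisible(path)
}
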