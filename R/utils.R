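# Internal helpers shared across modules.

stop_rdmem <- function(..., class = "rdmem_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) ||
      x < min) {
    stop_rdmem(sprintf("`%s` must be a single integer >= %d", name, min),
               class = "rdmem_invalid_parameter")
  }
  as.integer(x)
}

check_seed <- function(seed) {
  if (length(seed) != 1L || !is.numeric(seed) || is.na(seed)) {
    stop_rdmem("`seed` must be a single integer",
               class = "rdmem_invalid_parameter")
  }
  as.integer(seed)
}

# Run an expression under a local RNG state so generators are reproducible
# and do not disturb the caller's stream.
with_seed <- function(seed, expr) {
  seed <- check_seed(seed)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Row-wise L2 norms of a matrix.
row_norms <- function(m) sqrt(rowSums(m^2))

# Cosine distance matrix (1 - cosine similarity) between rows of m.
cosine_distance <- function(m) {
  nrm <- row_norms(m)
  if (any(nrm == 0)) {
    stop_rdmem("cosine distance undefined for zero-norm rows",
               class = "rdmem_zero_norm")
  }
  u <- m / nrm
  s <- tcrossprod(u)
  s[s > 1] <- 1
  s[s < -1] <- -1
  1 - s
}

offdiag <- function(m) m[row(m) != col(m)]

`%||%` <- function(a, b) if (is.null(a)) b else a
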