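# misc internal helpers

# run code with a private RNG stream; restores the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%null%` <- function(x, y) if (is.null(x)) y else x

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

one_hot <- function(x, levels) {
  m <- matrix(0, length(x), length(levels))
  idx <- match(x, levels)
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

# default molecule ids: mol001, mol002, ...
default_ids <- function(n) sprintf("mol%04d", seq_len(n))

sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable softmax
softmax <- function(w) {
  e <- exp(w - max(w))
  e / sum(e)
}

# row-indexed scatter-add: out[idx[k], ] += x[k, ], out has n rows
scatter_add <- function(x, idx, n) {
  out <- matrix(0, n, ncol(x))
  if (nrow(x) > 0L) {
    rs <- rowsum(x, group = idx)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}
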