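# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Full-precision numeric formatting: guarantees that write -> read -> write
# round-trips are the identity on doubles (17 significant digits suffice).
num_chr <- function(x) sprintf("%.17g", x)

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1L)
}

abort_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)
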