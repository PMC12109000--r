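# internal helpers shared across modules

# Combine integer components into a reproducible seed < 2^31.
derive_seed <- function(...) {
  parts <- as.numeric(c(...))
  s <- 0
  for (p in parts) s <- (s * 69069 + (p %% 2147483647)) %% 2147483647
  as.integer(s %% 2147483629 + 1)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

# largest-remainder apportionment of n into round(fractions * n) counts
apportion <- function(n, fractions) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- raw - base
  short <- n - sum(base)
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[bump] <- base[bump] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
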