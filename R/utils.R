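# Evaluate code under a temporary RNG seed, restoring global RNG state.
with_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# k child seeds deterministically derived from one master seed
child_seeds <- function(seed, k) {
  with_rng(seed, sample.int(.Machine$integer.max - 1L, k))
}

# symmetric matrix square root via eigendecomposition (PSD input)
sqrt_psd <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# integer allocation of n into parts proportional to w (largest remainder)
allocate_counts <- function(n, w) {
  if (n == 0) {
    return(setNames(rep(0L, length(w)), names(w)))
  }
  raw <- n * w / sum(w)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(w))
}
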