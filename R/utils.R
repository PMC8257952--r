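# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. All stochastic operations in the package go through this so
# that identical (inputs, seed) give bit-identical outputs.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Integer apportionment of `total` across cells proportional to `weights`
# (largest-remainder / Hamilton method). Ties on the fractional part are
# broken by cell order, so the result is deterministic.
apportion <- function(total, weights) {
  stopifnot(total >= 0, all(weights >= 0), sum(weights) > 0)
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  short <- total - sum(base)
  if (short > 0) {
    ord <- order(-(quota - base), seq_along(quota))
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

utils::globalVariables(c("region", "mean_pct", "sd_pct"))
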