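# internal helpers

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Banker's rounding to integer (round half to even), elementwise.
round_half_even <- function(x) {
  # base::round() already rounds half to even per IEC 60559
  round(x)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# quantile with linear interpolation between order statistics (type 7),
# the package-wide percentile rule
q_interp <- function(x, probs) stats::quantile(x, probs = probs, names = FALSE, type = 7)
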