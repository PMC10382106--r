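# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. Used everywhere a seed argument is accepted so that identical
# seeds give identical output regardless of surrounding code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# scalar checks used at public boundaries
stopifnot_scalar_count <- function(n, what = "n") {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 ||
      n != round(n)) {
    stop(sprintf("`%s` must be a single integer >= 1", what), call. = FALSE)
  }
}

# lognormal parameterised by its median and quartiles (as reported in
# clinical tables); sdlog recovered from the IQR of the log scale
rlnorm_iqr <- function(n, med, q1, q3, lo = -Inf, hi = Inf) {
  sdlog <- (log(q3) - log(q1)) / (2 * stats::qnorm(0.75))
  x <- stats::rlnorm(n, meanlog = log(med), sdlog = sdlog)
  pmin(pmax(x, lo), hi)
}
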