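#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

`%|e|%` <- function(x, y) if (nzchar(x)) x else y

#' Derive a stage-specific random seed from one global seed
#'
#' Every stochastic stage of the pipeline draws from its own stream derived
#' from `(seed, stage)`, so that adding replicates to one stage never
#' perturbs another. The derivation is a small string hash folded into the
#' 32-bit integer range.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

## Evaluate `code` under a seed derived from (seed, stage), restoring the
## caller's RNG state afterwards.
with_stage_seed <- function(seed, stage, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(stage_seed(seed, stage))
  force(code)
}

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

assert_prob <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) stop2("`%s` must be a number in %s%g, %g%s, got %s", name,
                 if (lo_open) "(" else "[", lo, hi,
                 if (hi_open) ")" else "]", format(x))
  invisible(x)
}

## Count-weighted mean/SD/n from (value, count) pairs; SD uses n - 1.
weighted_moments <- function(values, counts) {
  n <- sum(counts)
  m <- sum(values * counts) / n
  ss <- sum(counts * (values - m)^2)
  s <- if (n > 1) sqrt(ss / (n - 1)) else 0
  list(mean = m, sd = s, n = n)
}
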