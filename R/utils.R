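#' @keywords internal
#' @importFrom stats coef predict median setNames var cov qnorm pnorm pt
#'   pchisq phyper p.adjust rnorm runif rbinom rpois rnbinom rexp rgamma
#'   model.matrix lm.wfit lowess approx as.formula glm binomial plogis
#'   quantile sd
#' @importFrom utils read.delim read.csv write.csv write.table head
#'   packageVersion
"_PACKAGE"

## Counter-based seed substreams: every stochastic operation derives its own
## 32-bit seed from (master seed, stream key) so stages can be re-run
## independently and in any order without perturbing each other's draws.

#' Derive a reproducible substream seed
#'
#' Hashes a master seed together with an integer stream key into a new seed
#' in `[0, 2^31 - 1)`. Used by every stochastic operation in the package so
#' that a single master seed governs all randomness while each stage draws
#' from its own independent-looking stream.
#'
#' @param seed Integer master seed.
#' @param key Integer stream key (>= 0); distinct keys give distinct streams.
#' @return A single integer seed.
#' @export
substream_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(key))
  ## splitmix-style integer mixing in double arithmetic (exact below 2^53)
  m <- 2147483647  # 2^31 - 1
  x <- (abs(seed) %% m)
  for (k in c(key, 0x9E37)) {
    x <- (x * 48271 + (abs(k) %% m) * 16807 + 12345) %% m
  }
  as.integer(x)
}

with_substream <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, key))
  force(expr)
}

geometric_mean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tg <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_tg("`%s` must lie in [0, 1]", name)
  invisible(x)
}
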