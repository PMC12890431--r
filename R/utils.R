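#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. All user-facing stochastic functions route through this, which is
# what makes equal seeds give byte-identical outputs.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed derivation: keeps derived seeds in 32-bit range and
# decorrelates stages that share a master seed.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + as.double(offset) * 9973) %% 2147483629)
}

logit <- function(p) log(p / (1 - p))
invlogit <- function(x) stats::plogis(x)

sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)
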