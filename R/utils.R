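#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif fft var
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never clobbers the
# user's stream.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic child seed: a distinct 31-bit stream per (master, index).
# Lehmer-style mixing keeps the result a valid positive R integer.
deriveSeed <- function(master, index) {
  m <- 2147483647
  s <- (as.numeric(master) %% m) + 1
  for (k in seq_len(2)) s <- (s * 48271 + as.numeric(index) * 69621) %% m
  as.integer(s %% (m - 1) + 1)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

assertFinite <- function(x, what) {
  if (!all(is.finite(x)))
    stop("invalid argument: ", what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

assertCount <- function(x, what, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != as.integer(x) || x < min)
    stop("invalid argument: ", what, " must be a single integer >= ", min,
         call. = FALSE)
  invisible(as.integer(x))
}
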