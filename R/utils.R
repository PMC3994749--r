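#' @importFrom rlang abort warn inform %||%
#' @importFrom stats predict rnorm runif rbinom sd setNames
#' @importFrom utils head modifyList
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from (seed, index); kept well below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647L)
}

# Full-precision text encoding for doubles ("%.17g" round-trips IEEE-754).
num_to_chr <- function(x) sprintf("%.17g", x)
chr_to_num <- function(x) as.numeric(x)

is_binary01 <- function(x) all(x %in% c(0, 1))
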