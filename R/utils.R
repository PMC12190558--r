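#' @importFrom methods new as is
#' @importFrom stats rnorm runif optim setNames integrate sd var dnorm pnorm
#' @importFrom utils head read.csv write.csv
#' @importFrom ChemmineR smiles2sdf sdf2smiles atomblock bondblock
#' @importFrom ChemmineOB convertFormat forEachMol prop_OB fingerprint_OB
NULL

# Typed condition helper: every package error carries a subclass so callers
# (e.g. validity counting in generation_metrics) can catch selectively.
gg_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "gluegen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

gg_assert <- function(ok, msg, class = "gluegen_invalid_input") {
  if (!isTRUE(ok)) gg_stop(msg, class)
}

# Seeded evaluation that never leaks into (or depends on) the caller's RNG
# state. All stochastic operations in the package funnel through this.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Xavier-normal matrix (fan-based sd), the package-wide weight initializer.
xavier <- function(nrow, ncol) {
  sd <- sqrt(2 / (nrow + ncol))
  matrix(rnorm(nrow * ncol, sd = sd), nrow = nrow, ncol = ncol)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
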