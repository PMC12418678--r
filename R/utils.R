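## Internal constants and small helpers shared across modules.

## CODATA-14 Bohr radius in Angstrom.
BOHR_A <- 0.52917721067

## Hartree (a.u. of potential per unit charge) in kcal mol^-1 e^-1,
## used only at the reporting layer.
HARTREE_KCAL <- 627.509474

#' @importFrom stats integrate rnorm runif sd fft setNames cor
#' @importFrom utils head tail read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hc <- function(fmt, ..., class = "hcfit_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error")))
}

## Deterministic scoped RNG: every stochastic draw in the package goes
## through this so cases are bit-reproducible from a single integer seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

vnorm <- function(v) sqrt(sum(v^2))

unit3 <- function(v) {
  n <- vnorm(v)
  if (n < 1e-14) stop_hc("cannot normalize a zero vector")
  v / n
}

## factorial for small non-negative integers, exact
fact <- function(n) factorial(n)

## double factorial (2l+1)!!
dfact_odd <- function(l) prod(seq(1, 2 * l + 1, by = 2))
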