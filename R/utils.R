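#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
## caller's stream afterwards. All stochastic generators route through this so
## that identical specs give identical output regardless of ambient RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic sub-seed derivation from one master seed, kept < 2^31.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + 11 * stream) %% 2147483587
}

stat_mode <- function(x) {
  ux <- unique(x)
  ux[which.max(tabulate(match(x, ux)))]
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}
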