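# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Stop with a classed condition so callers/tests can match on the error type.
abort <- function(msg, class) {
  stop(structure(class = c(class, "ppgfusion_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         class = "invalid_parameter") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    abort(sprintf("`%s` must be a finite number in [%g, %g]", name, lower, upper),
          class)
  invisible(x)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
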