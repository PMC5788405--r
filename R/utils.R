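#' @keywords internal
"_PACKAGE"

# Run expr with a private RNG stream; global .Random.seed is untouched.
with_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Wrap angles to (-pi, pi].
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

db_to_pow <- function(db) 10^(db / 10)
pow_to_db <- function(p) 10 * log10(p)

`%||%` <- function(a, b) if (is.null(a)) b else a

ad_log <- function(..., verbose = getOption("alarmdet.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[alarmdet] ", ...)
  invisible(NULL)
}
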