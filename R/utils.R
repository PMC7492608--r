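# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pmbr <- function(...) stop(..., call. = FALSE)

assert_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_pmbr(sprintf("`%s` must be a finite numeric scalar", name))
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  assert_finite_scalar(x, name)
  if (x < min || x != round(x))
    stop_pmbr(sprintf("`%s` must be an integer >= %d", name, min))
  invisible(as.integer(x))
}

# run `expr` under a private RNG stream without disturbing the caller's state
with_private_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a child seed below 2^31 from a parent seed and a stream index
child_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483563
}

wrap_angle <- function(deg) {
  # wrap to (-180, 180]
  out <- ((deg + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}
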