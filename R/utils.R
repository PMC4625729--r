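# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_named("'%s' must be a single number", name)
  if (x < lower || x > upper)
    stop_named("'%s' = %g is outside [%g, %g]", name, x, lower, upper)
  invisible(x)
}

# Integer voxel offsets of a ball of radius r (includes the centre).
ball_offsets <- function(r) {
  s <- seq(-floor(r), floor(r))
  g <- expand.grid(dx = s, dy = s, dz = s)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}
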