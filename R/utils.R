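# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators are referentially transparent.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_petseg <- function(msg, class) {
  stop(structure(class = c(class, "petseg_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_len3 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 3 || any(!is.finite(x)))
    stop(sprintf("`%s` must be a finite numeric triple", name))
  as.numeric(x)
}

# World coordinates (mm) of voxel nodes along one axis, centered on the grid.
axis_mm <- function(n, spacing) (seq_len(n) - 1 - (n - 1) / 2) * spacing

# Full coordinate arrays (mm, grid-centered) for a grid of dims `d`.
grid_mm <- function(d, spacing) {
  gx <- axis_mm(d[1], spacing[1])
  gy <- axis_mm(d[2], spacing[2])
  gz <- axis_mm(d[3], spacing[3])
  list(
    x = array(gx, dim = d),
    y = array(rep(gy, each = d[1]), dim = d),
    z = array(rep(gz, each = d[1] * d[2]), dim = d)
  )
}
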