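# Internal geometry and misc helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom rlang abort
vec3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p))) {
    rlang::abort(sprintf("%s must be a finite numeric 3-vector", what))
  }
  p
}

unit <- function(v, what = "vector", tol = 1e-9) {
  n <- sqrt(sum(v^2))
  if (n < tol) {
    rlang::abort(sprintf("degenerate geometry: %s has near-zero length", what))
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Deterministic 31-bit seed derived from a master seed and an index, used to
# give each pipeline operation its own master seed.
sub_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 16807
  as.integer(s %% 2147483629) + 1L
}

# Per-subject random-number sub-streams. L'Ecuyer-CMRG streams are provably
# independent, so draws for one subject cannot leak correlation into
# another's; each operation derives all its streams from one master seed and
# restores the caller's RNG state afterwards.
save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
}

restore_rng <- function(state) {
  if (is.null(state)) {
    # no user RNG state existed: reset the generator kind to the session
    # default so our L'Ecuyer-CMRG switch cannot leak into later set.seed()
    RNGkind("default", "default", "default")
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

make_streams <- function(seed, n) {
  set.seed(as.integer(seed %% 2147483647), kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", globalenv(), inherits = FALSE)
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    streams[[i]] <- s
  }
  streams
}

use_stream <- function(stream) {
  assign(".Random.seed", stream, envir = globalenv())
}

# Coordinates as an n x 3 matrix from a landmark tibble.
coord_matrix <- function(points) {
  as.matrix(points[, c("x_mm", "y_mm", "z_mm")])
}

set_coords <- function(points, m) {
  points$x_mm <- m[, 1]
  points$y_mm <- m[, 2]
  points$z_mm <- m[, 3]
  points
}
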