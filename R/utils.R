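# Internal geometry and RNG helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seeds below 2^31, spread by a fixed multiplier so
# consecutive parents do not produce overlapping streams.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list((as.numeric(seed) * 48271 + 1e4 * seq_len(n)) %% 2147483629 + 1)
}

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Shoelace area of a polygon given as a 2-column matrix of vertices in order.
polygon_area <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Points-in-convex-polygon test; boundary counts as inside. `poly` must be a
# convex polygon in (counter)clockwise vertex order; px, py are vectors.
in_convex_hull <- function(px, py, poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(rep(FALSE, length(px)))
  pos <- neg <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) -
          (poly[j, 2] - poly[i, 2]) * (px - poly[i, 1])
    pos <- pos | cr > 1e-9
    neg <- neg | cr < -1e-9
  }
  !(pos & neg)
}

# Angular span (degrees) of a set of direction angles on the circle: the arc
# length of the shortest arc containing all points (360 minus the largest gap).
angular_span <- function(theta_deg) {
  th <- sort(theta_deg %% 360)
  if (length(th) < 2) return(0)
  gaps <- diff(c(th, th[1] + 360))
  360 - max(gaps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
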