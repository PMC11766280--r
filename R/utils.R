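# Internal geometry and error helpers shared across modules.

abort_input <- function(msg) rlang::abort(msg, class = "annulaR_input_error")
abort_degenerate <- function(msg) rlang::abort(msg, class = "annulaR_degenerate_error")

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort_degenerate("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Accept a tibble/data.frame with x,y,z columns or a 3-column matrix; return
# an n x 3 numeric matrix.
as_xyz_matrix <- function(points) {
  if (is.matrix(points)) {
    if (ncol(points) != 3L) abort_input("point matrix must have 3 columns")
    m <- points
  } else if (is.data.frame(points)) {
    if (!all(c("x", "y", "z") %in% names(points))) {
      abort_input("points must have columns x, y, z")
    }
    m <- cbind(points$x, points$y, points$z)
  } else {
    abort_input("points must be a data frame or a 3-column matrix")
  }
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) abort_input("points contain non-finite coordinates")
  colnames(m) <- c("x", "y", "z")
  m
}

as_uv_matrix <- function(points) {
  if (is.matrix(points)) {
    if (ncol(points) != 2L) abort_input("2D point matrix must have 2 columns")
    m <- points
  } else if (is.data.frame(points)) {
    if (!all(c("u", "v") %in% names(points))) {
      abort_input("2D points must have columns u, v")
    }
    m <- cbind(points$u, points$v)
  } else {
    abort_input("2D points must be a data frame or a 2-column matrix")
  }
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) abort_input("2D points contain non-finite coordinates")
  colnames(m) <- c("u", "v")
  m
}

xyz_tibble <- function(m) {
  tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3])
}

uv_tibble <- function(m) {
  tibble::tibble(u = m[, 1], v = m[, 2])
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
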