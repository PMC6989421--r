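# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_finite_matrix <- function(m, what = "coordinates") {
  if (!all(is.finite(m))) {
    bad <- which(!apply(is.finite(m), 1L, all))
    stopf("non-finite %s at row(s): %s", what,
          paste(utils::head(bad, 5L), collapse = ", "))
  }
  invisible(m)
}

as_points_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L, byrow = TRUE)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stopf("points must be an n x 3 matrix")
  points
}

# Row-wise Euclidean norms
row_norms <- function(m) sqrt(rowSums(m^2))

# Deterministic child seed from a base seed and a label; kept below 2^31.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
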