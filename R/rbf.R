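#' Fit a weighted least-squares RBF displacement field
#'
#' The core deformation model: a vector-valued radial basis function warp
#' \eqn{s(x) = c_0 + C x + \sum_i \lambda_i \phi(|x - x_i|)} fitted to
#' displacement samples at scattered centres. Fidelity at each centre is
#' traded against smoothness through the per-centre variance: for each
#' displacement component the symmetric system
#' \deqn{\begin{bmatrix} A + \alpha\,diag(\sigma^2) & P \\ P^T & 0
#'       \end{bmatrix} \begin{bmatrix} \lambda \\ c \end{bmatrix} =
#'       \begin{bmatrix} f \\ 0 \end{bmatrix}}
#' is solved, where \eqn{A_{ij} = \phi(|x_i - x_j|)}, \eqn{P = [1\; x\; y\; z]}
#' at the centres, \eqn{\sigma^2} the per-centre variances and \eqn{\alpha}
#' the global smoothing constant. Centres with zero variance are matched
#' exactly for any \eqn{\alpha}; high-variance centres relax towards the
#' smooth (affine + minimal-energy) field. The affine part is unpenalised, so
#' any affine displacement field is reproduced exactly.
#'
#' @param centres n x 3 matrix of centre positions (mm), n >= 4, not
#'   coplanar; duplicate centres (closer than 1e-6 mm) are rejected.
#' @param targets n x 3 matrix of displacement vectors at the centres (mm).
#' @param variances per-centre variances (mm^2), scalar or length-n vector.
#' @param basis `"biharmonic"` (\eqn{\phi(r) = r}, default — the minimal
#'   bending-energy interpolant in 3D) or `"triharmonic"`
#'   (\eqn{\phi(r) = r^3}).
#' @param alpha global smoothing constant (>= 0), default 1; the product
#'   `alpha * variance` is the diagonal augmentation.
#' @return An object of class `rbf_warp` with elements `centres`,
#'   `coefficients` (n x 3), `affine` (4 x 3: intercept row then the linear
#'   part), `basis`, `alpha`, `variances`.
#' @seealso [predict.rbf_warp()], [warp_mesh()], [compose_fields()]
#' @export
rbf_warp <- function(centres, targets, variances = 0,
                     basis = c("biharmonic", "triharmonic"), alpha = 1) {
  basis <- match.arg(basis)
  centres <- as_points_matrix(centres)
  targets <- as_points_matrix(targets)
  assert_finite_matrix(centres, "centres")
  assert_finite_matrix(targets, "targets")
  n <- nrow(centres)
  if (nrow(targets) != n) stopf("centres and targets differ in length")
  if (n < 4L) stopf("need at least 4 non-coplanar centres, got %d", n)
  variances <- rep_len(as.numeric(variances), n)
  if (any(!is.finite(variances)) || any(variances < 0))
    stopf("variances must be finite and non-negative")
  if (!is.finite(alpha) || alpha < 0) stopf("alpha must be >= 0")

  D <- .cross_dist_cpp(centres, centres)
  mind <- min(D[upper.tri(D)])
  if (mind < 1e-6)
    stopf("duplicate centres: minimum pairwise distance %.3g mm < 1e-6", mind)
  P <- cbind(1, centres)
  if (qr(P)$rank < 4L)
    stopf("degenerate centre configuration: centres are coplanar")

  A <- .rbf_kernel(D, basis)
  # smoothing: shift the diagonal in the kernel's definite direction. Both
  # r and r^3 are conditionally negative definite w.r.t. the linear
  # constraints, so the variational smoothing system subtracts alpha*sigma^2
  # (equivalently: add it to the conditionally positive definite -phi).
  diag(A) <- diag(A) - alpha * variances
  M <- rbind(cbind(A, P), cbind(t(P), matrix(0, 4L, 4L)))
  rc <- rcond(M)
  if (!is.finite(rc) || rc < 1e-15)
    stopf("singular RBF system (reciprocal condition number %.3g)", rc)
  sol <- solve(M, rbind(targets, matrix(0, 4L, 3L)))
  structure(list(centres = centres, coefficients = sol[seq_len(n), , drop = FALSE],
                 affine = sol[n + 1:4, , drop = FALSE], basis = basis,
                 alpha = alpha, variances = variances, targets = targets),
            class = "rbf_warp")
}

.rbf_kernel <- function(r, basis) {
  switch(basis, biharmonic = r, triharmonic = r^3,
         stopf("unknown basis '%s'", basis))
}

#' Evaluate an RBF warp at points
#'
#' @param object an `rbf_warp`
#' @param points m x 3 matrix (mm)
#' @param type `"position"` returns the displaced points
#'   `x + s(x)`; `"displacement"` returns `s(x)` itself.
#' @param ... unused
#' @return m x 3 matrix
#' @export
predict.rbf_warp <- function(object, points,
                             type = c("position", "displacement"), ...) {
  type <- match.arg(type)
  pts <- as_points_matrix(points)
  assert_finite_matrix(pts, "evaluation points")
  disp <- .rbf_kernel(.cross_dist_cpp(pts, object$centres), object$basis) %*%
    object$coefficients + cbind(1, pts) %*% object$affine
  if (type == "position") pts + disp else disp
}

#' @export
residuals.rbf_warp <- function(object, ...) {
  object$targets - predict(object, object$centres, type = "displacement")
}

#' @export
coef.rbf_warp <- function(object, ...) {
  list(coefficients = object$coefficients, affine = object$affine)
}

#' @export
print.rbf_warp <- function(x, ...) {
  res <- row_norms(residuals(x))
  cat(sprintf("<rbf_warp> %s basis, %d centres, alpha = %g\n",
              x$basis, nrow(x$centres), x$alpha))
  cat(sprintf("  max |target| %.3f mm; centre residuals: max %.3g mm, RMS %.3g mm\n",
              max(row_norms(x$targets)), max(res), sqrt(mean(res^2))))
  invisible(x)
}

#' @export
summary.rbf_warp <- function(object, ...) {
  res <- row_norms(residuals(object))
  out <- list(basis = object$basis, n_centres = nrow(object$centres),
              alpha = object$alpha,
              variance_range = range(object$variances),
              residual_max = max(res), residual_rms = sqrt(mean(res^2)),
              weighted_residual = sum(res^2 / pmax(object$variances, 1e-12)))
  class(out) <- "summary.rbf_warp"
  out
}

#' @export
print.summary.rbf_warp <- function(x, ...) {
  cat(sprintf(paste0("RBF warp: %s basis, %d centres, alpha = %g\n",
                     "variances in [%.3g, %.3g] mm^2\n",
                     "centre residuals: max %.3g mm, RMS %.3g mm\n"),
              x$basis, x$n_centres, x$alpha, x$variance_range[1L],
              x$variance_range[2L], x$residual_max, x$residual_rms))
  invisible(x)
}

#' Apply a warp to a surface mesh
#'
#' Vertex-wise evaluation of the displacement field; faces are unchanged.
#' @param warp an `rbf_warp` (or any object with a `predict` method mapping
#'   points to points, e.g. a composed field).
#' @param mesh a `surface_mesh`
#' @param stage stage label of the output mesh (default `"predicted"`).
#' @return a `surface_mesh`
#' @export
warp_mesh <- function(warp, mesh, stage = "predicted") {
  mesh$vertices <- if (inherits(warp, "composed_field"))
    warp(mesh$vertices) else predict(warp, mesh$vertices, type = "position")
  mesh$stage <- stage
  mesh
}

#' Compose displacement fields sequentially
#'
#' Returns a callable evaluator applying the warps in order (the output of
#' warp k feeds warp k + 1). Composition is pointwise sequential evaluation,
#' not summation of displacement fields.
#'
#' @param warps non-empty list of `rbf_warp` objects (or functions mapping an
#'   m x 3 matrix of points to displaced points).
#' @return a function of class `composed_field`: `f(points)` -> displaced
#'   points.
#' @export
compose_fields <- function(warps) {
  if (!is.list(warps) || length(warps) == 0L)
    stopf("compose_fields needs a non-empty list of warps")
  f <- function(points) {
    pts <- as_points_matrix(points)
    for (w in warps) {
      pts <- if (is.function(w)) w(pts) else predict(w, pts, type = "position")
    }
    pts
  }
  structure(f, class = c("composed_field", "function"))
}

#' Serialize / deserialize an RBF warp to JSON
#'
#' Round-trips all finite doubles exactly (full-precision JSON numbers).
#' @param warp an `rbf_warp`
#' @param path output / input file path
#' @return `write_warp_json`: `path` invisibly; `read_warp_json`: an
#'   `rbf_warp`.
#' @export
write_warp_json <- function(warp, path) {
  obj <- list(basis_id = warp$basis, alpha = warp$alpha,
              centres = warp$centres, variances = warp$variances,
              coefficients = warp$coefficients,
              affine = t(warp$affine),   # 3 x 4, one row per component
              targets = warp$targets)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_warp_json
#' @export
read_warp_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(centres = as_points_matrix(obj$centres),
                 coefficients = as_points_matrix(obj$coefficients),
                 affine = t(matrix(as.numeric(obj$affine), 3L, 4L)),
                 basis = obj$basis_id, alpha = obj$alpha,
                 variances = as.numeric(obj$variances),
                 targets = as_points_matrix(obj$targets)),
            class = "rbf_warp")
}
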