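#' Construct a rigid transform
#'
#' A proper rigid motion `x -> R x + t` with `R` a rotation (orthonormal,
#' determinant +1) and `t` a translation in mm.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation 3-vector, mm.
#' @param tol tolerance for the orthonormality/determinant checks.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-9) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stopf("rotation must be 3x3 and translation length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > tol)
    stopf("rotation is not orthonormal (max deviation %.3g)",
          max(abs(crossprod(rotation) - diag(3))))
  if (abs(det(rotation) - 1) > tol)
    stopf("rotation determinant is %.12g, not +1 (reflection?)", det(rotation))
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\nrotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 6), collapse = " "), "\n")
  invisible(x)
}

#' Apply a rigid transform to points
#' @param transform a `rigid_transform`
#' @param points n x 3 matrix (or 3-vector), mm
#' @return transformed n x 3 matrix
#' @export
apply_rigid <- function(transform, points) {
  pts <- as_points_matrix(points)
  assert_finite_matrix(pts, "points")
  sweep(pts %*% t(transform$rotation), 2L, transform$translation, `+`)
}

#' Compose rigid transforms (left-to-right application order)
#' @param a,b `rigid_transform`s; the result applies `a` first, then `b`.
#' @return a `rigid_transform`
#' @export
compose_rigid <- function(a, b) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation,
                  tol = 1e-6)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`
#' @return a `rigid_transform`
#' @export
invert_rigid <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation), tol = 1e-6)
}

# rotation by angle (radians) about a unit axis (Rodrigues)
rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3L, 3L, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# random rotation uniform over SO(3) via QR of a Gaussian matrix
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

random_rigid_transform <- function(translation_scale = 50) {
  rigid_transform(random_rotation(),
                  stats::rnorm(3L, sd = translation_scale), tol = 1e-6)
}

# Apply a rigid transform to every surface and landmark set of a dataset stage
transform_stage <- function(ds, transform, stage = c("pre", "post")) {
  stage <- match.arg(stage)
  for (fld in paste0(c("skin_", "bone_"), stage)) {
    if (!is.null(ds[[fld]]))
      ds[[fld]]$vertices <- apply_rigid(transform, ds[[fld]]$vertices)
  }
  lfld <- paste0("landmarks_", stage)
  ds[[lfld]] <- set_landmark_coords(
    ds[[lfld]], apply_rigid(transform, landmark_coords(ds[[lfld]])))
  ds
}
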