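#' Best-fit plane through 3D points
#'
#' Total least squares: the plane passes through the centroid and its normal
#' is the smallest-eigenvalue direction of the point covariance, minimising
#' the total squared orthogonal distance. The normal sign is canonicalised
#' (positive component on +z, then +y, then +x) for determinism; callers that
#' need an anatomical orientation apply their own rule.
#'
#' @param points n x 3 matrix, n >= 3, not collinear.
#' @return list with `centroid` (mm), `unit_normal`, `rms_residual` (mm),
#'   of class `frame_plane`.
#' @export
best_fit_plane <- function(points) {
  pts <- as_points_matrix(points)
  assert_finite_matrix(pts, "plane points")
  if (nrow(pts) < 3L) stopf("best-fit plane needs at least 3 points")
  centroid <- colMeans(pts)
  centred <- sweep(pts, 2L, centroid)
  ev <- eigen(crossprod(centred), symmetric = TRUE)
  # collinear (or coincident) points: two vanishing eigenvalues
  scale2 <- max(ev$values[1L], .Machine$double.eps)
  if (ev$values[2L] / scale2 < 1e-12)
    stopf("degenerate plane fit: points are collinear or coincident")
  normal <- ev$vectors[, 3L]
  for (k in c(3L, 2L, 1L)) {
    if (abs(normal[k]) > 1e-12) {
      if (normal[k] < 0) normal <- -normal
      break
    }
  }
  structure(list(centroid = centroid, unit_normal = normal,
                 rms_residual = sqrt(ev$values[3L] / nrow(pts))),
            class = "frame_plane")
}

project_onto_plane <- function(points, plane) {
  pts <- as_points_matrix(points)
  d <- as.numeric(sweep(pts, 2L, plane$centroid) %*% plane$unit_normal)
  pts - outer(d, plane$unit_normal)
}

# minimal rotation taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-14) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to a
    axis <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- axis - sum(axis * a) * a
    return(rotation_about_axis(axis, pi))
  }
  rotation_about_axis(v / s, atan2(s, cth))
}

#' Standardised skull-base reference-frame transform
#'
#' Builds the rigid transform that carries the 7 reference landmarks (right
#' and left lateral semicircular canal lateral and posterior points, right
#' and left glenoid fossae, crista galli — in that order) into the
#' standardised frame:
#' a best-fit plane through landmarks 1–6 is fitted and the six landmarks are
#' projected onto it; the line through the projected landmarks 1 and 2 is
#' taken onto the x-axis with its midpoint at the origin; the plane is
#' rotated about the x-axis to coincide with the x–y plane; and a final
#' rotation about the z-axis brings the crista galli onto the anterior (+y)
#' half of the y–z plane.
#'
#' After applying the returned transform: the midpoint of the projected
#' landmarks 1 and 2 is at the origin; the best-fit plane of landmarks 1–6 is
#' the x–y plane; the crista galli has x = 0 and y > 0; +z is superior
#' (chosen so `orientation_hint` — by default the crista galli — lands at
#' z >= 0, unless `flip_z` overrides); +x points towards landmark 1 (the
#' patient's right side). The x-axis alignment of the landmark 1–2 line is
#' only approximate after the final z-rotation and is not guaranteed.
#'
#' @param ref 7 x 3 matrix of reference landmark positions (mm), canonical
#'   order, or a `landmark_set` containing the 7 named reference landmarks.
#' @param orientation_hint optional point(s) (n x 3) whose mean should end up
#'   with z >= 0 (e.g. the centroid of the remaining bone landmarks).
#' @param flip_z force the opposite superior direction.
#' @return a `rigid_transform`
#' @export
compute_reference_transform <- function(ref, orientation_hint = NULL,
                                        flip_z = FALSE) {
  if (inherits(ref, "landmark_set")) ref <- reference_landmarks(ref)
  ref <- as_points_matrix(ref)
  if (nrow(ref) != 7L) stopf("need exactly 7 reference landmarks, got %d",
                             nrow(ref))
  assert_finite_matrix(ref, "reference landmarks")
  if (sqrt(sum((ref[1L, ] - ref[2L, ])^2)) < 1e-9)
    stopf("reference landmarks 1 and 2 coincide")
  plane <- best_fit_plane(ref[1:6, ])
  proj <- project_onto_plane(ref[1:6, ], plane)
  d <- proj[1L, ] - proj[2L, ]
  if (sqrt(sum(d^2)) < 1e-9)
    stopf("projected reference landmarks 1 and 2 coincide")
  d <- d / sqrt(sum(d^2))
  R1 <- rotation_between(d, c(1, 0, 0))
  m <- (proj[1L, ] + proj[2L, ]) / 2
  n1 <- as.numeric(R1 %*% plane$unit_normal)
  # rotate about x to map the plane normal onto +/- z; pick the sign that
  # puts the orientation hint superior
  ang_up <- atan2(n1[2L], n1[3L])  # about x: takes n1 onto +z
  candidates <- list(rotation_about_axis(c(1, 0, 0), ang_up),
                     rotation_about_axis(c(1, 0, 0), ang_up + pi))
  hint <- if (is.null(orientation_hint)) ref[7L, , drop = FALSE]
          else as_points_matrix(orientation_hint)
  hint_c <- colMeans(hint)
  hz <- vapply(candidates, function(Rx) {
    (Rx %*% R1 %*% (hint_c - m))[3L]
  }, numeric(1L))
  pick <- if (hz[1L] >= 0) 1L else 2L
  if (flip_z) pick <- 3L - pick
  Rx <- candidates[[pick]]
  g <- as.numeric(Rx %*% R1 %*% (ref[7L, ] - m))
  if (sqrt(g[1L]^2 + g[2L]^2) < 1e-9)
    stopf("crista galli lies on the z-axis; z-rotation undefined")
  psi <- pi / 2 - atan2(g[2L], g[1L])
  Rz <- rotation_about_axis(c(0, 0, 1), psi)
  Rtot <- Rz %*% Rx %*% R1
  rigid_transform(Rtot, -as.numeric(Rtot %*% m), tol = 1e-6)
}

#' Align a patient dataset into the standardised reference frame
#'
#' The pre- and post-operative stages are aligned independently, each by the
#' transform computed from its own 7 reference landmarks (located in
#' unoperated anatomy, so both stages land in a common frame). The reported
#' residual is the RMS pre/post discrepancy at the static (calvarial,
#' skull-base and reference) landmarks, echoing the congruence of unoperated
#' regions after alignment.
#'
#' @param ds a `patient_dataset`
#' @param flip_z force the opposite superior direction (both stages).
#' @return the aligned `patient_dataset`; `$alignment` holds the per-stage
#'   transforms and the static-landmark residual (mm, `NA` without post data).
#' @export
align_dataset <- function(ds, flip_z = FALSE) {
  hint_roles <- c("bone_moving", "craniometric", "bone_static")
  tr <- list()
  for (stage in c("pre", "post")) {
    lms <- ds[[paste0("landmarks_", stage)]]
    if (is.null(lms)) next
    refs <- reference_landmarks(lms)
    hint <- landmark_coords(lms[lms$role %in% hint_roles, , drop = FALSE])
    t_st <- compute_reference_transform(refs, orientation_hint = hint,
                                        flip_z = flip_z)
    ds <- transform_stage(ds, t_st, stage)
    tr[[stage]] <- t_st
  }
  residual <- NA_real_
  if (!is.null(ds$landmarks_post)) {
    static_roles <- c("bone_static", "reference")
    pre_s <- landmark_coords(
      ds$landmarks_pre[ds$landmarks_pre$role %in% static_roles, , drop = FALSE])
    post_s <- landmark_coords(
      ds$landmarks_post[ds$landmarks_post$role %in% static_roles, , drop = FALSE])
    residual <- sqrt(mean(rowSums((pre_s - post_s)^2)))
  }
  ds$aligned <- TRUE
  ds$alignment <- list(pre = tr$pre, post = tr$post,
                       static_rms_residual = residual)
  ds
}
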