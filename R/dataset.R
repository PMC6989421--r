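#' Construct a patient dataset
#'
#' Bundles the pre- and post-operative skin and bone meshes with the combined
#' (skin + bone) landmark sets for one patient, plus the cohort label.
#'
#' @param patient_id identifier string.
#' @param skin_pre,skin_post,bone_pre,bone_post `surface_mesh` objects (post
#'   meshes may be `NULL` for prediction-only use).
#' @param landmarks_pre,landmarks_post `landmark_set`s covering skin and bone
#'   (post may be `NULL`).
#' @param cohort one of `"monobloc_older"`, `"bipartition_older"`,
#'   `"bipartition_younger"`.
#' @return An object of class `patient_dataset`.
#' @export
patient_dataset <- function(patient_id, skin_pre, bone_pre, landmarks_pre,
                            skin_post = NULL, bone_post = NULL,
                            landmarks_post = NULL,
                            cohort = c("monobloc_older", "bipartition_older",
                                       "bipartition_younger")) {
  cohort <- match.arg(cohort)
  if (!inherits(landmarks_pre, "landmark_set"))
    stopf("landmarks_pre must be a landmark_set")
  if (!is.null(landmarks_post)) {
    if (!correspondable(landmarks_pre, landmarks_post))
      stopf("pre and post landmark sets are not correspondable")
  }
  structure(list(patient_id = as.character(patient_id),
                 skin_pre = skin_pre, bone_pre = bone_pre,
                 skin_post = skin_post, bone_post = bone_post,
                 landmarks_pre = landmarks_pre,
                 landmarks_post = landmarks_post,
                 cohort = cohort, aligned = FALSE, alignment = NULL),
            class = "patient_dataset")
}

#' @export
print.patient_dataset <- function(x, ...) {
  cat(sprintf("<patient_dataset> %s (%s)%s\n", x$patient_id, x$cohort,
              if (x$aligned) ", aligned" else ""))
  cat(sprintf("  pre: %d landmarks%s%s\n", nrow(x$landmarks_pre),
              if (!is.null(x$skin_pre)) ", skin mesh" else "",
              if (!is.null(x$bone_pre)) ", bone mesh" else ""))
  if (!is.null(x$landmarks_post))
    cat(sprintf("  post: %d landmarks%s%s\n", nrow(x$landmarks_post),
                if (!is.null(x$skin_post)) ", skin mesh" else "",
                if (!is.null(x$bone_post)) ", bone mesh" else ""))
  invisible(x)
}

# Extract the 7 reference landmarks (in canonical order) from a landmark set.
reference_landmarks <- function(lms) {
  idx <- match(REFERENCE_LANDMARK_NAMES, lms$name)
  if (anyNA(idx))
    stopf("missing reference landmark(s): %s",
          paste(REFERENCE_LANDMARK_NAMES[is.na(idx)], collapse = ", "))
  landmark_coords(lms, REFERENCE_LANDMARK_NAMES)
}
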