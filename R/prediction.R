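#' Predict the post-operative outcome for a patient
#'
#' Composes forward normalisation, the cohort surgical warp and reverse
#' normalisation (pointwise sequential evaluation) and transports every
#' pre-operative mesh vertex and landmark through the identical composite
#' field. Leave-one-out integrity is machine-enforced: the surgical model
#' must not have been built with this patient's data unless
#' `allow_leakage = TRUE`.
#'
#' @param patient an aligned `patient_dataset`
#' @param surgical a [surgical_model()]
#' @param normalisation a [normalisation_model()] for this patient
#' @param allow_leakage override the leave-one-out guard (e.g. for the
#'   degenerate-cohort demonstrations).
#' @return An object of class `craniowarp_prediction` with `skin`, `bone`
#'   (predicted `surface_mesh`es), `landmarks` (stage `"predicted"`) and
#'   `provenance`.
#' @export
predict_outcome <- function(patient, surgical, normalisation,
                            allow_leakage = FALSE) {
  if (!inherits(surgical, "surgical_model")) stopf("not a surgical_model")
  if (!inherits(normalisation, "normalisation_model"))
    stopf("missing or invalid normalisation model")
  if (!isTRUE(patient$aligned)) stopf("patient dataset must be aligned first")
  if (normalisation$patient_id != patient$patient_id)
    stopf("normalisation model belongs to patient %s, not %s",
          normalisation$patient_id, patient$patient_id)
  if (patient$patient_id %in% surgical$contributing && !allow_leakage)
    stopf(paste0("data leakage: patient %s contributed to the surgical ",
                 "model; rebuild with exclude = \"%s\" (or set ",
                 "allow_leakage = TRUE)"),
          patient$patient_id, patient$patient_id)
  composite <- compose_fields(list(normalisation$forward, surgical$warp,
                                   normalisation$reverse))
  skin <- bone <- NULL
  if (!is.null(patient$skin_pre)) skin <- warp_mesh(composite, patient$skin_pre)
  if (!is.null(patient$bone_pre)) bone <- warp_mesh(composite, patient$bone_pre)
  lms <- set_landmark_coords(patient$landmarks_pre,
                             composite(landmark_coords(patient$landmarks_pre)),
                             stage = "predicted")
  prov <- list(patient_id = patient$patient_id,
               cohort = surgical$cohort,
               surgical_contributing = surgical$contributing,
               surgical_excluded = surgical$excluded,
               basis = surgical$warp$basis,
               alpha = surgical$warp$alpha,
               variance_estimator = surgical$variance_estimator,
               normalisation_alpha = normalisation$forward$alpha,
               package_version = as.character(utils::packageVersion("craniowarp")))
  structure(list(patient_id = patient$patient_id, skin = skin, bone = bone,
                 landmarks = lms, provenance = prov),
            class = "craniowarp_prediction")
}

#' @export
print.craniowarp_prediction <- function(x, ...) {
  cat(sprintf("<craniowarp_prediction> patient %s (%s model, %d contributors)\n",
              x$patient_id, x$provenance$cohort,
              length(x$provenance$surgical_contributing)))
  if (!is.null(x$skin)) print(x$skin)
  if (!is.null(x$bone)) print(x$bone)
  invisible(x)
}
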