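# Cohort averaging: surgical models (leave-one-out) and the craniometric
# shape-size normalisation.

.check_cohort <- function(cohort) {
  if (!is.list(cohort) || !all(vapply(cohort, inherits, TRUE, "patient_dataset")))
    stopf("cohort must be a list of patient_dataset objects")
  if (any(!vapply(cohort, `[[`, TRUE, "aligned")))
    stopf("all cohort datasets must be aligned first (see align_dataset)")
  ids <- vapply(cohort, `[[`, "", "patient_id")
  if (anyDuplicated(ids)) stopf("duplicate patient id(s): %s",
                                paste(ids[duplicated(ids)], collapse = ", "))
  # sort by id so every downstream average is independent of input order
  cohort[order(ids)]
}

# per-landmark scalar variance of a list of n x 3 contribution matrices:
# trace of the sample covariance, optionally divided by the contribution
# count ("of_mean": the variance of the averaged landmark, the default
# fidelity target for the averaged vectors).
.landmark_variance <- function(mats, estimator = c("of_mean", "sample")) {
  estimator <- match.arg(estimator)
  n <- length(mats)
  arr <- simplify2array(mats)                   # L x 3 x n
  mean_ <- apply(arr, c(1L, 2L), mean)
  if (n < 2L) return(list(mean = mean_, variance = rep(0, nrow(mean_))))
  dev2 <- sweep(arr, c(1L, 2L), mean_)^2
  v <- apply(dev2, 1L, sum) / (n - 1L)          # trace of sample covariance
  if (estimator == "of_mean") v <- v / n
  list(mean = mean_, variance = as.numeric(v))
}

#' Build a cohort-averaged surgical model (leave-one-out)
#'
#' Averages the pre-operative landmark positions and the pre-to-post change
#' vectors over the contributing datasets (all landmarks, including the
#' static cranium and skull base, so the warp is constrained in unoperated
#' anatomy), and fits the variance-weighted least-squares RBF surgical warp
#' to the averaged change vectors at the averaged pre-operative landmarks.
#'
#' @param cohort list of aligned `patient_dataset`s with post-operative
#'   landmarks.
#' @param exclude patient id(s) excluded from the averages (leave-one-out:
#'   exclude the patient the warp will be applied to). May name several ids.
#' @param basis,alpha passed to [rbf_warp()].
#' @param variance_estimator `"of_mean"` (trace of the sample covariance of
#'   the contributed change vectors divided by the contribution count;
#'   default) or `"sample"` (raw sample variance).
#' @return An object of class `surgical_model`: cohort label, landmark
#'   names/roles/regions, `mean_pre` (L x 3), `mean_change` (L x 3),
#'   `variances` (L), `contributing` ids and the fitted `warp`.
#' @export
surgical_model <- function(cohort, exclude = NULL,
                           basis = "biharmonic", alpha = 1,
                           variance_estimator = c("of_mean", "sample")) {
  variance_estimator <- match.arg(variance_estimator)
  cohort <- .check_cohort(cohort)
  ids <- vapply(cohort, `[[`, "", "patient_id")
  unknown <- setdiff(exclude, ids)
  if (length(unknown))
    stopf("exclude id(s) not in cohort: %s", paste(unknown, collapse = ", "))
  keep <- cohort[!ids %in% exclude]
  if (length(keep) < 1L)
    stopf("no contributing datasets left after exclusion")
  if (any(vapply(keep, function(d) is.null(d$landmarks_post), TRUE)))
    stopf("all contributing datasets need post-operative landmarks")
  stop_unless_correspondable(lapply(keep, `[[`, "landmarks_pre"))
  ref <- keep[[1L]]$landmarks_pre
  pre <- lapply(keep, function(d) landmark_coords(d$landmarks_pre))
  chg <- lapply(keep, function(d)
    landmark_coords(d$landmarks_post) - landmark_coords(d$landmarks_pre))
  pre_stats <- .landmark_variance(pre, variance_estimator)
  chg_stats <- .landmark_variance(chg, variance_estimator)
  warp <- rbf_warp(pre_stats$mean, chg_stats$mean,
                   variances = chg_stats$variance, basis = basis,
                   alpha = alpha)
  structure(list(cohort = keep[[1L]]$cohort,
                 names = ref$name, roles = ref$role, regions = ref$region,
                 mean_pre = pre_stats$mean, mean_change = chg_stats$mean,
                 variances = chg_stats$variance,
                 variance_estimator = variance_estimator,
                 contributing = unname(vapply(keep, `[[`, "", "patient_id")),
                 excluded = as.character(exclude %||% character()),
                 warp = warp),
            class = "surgical_model")
}

#' @export
print.surgical_model <- function(x, ...) {
  cat(sprintf("<surgical_model> %s: %d landmarks averaged over %d datasets\n",
              x$cohort, length(x$names), length(x$contributing)))
  cat(sprintf("  mean |change|: %.2f mm (max %.2f); variances [%.3g, %.3g] mm^2\n",
              mean(row_norms(x$mean_change)), max(row_norms(x$mean_change)),
              min(x$variances), max(x$variances)))
  if (length(x$excluded))
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.surgical_model <- function(object, points,
                                   type = c("position", "displacement"),
                                   ...) {
  predict(object$warp, points, type = match.arg(type))
}

#' Cohort craniometric landmark statistics
#'
#' Per-landmark mean position and scalar variance of the 36 craniometric
#' landmarks over the cohort's aligned pre-operative datasets; these drive
#' the shape--size normalisation warp.
#'
#' @inheritParams surgical_model
#' @return list of class `craniometric_stats` with `names`, `mean` (36 x 3),
#'   `variances`, `n`, `estimator`.
#' @export
craniometric_stats <- function(cohort,
                               variance_estimator = c("of_mean", "sample")) {
  variance_estimator <- match.arg(variance_estimator)
  cohort <- .check_cohort(cohort)
  if (length(cohort) < 2L) stopf("need at least 2 datasets")
  stop_unless_correspondable(lapply(cohort, `[[`, "landmarks_pre"))
  cran_names <- cohort[[1L]]$landmarks_pre$name[
    cohort[[1L]]$landmarks_pre$role == "craniometric"]
  if (!length(cran_names)) stopf("no craniometric landmarks in cohort")
  pos <- lapply(cohort, function(d)
    landmark_coords(d$landmarks_pre, cran_names))
  st <- .landmark_variance(pos, variance_estimator)
  structure(list(names = cran_names, mean = st$mean,
                 variances = st$variance, n = length(cohort),
                 estimator = variance_estimator),
            class = "craniometric_stats")
}

#' @export
print.craniometric_stats <- function(x, ...) {
  cat(sprintf("<craniometric_stats> %d landmarks over %d datasets (%s)\n",
              length(x$names), x$n, x$estimator))
  cat(sprintf("  variances [%.3g, %.3g] mm^2\n", min(x$variances),
              max(x$variances)))
  invisible(x)
}

#' Build the per-patient shape--size normalisation model
#'
#' The forward warp is a weighted least-squares RBF fitted at the
#' individual's 36 craniometric landmark positions, with target vectors
#' pointing towards the cohort average and weighted by the cohort
#' craniometric variances: applying it to the whole dataset removes
#' individual size, asymmetry and proportion. The reverse warp is an exact
#' (zero-smoothing) interpolant fitted at the forward-warped positions with
#' targets back to the individual's positions, so forward-then-reverse
#' restores every craniometric landmark exactly.
#'
#' @param patient an aligned `patient_dataset` with all craniometric
#'   landmarks.
#' @param stats a [craniometric_stats()] object for the patient's cohort
#'   (conventionally computed without this patient).
#' @param basis,alpha passed to the forward [rbf_warp()].
#' @return An object of class `normalisation_model` with `forward` and
#'   `reverse` `rbf_warp`s.
#' @export
normalisation_model <- function(patient, stats, basis = "biharmonic",
                                alpha = 1) {
  if (!inherits(stats, "craniometric_stats"))
    stopf("stats must be a craniometric_stats object")
  if (!isTRUE(patient$aligned))
    stopf("patient dataset must be aligned first")
  idx <- match(stats$names, patient$landmarks_pre$name)
  if (anyNA(idx))
    stopf("missing craniometric landmark(s): %s",
          paste(stats$names[is.na(idx)], collapse = ", "))
  own <- landmark_coords(patient$landmarks_pre, stats$names)
  forward <- rbf_warp(own, stats$mean - own, variances = stats$variances,
                      basis = basis, alpha = alpha)
  warped <- predict(forward, own, type = "position")
  reverse <- rbf_warp(warped, own - warped, variances = 0, basis = basis,
                      alpha = 0)
  structure(list(patient_id = patient$patient_id, names = stats$names,
                 centres = own, forward = forward, reverse = reverse,
                 stats = stats),
            class = "normalisation_model")
}

#' @export
print.normalisation_model <- function(x, ...) {
  cat(sprintf("<normalisation_model> patient %s: %d craniometric centres\n",
              x$patient_id, nrow(x$centres)))
  cat(sprintf("  mean |towards cohort average|: %.2f mm\n",
              mean(row_norms(x$forward$targets))))
  invisible(x)
}

#' @export
predict.normalisation_model <- function(object, points,
                                        direction = c("forward", "reverse"),
                                        type = c("position", "displacement"),
                                        ...) {
  direction <- match.arg(direction)
  predict(object[[direction]], points, type = match.arg(type))
}
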