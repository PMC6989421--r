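# End-to-end orchestration: dataset directory IO, run configuration and the
# full align -> model -> normalise -> predict -> evaluate pipeline.

#' Write / read a patient dataset directory
#'
#' One directory per patient: `skin_pre.ply`, `bone_pre.ply` (and `_post`
#' when present), `landmarks_pre.csv`, `landmarks_post.csv`, `meta.json`
#' (patient id and cohort label).
#'
#' @param ds a `patient_dataset`
#' @param dir patient directory
#' @param binary write binary little-endian PLY meshes
#' @return the directory (write) or a `patient_dataset` (read)
#' @export
write_patient_dataset <- function(ds, dir, binary = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (fld in c("skin_pre", "bone_pre", "skin_post", "bone_post")) {
    if (!is.null(ds[[fld]]))
      write_mesh(ds[[fld]], file.path(dir, paste0(fld, ".ply")),
                 binary = binary)
  }
  write_landmarks(ds$landmarks_pre, file.path(dir, "landmarks_pre.csv"))
  if (!is.null(ds$landmarks_post))
    write_landmarks(ds$landmarks_post, file.path(dir, "landmarks_post.csv"))
  jsonlite::write_json(list(patient_id = ds$patient_id, cohort = ds$cohort,
                            units = "mm"),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_patient_dataset
#' @export
read_patient_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  if (!is.null(meta$units) && !identical(meta$units, "mm"))
    stopf("dataset '%s' declares units '%s'; only mm is supported",
          dir, meta$units)
  rd <- function(name, cls, stage) {
    p <- file.path(dir, paste0(name, ".ply"))
    if (file.exists(p)) read_mesh(p, surface_class = cls, stage = stage)
    else NULL
  }
  lpost <- file.path(dir, "landmarks_post.csv")
  patient_dataset(
    meta$patient_id,
    skin_pre = rd("skin_pre", "skin", "pre"),
    bone_pre = rd("bone_pre", "bone", "pre"),
    landmarks_pre = read_landmarks(file.path(dir, "landmarks_pre.csv"),
                                   patient_id = meta$patient_id, stage = "pre"),
    skin_post = rd("skin_post", "skin", "post"),
    bone_post = rd("bone_post", "bone", "post"),
    landmarks_post = if (file.exists(lpost))
      read_landmarks(lpost, patient_id = meta$patient_id, stage = "post")
    else NULL,
    cohort = meta$cohort)
}

#' Pipeline run configuration
#'
#' @param cohort_dir directory of per-patient dataset subdirectories, or
#'   `NULL` to simulate a cohort.
#' @param out_dir output directory for all artifacts.
#' @param n,simulate_preset when simulating: cohort size and preset
#'   (`"monobloc"` or `"bipartition"`).
#' @param basis,alpha RBF basis and smoothing constant.
#' @param variance_estimator `"of_mean"` or `"sample"`.
#' @param exclude extra patient ids excluded from every surgical model (on
#'   top of the automatic leave-one-out exclusion of the predicted patient).
#' @param seed master seed.
#' @param flip_z force the opposite superior direction during alignment.
#' @param log_level `"info"` or `"quiet"`.
#' @return list of class `run_config`
#' @export
run_config <- function(cohort_dir = NULL, out_dir = "craniowarp_out",
                       n = 10L, simulate_preset = "monobloc",
                       basis = "biharmonic", alpha = 1,
                       variance_estimator = "of_mean",
                       exclude = character(), seed = 1L, flip_z = FALSE,
                       log_level = "info") {
  structure(list(cohort_dir = cohort_dir, out_dir = out_dir, n = as.integer(n),
                 simulate_preset = simulate_preset, basis = basis,
                 alpha = alpha, variance_estimator = variance_estimator,
                 exclude = as.character(exclude), seed = as.integer(seed),
                 flip_z = isTRUE(flip_z), log_level = log_level),
            class = "run_config")
}

#' Read a run configuration from a YAML or JSON file
#' @param path config file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, obj[intersect(names(obj), names(formals(run_config)))])
}

.log <- function(config, fmt, ...) {
  if (!identical(config$log_level, "quiet"))
    message(sprintf(paste0("[craniowarp] ", fmt), ...))
}

#' Run the full prediction pipeline
#'
#' Align every dataset into the reference frame, compute cohort craniometric
#' statistics, then for each patient build the leave-one-out surgical model
#' and the normalisation model, predict the post-operative outcome, and (when
#' actual post-operative surfaces exist) evaluate it with a signed-distance
#' map. All artifacts are written under `config$out_dir` with provenance
#' (resolved config, its hash, package version).
#'
#' @param config a [run_config()]
#' @param cohort optional pre-built list of `patient_dataset`s (overrides
#'   `cohort_dir` / simulation).
#' @return invisibly, a list with the aligned cohort, per-patient predictions
#'   and the evaluation summary data.frame.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cohort)) {
    if (!is.null(config$cohort_dir)) {
      dirs <- list.dirs(config$cohort_dir, recursive = FALSE)
      if (!length(dirs)) stopf("no patient directories in %s",
                               config$cohort_dir)
      .log(config, "reading %d patient datasets from %s", length(dirs),
           config$cohort_dir)
      cohort <- lapply(dirs, read_patient_dataset)
    } else {
      .log(config, "simulating %d-patient %s cohort (seed %d)", config$n,
           config$simulate_preset, config$seed)
      cohort <- generate_cohort(
        n = config$n,
        cohort = if (config$simulate_preset == "bipartition")
          "bipartition_older" else "monobloc_older",
        surgery = surgery_params(
          bipartition = config$simulate_preset == "bipartition"),
        seed = config$seed)
    }
  }
  cohort <- lapply(cohort, function(ds) {
    if (isTRUE(ds$aligned)) ds else align_dataset(ds, flip_z = config$flip_z)
  })
  ids <- vapply(cohort, `[[`, "", "patient_id")
  names(cohort) <- ids
  for (ds in cohort)
    .log(config, "aligned %s: %d landmarks, static pre/post RMS %.3f mm",
         ds$patient_id, nrow(ds$landmarks_pre),
         ds$alignment$static_rms_residual)

  # provenance: resolved config + hash
  cfg_path <- file.path(config$out_dir, "run_config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       null = "null")
  prov <- list(config_hash = unname(tools::md5sum(cfg_path)),
               package_version =
                 as.character(utils::packageVersion("craniowarp")))

  stats <- craniometric_stats(cohort,
                              variance_estimator = config$variance_estimator)
  results <- list()
  rows <- list()
  for (id in setdiff(ids, config$exclude)) {
    ds <- cohort[[id]]
    model <- surgical_model(cohort, exclude = unique(c(id, config$exclude)),
                            basis = config$basis, alpha = config$alpha,
                            variance_estimator = config$variance_estimator)
    norm <- normalisation_model(ds, stats, basis = config$basis,
                                alpha = config$alpha)
    pred <- predict_outcome(ds, model, norm)
    pdir <- file.path(config$out_dir, id)
    dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(pred$skin))
      write_mesh(pred$skin, file.path(pdir, "predicted_skin.ply"))
    if (!is.null(pred$bone))
      write_mesh(pred$bone, file.path(pdir, "predicted_bone.ply"))
    write_landmarks(pred$landmarks, file.path(pdir, "predicted_landmarks.csv"))
    jsonlite::write_json(c(pred$provenance, prov),
                         file.path(pdir, "provenance.json"),
                         auto_unbox = TRUE)
    row <- data.frame(patient_id = id,
                      contributing = length(model$contributing),
                      landmark_rms = NA_real_, sdm_mean = NA_real_,
                      sdm_rms = NA_real_)
    if (!is.null(ds$landmarks_post)) {
      dlm <- landmark_coords(pred$landmarks) - landmark_coords(ds$landmarks_post)
      row$landmark_rms <- sqrt(mean(rowSums(dlm^2)))
    }
    if (!is.null(pred$skin) && !is.null(ds$skin_post)) {
      sdm <- signed_distance_map(pred$skin, ds$skin_post)
      export_colour_map(sdm, pred$skin,
                        path = file.path(pdir, "difference_map.ply"))
      row$sdm_mean <- sdm$summary[["mean"]]
      row$sdm_rms <- sdm$summary[["rms"]]
      results[[id]] <- list(prediction = pred, distance_map = sdm)
    } else results[[id]] <- list(prediction = pred)
    .log(config,
         "predicted %s (%d contributors): landmark RMS %.3f mm, map RMS %s",
         id, length(model$contributing), row$landmark_rms,
         ifelse(is.na(row$sdm_rms), "n/a", sprintf("%.3f mm", row$sdm_rms)))
    rows[[id]] <- row
  }
  summary_df <- do.call(rbind, rows)
  utils::write.csv(summary_df, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)
  invisible(list(cohort = cohort, results = results, summary = summary_df,
                 provenance = prov))
}
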