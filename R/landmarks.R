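#' Landmark roles and facial regions
#'
#' Landmarks carry a `role` describing how the pipeline uses them and a
#' `region` used for colour-coded reporting of change vectors and
#' signed-distance summaries.
#'
#' Roles:
#' \describe{
#'   \item{skin}{placed on the facial skin iso-surface; moved by surgery.}
#'   \item{bone_moving}{on operated (osteotomised) facial bone.}
#'   \item{craniometric}{bone landmarks encoding craniofacial proportions;
#'     the 36-point subset driving the shape--size normalisation warp.}
#'   \item{bone_static}{calvarial/skull-base bone landmarks constraining the
#'     warps in unoperated anatomy.}
#'   \item{reference}{the 7 skull-base landmarks defining the standardised
#'     reference frame (semicircular canals, glenoid fossae, crista galli).}
#' }
#' @name landmark-schema
#' @keywords internal
NULL

LANDMARK_ROLES <- c("skin", "bone_moving", "bone_static", "craniometric",
                    "reference")
LANDMARK_REGIONS <- c("forehead", "brow", "ocular", "nasal", "maxillary",
                      "zygomatic", "mandibular", "calvarium_skull_base",
                      "none")
BONE_ROLES <- c("bone_moving", "bone_static", "craniometric", "reference")

# Names of the 7 reference-frame landmarks, in their canonical order
# (right/left lateral semicircular canal lateral + posterior points, right and
# left glenoid fossae, crista galli).
REFERENCE_LANDMARK_NAMES <- c("r_lsc_lateral", "l_lsc_lateral",
                              "r_lsc_posterior", "l_lsc_posterior",
                              "r_glenoid", "l_glenoid", "crista_galli")

# region layout: counts of midline landmarks and left/right pairs, per role
.dict_layout <- function() {
  rbind(
    data.frame(role = "skin", region = c("forehead", "brow", "ocular", "nasal",
                                         "maxillary", "zygomatic", "mandibular"),
               mid = c(4L, 0L, 0L, 4L, 2L, 0L, 2L),
               pairs = c(4L, 5L, 6L, 2L, 6L, 5L, 5L)),
    data.frame(role = "craniometric",
               region = c("forehead", "brow", "ocular", "nasal", "maxillary",
                          "zygomatic"),
               mid = c(2L, 0L, 0L, 2L, 2L, 0L),
               pairs = c(2L, 2L, 4L, 1L, 3L, 3L)),
    data.frame(role = "bone_moving",
               region = c("forehead", "brow", "ocular", "nasal", "maxillary",
                          "zygomatic", "mandibular"),
               mid = c(2L, 0L, 0L, 2L, 2L, 0L, 2L),
               pairs = c(2L, 3L, 3L, 1L, 3L, 3L, 2L)),
    data.frame(role = "bone_static", region = "calvarium_skull_base",
               mid = 3L, pairs = 2L)
  )
}

#' The packaged default landmark dictionary
#'
#' Defines the canonical landmark name list, roles and regions used by the
#' synthetic generator and by landmark file validation: 78 skin landmarks, 78
#' bone landmarks of which 36 carry the craniometric role, 7 static calvarial
#' landmarks and the 7 reference-frame landmarks.
#'
#' @return A data.frame with columns `name`, `role`, `region`, `side`
#'   (`"l"`, `"r"` or `"m"`) and `pair` (name of the mirror-image partner, or
#'   `NA` for midline landmarks).
#' @examples
#' d <- landmark_dictionary()
#' table(d$role)
#' @export
landmark_dictionary <- function() {
  lay <- .dict_layout()
  rows <- vector("list", nrow(lay) + 1L)
  for (i in seq_len(nrow(lay))) {
    role <- lay$role[i]; region <- lay$region[i]
    prefix <- switch(role, skin = "skin", craniometric = "cran",
                     bone_moving = "bone", bone_static = "calv")
    mids <- if (lay$mid[i] > 0L)
      sprintf("%s_%s_m_%d", prefix, region, seq_len(lay$mid[i])) else character()
    ln <- rn <- character()
    if (lay$pairs[i] > 0L) {
      ln <- sprintf("%s_%s_l_%d", prefix, region, seq_len(lay$pairs[i]))
      rn <- sprintf("%s_%s_r_%d", prefix, region, seq_len(lay$pairs[i]))
    }
    rows[[i]] <- data.frame(
      name = c(mids, ln, rn),
      role = role, region = region,
      side = c(rep("m", length(mids)), rep("l", length(ln)),
               rep("r", length(rn))),
      pair = c(rep(NA_character_, length(mids)), rn, ln),
      stringsAsFactors = FALSE)
  }
  ref_side <- c("r", "l", "r", "l", "r", "l", "m")
  ref_pair <- c("l_lsc_lateral", "r_lsc_lateral", "l_lsc_posterior",
                "r_lsc_posterior", "l_glenoid", "r_glenoid", NA)
  rows[[length(rows)]] <- data.frame(
    name = REFERENCE_LANDMARK_NAMES, role = "reference",
    region = "calvarium_skull_base", side = ref_side, pair = ref_pair,
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Construct a landmark set
#'
#' An ordered set of named 3D anatomical landmarks (coordinates in mm) with
#' role and region labels, belonging to one patient at one stage.
#'
#' @param df data.frame with columns `name`, `x`, `y`, `z`, `role`, `region`.
#' @param patient_id patient identifier string.
#' @param stage one of `"pre"`, `"post"`, `"predicted"`.
#' @return An object of class `landmark_set` (a data.frame).
#' @export
landmark_set <- function(df, patient_id = "unknown",
                         stage = c("pre", "post", "predicted")) {
  stage <- match.arg(stage)
  need <- c("name", "x", "y", "z", "role", "region")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("landmark data missing column(s): %s",
                          paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  df$name <- as.character(df$name); df$role <- as.character(df$role)
  df$region <- as.character(df$region)
  if (any(!nzchar(df$name))) stopf("landmark names must be non-empty")
  if (anyDuplicated(df$name)) stopf("duplicate landmark name(s): %s",
    paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  bad_role <- setdiff(unique(df$role), LANDMARK_ROLES)
  if (length(bad_role)) stopf("unknown landmark role(s): %s",
                              paste(bad_role, collapse = ", "))
  bad_reg <- setdiff(unique(df$region), LANDMARK_REGIONS)
  if (length(bad_reg)) stopf("unknown landmark region(s): %s",
                             paste(bad_reg, collapse = ", "))
  assert_finite_matrix(as.matrix(df[, c("x", "y", "z")]), "landmark positions")
  structure(df, patient_id = as.character(patient_id), stage = stage,
            class = c("landmark_set", "data.frame"))
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> patient %s, stage %s: %d landmarks\n",
              attr(x, "patient_id"), attr(x, "stage"), nrow(x)))
  print(table(role = x$role))
  invisible(x)
}

#' Landmark coordinates as a matrix
#' @param lms a `landmark_set`
#' @param names optional character vector selecting (and ordering) landmarks.
#' @return numeric n x 3 matrix with landmark names as rownames.
#' @export
landmark_coords <- function(lms, names = NULL) {
  if (!is.null(names)) {
    idx <- match(names, lms$name)
    if (anyNA(idx)) stopf("landmark(s) not found: %s",
                          paste(names[is.na(idx)], collapse = ", "))
    lms <- lms[idx, , drop = FALSE]
  }
  m <- as.matrix(lms[, c("x", "y", "z")])
  rownames(m) <- lms$name
  m
}

#' Replace landmark coordinates, keeping names/roles/regions
#' @param lms a `landmark_set`
#' @param coords numeric nrow(lms) x 3 matrix
#' @param stage optional new stage label
#' @return a `landmark_set`
#' @export
set_landmark_coords <- function(lms, coords, stage = NULL) {
  coords <- as_points_matrix(coords)
  if (nrow(coords) != nrow(lms)) stopf("coordinate count mismatch")
  lms$x <- coords[, 1L]; lms$y <- coords[, 2L]; lms$z <- coords[, 3L]
  if (!is.null(stage)) attr(lms, "stage") <- stage
  lms
}

#' Test whether two landmark sets are correspondable
#'
#' Two sets correspond iff they contain identical name sequences.
#' @param a,b `landmark_set` objects
#' @return logical
#' @export
correspondable <- function(a, b) {
  nrow(a) == nrow(b) && all(a$name == b$name)
}

stop_unless_correspondable <- function(sets) {
  ref <- sets[[1L]]
  for (i in seq_along(sets)[-1L]) {
    if (!correspondable(ref, sets[[i]])) {
      extra <- setdiff(sets[[i]]$name, ref$name)
      miss <- setdiff(ref$name, sets[[i]]$name)
      stopf("landmark sets not correspondable (set %d): missing [%s], extra [%s]",
            i, paste(utils::head(miss, 5L), collapse = ", "),
            paste(utils::head(extra, 5L), collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Read landmarks from CSV or JSON
#'
#' CSV files use the header `name,x,y,z,role,region`; the JSON schema is an
#' object with fields `patient_id`, `stage`, `units` (must be `"mm"`) and a
#' `landmarks` array of `{name, x, y, z, role, region}` records. Coordinates
#' are millimetres; files declaring any other unit are rejected rather than
#' converted.
#'
#' @param path file path (`.csv` or `.json`)
#' @param patient_id,stage used for CSV input (JSON carries its own).
#' @return a `landmark_set`
#' @export
read_landmarks <- function(path, patient_id = "unknown", stage = "pre") {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    return(landmark_set(df, patient_id = patient_id, stage = stage))
  }
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.null(obj$units) && !identical(obj$units, "mm"))
      stopf("landmark file declares units '%s'; only mm is supported", obj$units)
    return(landmark_set(as.data.frame(obj$landmarks),
                        patient_id = obj$patient_id %||% patient_id,
                        stage = obj$stage %||% stage))
  }
  stopf("unsupported landmark file extension: '%s'", ext)
}

#' Write landmarks to CSV or JSON
#' @param lms a `landmark_set`
#' @param path output path; format chosen by extension (`.csv` or `.json`)
#' @return `path`, invisibly
#' @export
write_landmarks <- function(lms, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(as.data.frame(lms), path, row.names = FALSE,
                     quote = FALSE)
  } else if (ext == "json") {
    obj <- list(patient_id = attr(lms, "patient_id"),
                stage = attr(lms, "stage"), units = "mm",
                landmarks = as.data.frame(lms))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else stopf("unsupported landmark file extension: '%s'", ext)
  invisible(path)
}
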