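# Prediction quality: signed-distance maps, per-region summaries, landmark
# placement reliability.

#' Signed-distance map between a predicted and an actual surface
#'
#' For every vertex of the predicted mesh, the triangle-exact closest point
#' on the actual mesh is found; the distance is signed positive when the
#' vertex lies on the outward-normal side of the actual surface
#' (over-prediction) and negative inside. The surface normal at the foot
#' point is the barycentric interpolation of angle-weighted vertex normals.
#' If the actual mesh is not consistently oriented the map falls back to
#' unsigned distances with a warning and `unsigned = TRUE`.
#'
#' @param predicted,actual `surface_mesh`es in the same frame.
#' @return An object of class `signed_distance_map`: `distance` (per
#'   predicted vertex, mm), `summary` (mean, RMS, median, 5th/95th
#'   percentiles), `unsigned` flag, and the closest-point details.
#' @export
signed_distance_map <- function(predicted, actual) {
  if (nrow(predicted$vertices) == 0L || nrow(actual$faces) == 0L)
    stopf("both meshes must be non-empty")
  cp <- closest_point_on_mesh(predicted$vertices, actual)
  unsigned <- FALSE
  if (!is_consistently_oriented(actual)) {
    warning("actual mesh is not consistently oriented; ",
            "returning unsigned distances", call. = FALSE)
    d <- cp$distance
    unsigned <- TRUE
  } else {
    vn <- vertex_normals(actual)
    f <- actual$faces[cp$face, , drop = FALSE]
    n_foot <- cp$bary[, 1L] * vn[f[, 1L], , drop = FALSE] +
      cp$bary[, 2L] * vn[f[, 2L], , drop = FALSE] +
      cp$bary[, 3L] * vn[f[, 3L], , drop = FALSE]
    side <- rowSums((predicted$vertices - cp$points) * n_foot)
    d <- cp$distance * ifelse(side < 0, -1, 1)
  }
  structure(list(distance = d, unsigned = unsigned,
                 closest = cp,
                 summary = c(mean = mean(d), rms = sqrt(mean(d^2)),
                             median = stats::median(d),
                             p5 = unname(stats::quantile(d, 0.05)),
                             p95 = unname(stats::quantile(d, 0.95))),
                 sign_convention = "positive = predicted outside actual"),
            class = "signed_distance_map")
}

#' @export
print.signed_distance_map <- function(x, ...) {
  cat(sprintf("<signed_distance_map> %d vertices%s\n", length(x$distance),
              if (x$unsigned) " (unsigned fallback)" else ""))
  print(round(x$summary, 3))
  invisible(x)
}

#' @export
summary.signed_distance_map <- function(object, ...) object$summary

#' Per-region summary of a signed-distance map
#'
#' @param map a [signed_distance_map()]
#' @param regions character vector of region labels, one per predicted-mesh
#'   vertex, from the standard vocabulary (`"none"` allowed).
#' @return data.frame with one row per region present: n, mean, RMS, min,
#'   max.
#' @export
region_summary <- function(map, regions) {
  regions <- as.character(regions)
  if (length(regions) != length(map$distance))
    stopf("need one region label per vertex (%d != %d)", length(regions),
          length(map$distance))
  bad <- setdiff(unique(regions), LANDMARK_REGIONS)
  if (length(bad)) stopf("unknown region name(s): %s",
                         paste(bad, collapse = ", "))
  d <- map$distance
  out <- do.call(rbind, lapply(split(seq_along(d), regions), function(i)
    data.frame(n = length(i), mean = mean(d[i]), rms = sqrt(mean(d[i]^2)),
               min = min(d[i]), max = max(d[i]))))
  out <- cbind(region = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Intra-operator landmark placement reliability
#'
#' From repeated placements of the same landmark set, computes the
#' per-landmark SD — the root-mean-square Euclidean deviation from the mean
#' position over the repeats — plus per-axis SDs, and assigns each landmark
#' to an accuracy band at the 1 / 2 / 3 mm thresholds (half-open intervals:
#' `high` [0, 1), `accurate` [1, 2), `less_accurate` [2, 3),
#' `out_of_band` [3, Inf)).
#'
#' @param repeats list of >= 2 correspondable `landmark_set`s.
#' @return data.frame of class `reliability_report` with columns `name`,
#'   `role`, `region`, `sd` (mm), `sd_x`, `sd_y`, `sd_z`, `band`.
#' @export
landmark_reliability <- function(repeats) {
  if (!is.list(repeats) || length(repeats) < 2L)
    stopf("need at least 2 repeated landmark sets")
  stop_unless_correspondable(repeats)
  arr <- simplify2array(lapply(repeats, landmark_coords))   # L x 3 x R
  mean_ <- apply(arr, c(1L, 2L), mean)
  dev <- sweep(arr, c(1L, 2L), mean_)
  sd3 <- sqrt(apply(dev^2, 1L, mean) * 3)   # mean over repeats of |dev|^2
  sd_axis <- sqrt(apply(dev^2, c(1L, 2L), mean))
  band <- cut(sd3, breaks = c(0, 1, 2, 3, Inf), right = FALSE,
              labels = c("high", "accurate", "less_accurate", "out_of_band"))
  ref <- repeats[[1L]]
  out <- data.frame(name = ref$name, role = ref$role, region = ref$region,
                    sd = sd3, sd_x = sd_axis[, 1L], sd_y = sd_axis[, 2L],
                    sd_z = sd_axis[, 3L], band = as.character(band))
  class(out) <- c("reliability_report", "data.frame")
  out
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> %d landmarks, %s\n", nrow(x),
              "SD = RMS 3D deviation from the mean position"))
  tab <- table(factor(x$band, levels = c("high", "accurate", "less_accurate",
                                         "out_of_band")))
  pct <- 100 * tab / nrow(x)
  for (b in names(tab))
    cat(sprintf("  %-13s %3d (%.1f%%)\n", b, tab[[b]], pct[[b]]))
  invisible(x)
}

#' Export a colour-coded difference mesh
#'
#' Maps signed distances onto a diverging colour scale (blue = predicted
#' inside the actual surface, green = 0, red = outside), clipped at the
#' scale limits, and optionally writes a PLY with uchar RGB vertex colours
#' plus a CSV sidecar of the raw per-vertex values.
#'
#' @param map a [signed_distance_map()]
#' @param mesh the predicted `surface_mesh` the map was computed on.
#' @param limits `c(min, max)` colour scale limits in mm, min < max.
#' @param path optional output PLY path (the sidecar takes the same name
#'   with extension `.csv`).
#' @return list with `mesh`, `colors` (n x 3 integer, 0-255) and the paths
#'   written (if any).
#' @export
export_colour_map <- function(map, mesh, limits = c(-5, 5), path = NULL) {
  if (length(limits) != 2L || !all(is.finite(limits)) ||
      limits[1L] >= limits[2L])
    stopf("limits must be finite with min < max")
  v <- pmin(pmax(map$distance, limits[1L]), limits[2L])
  # piecewise-linear diverging ramp, green at 0
  t <- ifelse(v < 0, v / abs(limits[1L]), v / abs(limits[2L]))
  ramp <- grDevices::colorRamp(c("#0000FF", "#00FF00", "#FF0000"))
  colors <- ramp((t + 1) / 2)
  colors <- matrix(as.integer(round(colors)), ncol = 3L)
  written <- character()
  if (!is.null(path)) {
    write_mesh(mesh, path, colors = colors)
    sidecar <- paste0(tools::file_path_sans_ext(path), ".csv")
    utils::write.csv(data.frame(vertex = seq_along(map$distance),
                                signed_distance_mm = map$distance),
                     sidecar, row.names = FALSE)
    written <- c(path, sidecar)
  }
  list(mesh = mesh, colors = colors, paths = written)
}
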