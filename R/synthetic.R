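# Synthetic head, surgery and cohort generator. Heads are parametric
# (superellipsoid-like radial surfaces); every landmark position is an exact
# function of the parameters, so ground truth is available for every stage of
# the pipeline.

#' Head shape parameters for the synthetic generator
#'
#' @param scale overall size factor (1 = adult-like head, canonical
#'   half-width ~72 mm); sensible range 0.7–1.3.
#' @param turricephaly vertical (z) stretch factor; > 1 gives the tall
#'   (turricephalic) skull, range 0.8–1.3.
#' @param brachycephaly antero-posterior (y) compression factor; > 1 gives
#'   the short (brachycephalic) skull, range 0.8–1.25.
#' @param asymmetry amplitude (mm) of a smooth unilateral cheek/calvarial
#'   bulge, range 0–6.
#' @param retrusion mid-face retrusion depth (mm), range 0–12.
#' @param seed integer; generation is fully deterministic given the params.
#' @return list of class `head_params`
#' @export
head_params <- function(scale = 1, turricephaly = 1, brachycephaly = 1,
                        asymmetry = 0, retrusion = 0, seed = 1L) {
  stopifnot(scale > 0, turricephaly > 0, brachycephaly > 0,
            asymmetry >= 0, retrusion >= 0)
  structure(list(scale = scale, turricephaly = turricephaly,
                 brachycephaly = brachycephaly, asymmetry = asymmetry,
                 retrusion = retrusion, seed = as.integer(seed)),
            class = "head_params")
}

#' Surgical displacement-field parameters
#'
#' The simulated operation advances the mid-face/forehead by a smooth
#' analytic field decaying with distance from the facial apex, vanishing at
#' the skull base.
#'
#' @param advancement 3-vector (mm): displacement at the mid-face apex
#'   (+y anterior). Default 15 mm forward, a typical distraction advancement.
#' @param descent additional inferior (-z) displacement component (mm).
#' @param falloff Gaussian decay length-scale (mm) of the field.
#' @param bipartition add para-midline maxillary divergence and orbital
#'   medialisation components.
#' @param noise_sd SD (mm) of isotropic Gaussian placement noise added to
#'   the post-operative landmark placements only (surfaces are transported
#'   noise-free), emulating manual landmarking error. The 7 reference-frame
#'   landmarks are placed noise-free (deep anatomical points with the
#'   highest placement reliability).
#' @param mandible_rotation additionally rotate mandibular landmarks about a
#'   condylar axis, proportional to the mid-face descent (auto-rotation).
#' @param seed integer seed for the placement noise.
#' @return list of class `surgery_params`
#' @export
surgery_params <- function(advancement = c(0, 15, 0), descent = 4,
                           falloff = 40, bipartition = FALSE, noise_sd = 1,
                           mandible_rotation = FALSE, seed = 1L) {
  stopifnot(length(advancement) == 3L, falloff > 0, noise_sd >= 0)
  structure(list(advancement = as.numeric(advancement),
                 descent = as.numeric(descent), falloff = as.numeric(falloff),
                 bipartition = isTRUE(bipartition),
                 noise_sd = as.numeric(noise_sd),
                 mandible_rotation = isTRUE(mandible_rotation),
                 seed = as.integer(seed)),
            class = "surgery_params")
}

# direction on the unit sphere from latitude/longitude in degrees;
# lon 0 = anterior (+y), lon > 0 towards the patient's right (+x),
# lat > 0 superior (+z)
.dir <- function(lat, lon) {
  la <- lat * pi / 180; lo <- lon * pi / 180
  cbind(cos(la) * sin(lo), cos(la) * cos(lo), sin(la))
}

.angdist <- function(u, v) {
  d <- u %*% as.numeric(v)
  acos(pmin(pmax(d, -1), 1))
}

# canonical bone radius (mm) along unit directions u (rows)
.bone_radius <- function(u, retrusion = 0) {
  ax <- c(72, 88, 78)
  ell <- 1 / sqrt((u[, 1L] / ax[1L])^2 + (u[, 2L] / ax[2L])^2 +
                    (u[, 3L] / ax[3L])^2)
  face <- 6 * exp(-(.angdist(u, .dir(-5, 0)) / 0.5)^2)
  chin <- 4 * exp(-(.angdist(u, .dir(-55, 0)) / 0.35)^2)
  retr <- retrusion * exp(-(.angdist(u, .dir(-12, 0)) / 0.45)^2)
  as.numeric(ell + face + chin - retr)
}

# skin thickness (mm): thicker over the cheeks, thinner over the forehead
.skin_thickness <- function(u) {
  t <- 5 +
    4 * exp(-(.angdist(u, .dir(-18, 35)) / 0.4)^2) +
    4 * exp(-(.angdist(u, .dir(-18, -35)) / 0.4)^2) -
    2.5 * exp(-(.angdist(u, .dir(45, 0)) / 0.5)^2)
  pmax(as.numeric(t), 2)
}

# per-patient shape map (canonical mm coordinates -> patient coordinates)
.shape_map <- function(params) {
  ca <- c(-40, 40, 10)   # centre of the asymmetric bulge (left cheek)
  function(x) {
    x <- as_points_matrix(x)
    d2 <- rowSums(sweep(x, 2L, ca)^2)
    x[, 1L] <- x[, 1L] + params$asymmetry * exp(-d2 / 45^2)
    x[, 2L] <- x[, 2L] / params$brachycephaly
    x[, 3L] <- x[, 3L] * params$turricephaly
    params$scale * x
  }
}

# canonical interior positions of the 7 reference landmarks (mm)
.reference_canonical <- function() {
  m <- rbind(r_lsc_lateral   = c( 42, -15, -15),
             l_lsc_lateral   = c(-42, -15, -15),
             r_lsc_posterior = c( 38, -25, -15),
             l_lsc_posterior = c(-38, -25, -15),
             r_glenoid       = c( 48,   5, -25),
             l_glenoid       = c(-48,   5, -25),
             crista_galli    = c(  0,  55,  -5))
  m[REFERENCE_LANDMARK_NAMES, , drop = FALSE]
}

# angular patches per region (degrees): lat range and right-side lon range
.region_patches <- function() {
  list(forehead   = list(lat = c(36, 58),  lon = c(8, 38)),
       brow       = list(lat = c(22, 32),  lon = c(10, 45)),
       ocular     = list(lat = c(8, 20),   lon = c(12, 45)),
       nasal      = list(lat = c(-15, 15), lon = c(5, 12)),
       maxillary  = list(lat = c(-35, -10), lon = c(8, 40)),
       zygomatic  = list(lat = c(0, 15),   lon = c(50, 75)),
       mandibular = list(lat = c(-60, -38), lon = c(8, 45)))
}

# deterministic (lat, lon) for every surface landmark in the dictionary;
# small per-role latitude offsets keep skin/craniometric/bone landmarks in a
# region distinct; left-side landmarks mirror their right partners.
.landmark_directions <- function(dict = landmark_dictionary()) {
  patches <- .region_patches()
  role_off <- c(skin = 0, cran = 1.7, bone = -1.7)
  out <- matrix(NA_real_, nrow(dict), 2L,
                dimnames = list(dict$name, c("lat", "lon")))
  calv <- rbind(calv_calvarium_skull_base_m_1 = c(84, 0),
                calv_calvarium_skull_base_m_2 = c(10, 179),
                calv_calvarium_skull_base_m_3 = c(68, 0),
                calv_calvarium_skull_base_l_1 = c(55, -110),
                calv_calvarium_skull_base_r_1 = c(55, 110),
                calv_calvarium_skull_base_l_2 = c(12, -100),
                calv_calvarium_skull_base_r_2 = c(12, 100))
  for (i in seq_len(nrow(dict))) {
    nm <- dict$name[i]
    if (dict$role[i] == "reference") next
    if (dict$role[i] == "bone_static") { out[i, ] <- calv[nm, ]; next }
    p <- patches[[dict$region[i]]]
    prefix <- sub("_.*", "", nm)
    k <- as.integer(sub(".*_", "", nm))
    side <- dict$side[i]
    if (side == "m") {
      # midline column: spread in latitude, alternate a small lat shift
      n_m <- sum(dict$role == dict$role[i] & dict$region == dict$region[i] &
                   dict$side == "m")
      lat <- p$lat[1L] + (k - 0.5) / n_m * diff(p$lat)
      lon <- 0
    } else {
      n_p <- sum(dict$role == dict$role[i] & dict$region == dict$region[i] &
                   dict$side == "r")
      # two-column zig-zag layout inside the patch
      lat <- p$lat[1L] + (k - 0.5) / n_p * diff(p$lat)
      lon <- p$lon[1L] + (if (k %% 2L) 0.3 else 0.7) * diff(p$lon)
      if (side == "l") lon <- -lon
    }
    out[i, ] <- c(lat + role_off[[prefix]], lon)
  }
  out
}

# latitude-longitude triangulation of the unit sphere with polar caps
.uv_sphere <- function(n_lat = 25L, n_lon = 36L) {
  lats <- seq(-90, 90, length.out = n_lat)[-c(1L, n_lat)]
  lons <- seq(-180, 180, length.out = n_lon + 1L)[-(n_lon + 1L)]
  grid <- expand.grid(lon = lons, lat = lats)
  dirs <- rbind(.dir(grid$lat, grid$lon), c(0, 0, -1), c(0, 0, 1))
  south <- nrow(dirs) - 1L; north <- nrow(dirs)
  idx <- function(i, j) (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  faces <- list()
  nr <- length(lats)
  for (i in seq_len(nr - 1L)) {
    for (j in seq_len(n_lon)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      c_ <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
      faces[[length(faces) + 1L]] <- c(a, b, d)
      faces[[length(faces) + 1L]] <- c(a, d, c_)
    }
  }
  for (j in seq_len(n_lon)) {
    faces[[length(faces) + 1L]] <- c(south, idx(1L, j + 1L), idx(1L, j))
    faces[[length(faces) + 1L]] <- c(north, idx(nr, j), idx(nr, j + 1L))
  }
  list(dirs = dirs, faces = do.call(rbind, faces))
}

# orient all faces outward (positive enclosed volume)
.orient_outward <- function(vertices, faces) {
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c_ <- vertices[faces[, 3L], , drop = FALSE]
  vol <- sum(a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) +
               a[, 2L] * (b[, 3L] * c_[, 1L] - b[, 1L] * c_[, 3L]) +
               a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])) / 6
  if (vol < 0) faces[, 2:3] <- faces[, 3:2]
  faces
}

#' Closed triangulated sphere mesh
#'
#' Convenience surface for distance-map validation (e.g. concentric-sphere
#' tests with analytically known signed distances).
#' @param radius sphere radius, mm
#' @param n_lat,n_lon latitude/longitude resolution
#' @param centre sphere centre (mm)
#' @return a `surface_mesh` (outward-oriented)
#' @export
sphere_mesh <- function(radius = 50, n_lat = 40L, n_lon = 64L,
                        centre = c(0, 0, 0)) {
  s <- .uv_sphere(n_lat, n_lon)
  v <- sweep(s$dirs * radius, 2L, centre, `+`)
  surface_mesh(v, .orient_outward(v, s$faces), surface_class = "skin",
               stage = "pre")
}

#' Generate a synthetic head (bone + skin mesh and full landmark set)
#'
#' The bone surface is a smoothly deformed superellipsoid-like radial surface
#' with facial and chin protrusions; the skin is the bone offset outward by a
#' spatially varying thickness (thicker over the cheeks, thinner over the
#' forehead). Landmark positions are exact analytic functions of the
#' parameters — they are not snapped to mesh vertices.
#'
#' @param params a [head_params()] object
#' @param patient_id id attached to the landmark set
#' @param n_lat,n_lon mesh resolution
#' @return list with `skin` and `bone` (`surface_mesh`), `landmarks`
#'   (pre-operative `landmark_set` covering all roles) and `params`.
#' @export
generate_head <- function(params = head_params(), patient_id = "synthetic",
                          n_lat = 25L, n_lon = 36L) {
  stopifnot(inherits(params, "head_params"))
  psi <- .shape_map(params)
  sph <- .uv_sphere(n_lat, n_lon)
  rb <- .bone_radius(sph$dirs, params$retrusion)
  bone_v <- psi(sph$dirs * rb)
  skin_v <- psi(sph$dirs * (rb + .skin_thickness(sph$dirs)))
  bone <- surface_mesh(bone_v, .orient_outward(bone_v, sph$faces),
                       surface_class = "bone", stage = "pre")
  skin <- surface_mesh(skin_v, .orient_outward(skin_v, sph$faces),
                       surface_class = "skin", stage = "pre")
  dict <- landmark_dictionary()
  dl <- .landmark_directions(dict)
  pos <- matrix(NA_real_, nrow(dict), 3L)
  surf <- dict$role != "reference"
  u <- .dir(dl[surf, "lat"], dl[surf, "lon"])
  r <- .bone_radius(u, params$retrusion)
  r[dict$role[surf] == "skin"] <- r[dict$role[surf] == "skin"] +
    .skin_thickness(u)[dict$role[surf] == "skin"]
  pos[surf, ] <- psi(u * r)
  pos[!surf, ] <- psi(.reference_canonical())
  lms <- landmark_set(data.frame(name = dict$name, x = pos[, 1L],
                                 y = pos[, 2L], z = pos[, 3L],
                                 role = dict$role, region = dict$region),
                      patient_id = patient_id, stage = "pre")
  list(skin = skin, bone = bone, landmarks = lms, params = params)
}

#' The analytic ground-truth surgical displacement field
#'
#' @param params a [surgery_params()] object
#' @return function mapping an m x 3 matrix of points (generator frame, mm)
#'   to an m x 3 matrix of displacements (mm).
#' @export
surgical_field <- function(params) {
  apex <- c(0, 90, -5)
  adv <- params$advancement + c(0, 0, -params$descent)
  L <- params$falloff
  bip <- params$bipartition
  anchors <- .reference_canonical()   # the field vanishes at the skull base
  La <- 25
  function(x) {
    x <- as_points_matrix(x)
    w <- exp(-rowSums(sweep(x, 2L, apex)^2) / L^2)
    d_ref <- apply(.cross_dist_cpp(x, anchors), 1L, min)
    mask <- 1 - exp(-(d_ref / La)^2)
    disp <- outer(w * mask, adv)
    if (bip) {
      wm <- exp(-rowSums(sweep(x, 2L, c(0, 75, -35))^2) / 35^2)
      wo <- exp(-rowSums(sweep(x, 2L, c(0, 75, 15))^2) / 25^2)
      disp[, 1L] <- disp[, 1L] + mask * (0.25 * x[, 1L] * wm -
                                           0.35 * x[, 1L] * wo)
    }
    disp
  }
}

#' Simulate facial distraction surgery on a synthetic head
#'
#' Applies the smooth analytic surgical field of [surgical_field()] to the
#' head's meshes and landmarks. Gaussian placement noise (`noise_sd`) is
#' added to the post-operative landmark placements only; surfaces are
#' transported noise-free. Optionally the mandibular landmarks additionally
#' rotate about a condylar axis proportionally to the mid-face descent
#' (auto-rotation).
#'
#' @param head output of [generate_head()]
#' @param params a [surgery_params()] object
#' @return list with post-operative `skin`, `bone`, `landmarks` (noisy,
#'   stage `"post"`), `landmarks_true` (noise-free), and `field` (the
#'   ground-truth displacement function).
#' @export
simulate_surgery <- function(head, params = surgery_params()) {
  stopifnot(inherits(params, "surgery_params"))
  field <- surgical_field(params)
  move <- function(x) x + field(x)
  skin <- head$skin; bone <- head$bone
  skin$vertices <- move(skin$vertices); skin$stage <- "post"
  bone$vertices <- move(bone$vertices); bone$stage <- "post"
  pre <- landmark_coords(head$landmarks)
  post_true <- move(pre)
  if (params$mandible_rotation && params$descent > 0) {
    mand <- head$landmarks$region == "mandibular"
    if (any(mand)) {
      ang <- -0.4 * params$descent * pi / 180   # degrees per mm of descent
      pivot <- c(0, 5, -25)                     # condylar (glenoid-level) axis
      Rx <- rotation_about_axis(c(1, 0, 0), ang)
      post_true[mand, ] <- sweep(sweep(post_true[mand, , drop = FALSE], 2L,
                                       pivot) %*% t(Rx), 2L, pivot, `+`)
    }
  }
  post <- post_true
  if (params$noise_sd > 0) {
    noise <- with_seed(params$seed,
      matrix(stats::rnorm(length(post), sd = params$noise_sd), ncol = 3L))
    # reference landmarks are deep anatomical structures with the highest
    # placement reliability; they are placed noise-free so frame error does
    # not contaminate the simulated surgical signal
    noise[head$landmarks$role == "reference", ] <- 0
    post <- post + noise
  }
  lms_post <- set_landmark_coords(head$landmarks, post, stage = "post")
  lms_true <- set_landmark_coords(head$landmarks, post_true, stage = "post")
  list(skin = skin, bone = bone, landmarks = lms_post,
       landmarks_true = lms_true, field = field)
}

#' Generate a synthetic patient cohort with one shared surgical field
#'
#' Draws per-patient head parameters uniformly from the given ranges,
#' simulates the shared operation on each, and returns unaligned
#' `patient_dataset`s. Fully reproducible from `(seed, n, ranges)`; each
#' patient's draw depends only on the seed and its own id, so cohort
#' generation is order-independent per patient.
#'
#' @param n number of patients (>= 2)
#' @param cohort cohort label for the datasets
#' @param ranges named list of `c(min, max)` ranges for `scale`,
#'   `turricephaly`, `brachycephaly`, `asymmetry`, `retrusion`.
#' @param surgery a [surgery_params()] object (per-patient noise seeds are
#'   derived from `seed` and the patient id).
#' @param seed master seed
#' @param n_lat,n_lon mesh resolution
#' @param ids patient identifiers
#' @return list of `patient_dataset`s; each carries the generator truth in
#'   `$truth` (`field`, `landmarks_post_true`).
#' @export
generate_cohort <- function(n = 10L, cohort = "monobloc_older",
                            ranges = list(scale = c(0.95, 1.05),
                                          turricephaly = c(0.95, 1.10),
                                          brachycephaly = c(0.90, 1.05),
                                          asymmetry = c(0, 2),
                                          retrusion = c(0, 6)),
                            surgery = surgery_params(),
                            seed = 1L, n_lat = 25L, n_lon = 36L,
                            ids = sprintf("P%03d", seq_len(n))) {
  if (n < 2L) stopf("a cohort needs at least 2 patients")
  stopifnot(length(ids) == n)
  draw <- function(rng) stats::runif(1L, rng[1L], rng[2L])
  out <- vector("list", n)
  names(out) <- ids
  if (surgery$bipartition) {
    if (!cohort %in% c("bipartition_older", "bipartition_younger"))
      cohort <- "bipartition_older"
  }
  for (i in seq_len(n)) {
    id <- ids[i]
    ps <- child_seed(seed, id)
    hp <- with_seed(ps, head_params(
      scale = draw(ranges$scale %||% c(1, 1)),
      turricephaly = draw(ranges$turricephaly %||% c(1, 1)),
      brachycephaly = draw(ranges$brachycephaly %||% c(1, 1)),
      asymmetry = draw(ranges$asymmetry %||% c(0, 0)),
      retrusion = draw(ranges$retrusion %||% c(0, 0)),
      seed = ps))
    head <- generate_head(hp, patient_id = id, n_lat = n_lat, n_lon = n_lon)
    sp <- surgery
    sp$seed <- child_seed(ps, "placement")
    post <- simulate_surgery(head, sp)
    ds <- patient_dataset(id, skin_pre = head$skin, bone_pre = head$bone,
                          landmarks_pre = head$landmarks,
                          skin_post = post$skin, bone_post = post$bone,
                          landmarks_post = post$landmarks, cohort = cohort)
    ds$truth <- list(field = post$field,
                     landmarks_post_true = post$landmarks_true,
                     head_params = hp)
    out[[i]] <- ds
  }
  out
}
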