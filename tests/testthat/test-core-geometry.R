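# Rigid transforms, closest-point queries, mesh and landmark IO.

test_that("rigid transforms apply correctly and preserve distances", {
  pts <- rbind(c(1, 0, 0), c(0, 2, 0), c(0, 0, 3))
  expect_equal(apply_rigid(rigid_transform(), pts), pts)

  Rz90 <- craniowarp:::rotation_about_axis(c(0, 0, 1), pi / 2)
  out <- apply_rigid(rigid_transform(Rz90), matrix(c(1, 0, 0), 1))
  expect_equal(as.numeric(out), c(0, 1, 0), tolerance = 1e-12)

  set.seed(11)
  tr <- craniowarp:::random_rigid_transform()
  p <- matrix(rnorm(150, sd = 30), 50, 3)
  moved <- apply_rigid(tr, p)
  expect_lt(max(abs(dist(moved) - dist(p)) / pmax(dist(p), 1)), 1e-9)

  p[3, 1] <- NaN
  expect_error(apply_rigid(tr, p), "non-finite")
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
})

test_that("rigid composition and inversion are consistent", {
  set.seed(3)
  a <- craniowarp:::random_rigid_transform()
  b <- craniowarp:::random_rigid_transform()
  p <- matrix(rnorm(30), 10, 3)
  expect_equal(apply_rigid(compose_rigid(a, b), p),
               apply_rigid(b, apply_rigid(a, p)), tolerance = 1e-9)
  expect_equal(apply_rigid(invert_rigid(a), apply_rigid(a, p)), p,
               tolerance = 1e-9)
})

test_that("closest point returns vertices and plane feet exactly", {
  m <- tetra_mesh()
  hit <- closest_point_on_mesh(m$vertices[2, ], m)
  expect_equal(hit$distance, 0)
  expect_equal(as.numeric(hit$points), m$vertices[2, ])

  tri <- flat_triangle_mesh()
  centroid <- colMeans(tri$vertices)
  hit <- closest_point_on_mesh(centroid + c(0, 0, 2), tri)
  expect_equal(hit$distance, 2, tolerance = 1e-12)
  expect_equal(as.numeric(hit$points), centroid, tolerance = 1e-12)
  expect_error(closest_point_on_mesh(c(0, 0, 0),
                                     surface_mesh(tri$vertices,
                                                  matrix(integer(), 0, 3))),
               "no faces")
})

test_that("closest point matches the brute-force oracle on random queries", {
  set.seed(21)
  mesh <- sphere_mesh(radius = 30, n_lat = 12, n_lon = 10)  # 200 faces
  expect_equal(nrow(mesh$faces), 200)
  q <- matrix(runif(300, -50, 50), 100, 3)
  hits <- closest_point_on_mesh(q, mesh)
  for (i in seq_len(nrow(q))) {
    o <- oracle_closest(q[i, ], mesh)
    expect_equal(hits$distance[i], o$distance, tolerance = 1e-10)
    expect_equal(as.numeric(hits$points[i, ]), as.numeric(o$point),
                 tolerance = 1e-8)
  }
})

test_that("distance grows monotonically along the ray away from the foot", {
  m <- tetra_mesh()
  q <- c(3, 2, 2.5)
  hit <- closest_point_on_mesh(q, m)
  dirn <- (q - as.numeric(hit$points)) / hit$distance
  d_along <- vapply(c(1, 2, 4, 8), function(s)
    closest_point_on_mesh(as.numeric(hit$points) + s * dirn, m)$distance,
    numeric(1))
  expect_true(all(diff(d_along) > 0))
})

test_that("closest-point ties resolve to the lowest face index", {
  # two parallel triangles equidistant from the origin
  v <- rbind(c(-1, -1, 1), c(1, -1, 1), c(0, 1, 1),
             c(-1, -1, -1), c(1, -1, -1), c(0, 1, -1))
  m <- surface_mesh(v, rbind(c(1, 2, 3), c(4, 5, 6)))
  hit <- closest_point_on_mesh(c(0, 0, 0), m)
  expect_equal(hit$face, 1L)
})

test_that("degenerate faces are dropped at construction", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 0, 0))
  f <- rbind(c(1, 2, 3), c(1, 2, 4))  # second face has zero area
  m <- surface_mesh(v, f)
  expect_equal(nrow(m$faces), 1L)
  expect_error(surface_mesh(v, rbind(c(1, 2, 5))), "out of range")
})

test_that("mesh IO round-trips through OBJ, PLY (ascii + binary) and STL", {
  m <- sphere_mesh(radius = 20, n_lat = 7, n_lon = 8)
  for (spec in list(c("m.obj", FALSE), c("m.ply", FALSE), c("m.ply", TRUE),
                    c("m.stl", FALSE))) {
    path <- file.path(withr::local_tempdir(), spec[[1]])
    write_mesh(m, path, binary = as.logical(spec[[2]]))
    back <- read_mesh(path)
    tol <- if (grepl("ply$", path) && as.logical(spec[[2]])) 1e-5 else 1e-6
    if (grepl("stl$", path)) {
      # STL stores per-facet vertices; welding may reorder them
      ord <- function(v) {
        r <- round(v, 6)
        r[order(r[, 1], r[, 2], r[, 3]), ]
      }
      expect_equal(ord(back$vertices), ord(m$vertices), tolerance = tol,
                   ignore_attr = TRUE)
    } else {
      expect_equal(back$vertices, m$vertices, tolerance = tol,
                   ignore_attr = TRUE)
    }
    expect_equal(nrow(back$faces), nrow(m$faces))
    # same surface: closest-point distance from read-back vertices ~ 0
    expect_lt(max(closest_point_on_mesh(back$vertices, m)$distance), 1e-3)
  }
})

test_that("landmark sets validate names, roles and units", {
  d <- data.frame(name = c("a", "b"), x = 1:2, y = 0, z = 0,
                  role = "skin", region = "nasal")
  lms <- landmark_set(d, "P1", "pre")
  expect_s3_class(lms, "landmark_set")
  expect_error(landmark_set(rbind(d, d[1, ])), "duplicate")
  d2 <- d; d2$role[1] <- "bogus"
  expect_error(landmark_set(d2), "unknown landmark role")
  d3 <- d; d3$x[1] <- Inf
  expect_error(landmark_set(d3), "non-finite")

  tmp <- withr::local_tempdir()
  write_landmarks(lms, file.path(tmp, "l.csv"))
  back <- read_landmarks(file.path(tmp, "l.csv"), "P1", "pre")
  expect_true(correspondable(lms, back))
  expect_equal(landmark_coords(back), landmark_coords(lms))

  write_landmarks(lms, file.path(tmp, "l.json"))
  back2 <- read_landmarks(file.path(tmp, "l.json"))
  expect_equal(landmark_coords(back2), landmark_coords(lms))
  expect_equal(attr(back2, "patient_id"), "P1")

  # unit metadata other than mm is rejected, not converted
  obj <- jsonlite::read_json(file.path(tmp, "l.json"), simplifyVector = TRUE)
  obj$units <- "m"
  jsonlite::write_json(obj, file.path(tmp, "bad.json"), auto_unbox = TRUE)
  expect_error(read_landmarks(file.path(tmp, "bad.json")), "units")
})

test_that("the landmark dictionary carries the full role schema", {
  d <- landmark_dictionary()
  counts <- table(d$role)
  expect_equal(counts[["skin"]], 78L)
  expect_equal(counts[["craniometric"]], 36L)
  expect_equal(counts[["bone_moving"]] + counts[["craniometric"]], 78L)
  expect_equal(counts[["bone_static"]], 7L)
  expect_equal(counts[["reference"]], 7L)
  expect_false(anyDuplicated(d$name) > 0)
  # mirror pairs are symmetric
  paired <- d[!is.na(d$pair), ]
  expect_true(all(d$pair[match(paired$pair, d$name)] == paired$name))
  # craniometric landmarks are bone landmarks (not skin)
  expect_true(all(d$region[d$role == "craniometric"] != "none"))
  expect_equal(d$name[d$role == "reference"],
               craniowarp:::REFERENCE_LANDMARK_NAMES)
  # the shipped CSV copy agrees with the programmatic dictionary
  csv <- read.csv(system.file("extdata", "landmark_dictionary.csv",
                              package = "craniowarp"),
                  stringsAsFactors = FALSE)
  expect_equal(csv, d, ignore_attr = TRUE)
})
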