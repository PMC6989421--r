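# Shared fixtures and independent oracles for the test suite.

# a regular tetrahedron mesh (4 faces)
tetra_mesh <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  surface_mesh(v, f)
}

# one large triangle in the z = 0 plane
flat_triangle_mesh <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)),
               matrix(c(1, 2, 3), 1))
}

# a canonical reference-landmark set already satisfying the frame
# postconditions (plane of 1-6 is z = 0, midpoint of 1-2 at the origin,
# crista galli on +y)
canonical_reference <- function() {
  rbind(c(45, 0, 0), c(-45, 0, 0),
        c(40, -20, 0), c(-40, -20, 0),
        c(50, 10, 0), c(-50, 10, 0),
        c(0, 60, 10))
}

# random valid reference landmarks: canonical geometry plus jitter, pushed
# through a random rigid motion
random_reference <- function(jitter = 2) {
  ref <- canonical_reference() +
    matrix(stats::rnorm(21, sd = jitter), 7, 3)
  tr <- craniowarp:::random_rigid_transform()
  list(ref = apply_rigid(tr, ref), transform = tr)
}

# independent closest-point oracle: per-triangle plane projection with
# barycentric inside test, else the best of the three clamped edge segments
oracle_closest <- function(query, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  best_d <- Inf; best_p <- NULL; best_face <- NA_integer_
  seg_closest <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab * ab)
    a + min(max(t, 0), 1) * ab
  }
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1L], ]; b <- v[f[i, 2L], ]; c_ <- v[f[i, 3L], ]
    n <- c((b - a)[2] * (c_ - a)[3] - (b - a)[3] * (c_ - a)[2],
           (b - a)[3] * (c_ - a)[1] - (b - a)[1] * (c_ - a)[3],
           (b - a)[1] * (c_ - a)[2] - (b - a)[2] * (c_ - a)[1])
    n <- n / sqrt(sum(n^2))
    foot <- query - sum((query - a) * n) * n
    # barycentric coordinates of foot
    m <- cbind(b - a, c_ - a)
    uv <- qr.solve(m, foot - a)
    cand <- if (all(uv >= 0) && sum(uv) <= 1) foot else {
      cands <- list(seg_closest(query, a, b), seg_closest(query, b, c_),
                    seg_closest(query, a, c_))
      cands[[which.min(vapply(cands, function(p) sum((query - p)^2), 0))]]
    }
    d <- sqrt(sum((query - cand)^2))
    if (d < best_d) { best_d <- d; best_p <- cand; best_face <- i }
  }
  list(point = best_p, face = best_face, distance = best_d)
}

# independent dense solve of the weighted RBF system (component-wise,
# straightforward construction, qr.solve)
oracle_rbf_solve <- function(centres, targets, variances, alpha,
                             phi = function(r) r) {
  n <- nrow(centres)
  D <- as.matrix(stats::dist(centres))
  A <- phi(D)
  diag(A) <- diag(A) - alpha * rep_len(variances, n)
  P <- cbind(1, centres)
  M <- rbind(cbind(A, P), cbind(t(P), matrix(0, 4, 4)))
  sol <- qr.solve(M, rbind(targets, matrix(0, 4, 3)))
  list(lambda = sol[1:n, , drop = FALSE], affine = sol[n + 1:4, , drop = FALSE])
}

oracle_rbf_eval <- function(fit, centres, points, phi = function(r) r) {
  D <- craniowarp:::.cross_dist_cpp(as.matrix(points), as.matrix(centres))
  phi(D) %*% fit$lambda + cbind(1, as.matrix(points)) %*% fit$affine
}

# random scattered displacement samples (non-degenerate with prob 1)
random_samples <- function(n, spread = 60, disp = 5) {
  list(centres = matrix(stats::runif(n * 3, -spread, spread), n, 3),
       targets = matrix(stats::rnorm(n * 3, sd = disp), n, 3))
}

# small aligned synthetic cohort used by several files
make_aligned_cohort <- function(n = 5, seed = 7, noise_sd = 1,
                                ranges = NULL, surgery = NULL,
                                n_lat = 17, n_lon = 24) {
  if (is.null(surgery)) surgery <- surgery_params(noise_sd = noise_sd)
  args <- list(n = n, seed = seed, surgery = surgery,
               n_lat = n_lat, n_lon = n_lon)
  if (!is.null(ranges)) args$ranges <- ranges
  co <- do.call(generate_cohort, args)
  lapply(co, align_dataset)
}

zero_ranges <- list(scale = c(1, 1), turricephaly = c(1, 1),
                    brachycephaly = c(1, 1), asymmetry = c(0, 0),
                    retrusion = c(0, 0))
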