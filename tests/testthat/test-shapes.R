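# Synthetic shape generators and their closed-form oracles.

test_that("octahedron combinatorics follow the subdivision arithmetic", {
  oc0 <- make_octahedron(0)
  expect_equal(nrow(oc0$vertices), 6L)
  expect_equal(nrow(oc0$faces), 8L)
  for (k in 0:3) {
    oc <- make_octahedron(k)
    expect_equal(nrow(oc$faces), 8L * 4L^k)
    expect_equal(nrow(oc$vertices), 4L * 4L^k + 2L)
  }
  oct <- make_octahedron(target_vertices = 20000)
  expect_lt(abs(nrow(oct$vertices) - 20000) / 20000, 0.02)
})

test_that("every equatorial dihedral of the octahedron is exactly arccos(-1/3)", {
  oc <- make_octahedron(3)
  fn <- face_normals(oc)
  f <- oc$faces
  v <- oc$vertices
  # equator edges: both endpoints at z == 0; find their two incident faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fid <- rep(seq_len(nrow(f)), 3L)
  on_eq <- v[he[, 1], 3] == 0 & v[he[, 2], 3] == 0
  key <- paste(pmin(he[on_eq, 1], he[on_eq, 2]), pmax(he[on_eq, 1], he[on_eq, 2]))
  fids <- split(fid[on_eq], key)
  fids <- fids[vapply(fids, length, 1L) == 2L]
  expect_gt(length(fids), 0L)
  target <- acos(-1 / 3) * 180 / pi
  for (pr in fids) {
    cosang <- sum(fn[pr[1], ] * fn[pr[2], ])
    dihedral <- 180 - acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    expect_equal(dihedral, target, tolerance = 1e-6)
  }
})

test_that("lens oracle half-angles match a finite-difference tangent at the rim", {
  for (p in list(c(0.5, 0.5, 0.25), c(0.4, 0.8, 0.32), c(0.5, 0.5, 0.433))) {
    R_up <- p[1]; R_dn <- p[2]; a <- p[3]
    o <- make_lens(R_up, R_dn, a, 500)$oracle
    eps <- 1e-9
    zcap <- function(R, r) sqrt(R^2 - r^2) - sqrt(R^2 - a^2)
    slope_up <- (zcap(R_up, a - eps) - zcap(R_up, a)) / eps
    slope_dn <- (zcap(R_dn, a - eps) - zcap(R_dn, a)) / eps
    half_num <- c(atan(slope_up), atan(slope_dn)) * 180 / pi
    expect_equal(unname(o$half_angles), half_num, tolerance = 1e-5)
    expect_equal(o$edge_angle, sum(half_num), tolerance = 1e-5)
  }
  expect_equal(make_lens(0.5, 0.5, 0.5 * sqrt(0.75), 500)$oracle$edge_angle,
               120, tolerance = 1e-9)
  expect_equal(make_lens(0.5, 0.5, 0.25, 500)$oracle$edge_angle,
               60, tolerance = 1e-9)
  expect_error(make_lens(0.5, 0.5, 0.6, 500), "infeasible")
})

test_that("generated solids are watertight with outward orientation", {
  shapes <- list(make_lens(0.5, 0.5, 0.4, 3000)$mesh,
                 make_blunt_lens(0.5, 0.35, 0.25, 0.06, 5000)$mesh,
                 make_cylinder(0.3, 0.4, 3000)$mesh,
                 make_bowl_top(0.4, 1.2, 0.5, 5000)$mesh,
                 make_octahedron(target_vertices = 2000),
                 make_sphere(1, 2000))
  for (m in shapes) {
    expect_gt(mesh_volume(m), 0)
    e <- rbind(m$faces[, c(1, 2)], m$faces[, c(2, 3)], m$faces[, c(3, 1)])
    cnt <- table(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
    expect_true(all(cnt == 2L))   # closed 2-manifold
  }
})

test_that("generators are deterministic and hit their target count", {
  a <- make_lens(0.4, 0.8, 0.32, 20000)
  b <- make_lens(0.4, 0.8, 0.32, 20000)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$faces, b$mesh$faces)
  expect_lt(abs(nrow(a$mesh$vertices) - 20000) / 20000, 0.02)
  s1 <- make_sphere(2, 5000)
  expect_equal(unname(ceam:::row_norms(s1$vertices)), rep(2, nrow(s1$vertices)),
               tolerance = 1e-9)
})

test_that("piecewise signals are deterministic with faithful block structure", {
  exact <- make_piecewise_signal(c(60, 150), c(100, 100), 0)
  expect_identical(exact$signal, c(rep(60, 100), rep(150, 100)))
  expect_equal(exact$truth$breakpoints, 100)

  s1 <- make_piecewise_signal(c(60, 150), c(100, 100), 2, seed = 7)
  s2 <- make_piecewise_signal(c(60, 150), c(100, 100), 2, seed = 7)
  expect_identical(s1$signal, s2$signal)
  expect_lt(abs(mean(s1$signal[1:100]) - 60), 3 * 2 / sqrt(100))

  single <- make_piecewise_signal(90, 50, 1, seed = 1)
  expect_length(single$truth$breakpoints, 0L)
  expect_error(make_piecewise_signal(c(1, 2), 5, 1), "equal length")

  # generator does not disturb the session RNG
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(make_piecewise_signal(90, 10, 1, seed = 9)); after <- runif(1)
  expect_identical(before, after)
})

test_that("blunt lens parameters are validated", {
  expect_error(make_blunt_lens(0.5, 0.35, 0, 0.06), "band fraction")
  expect_error(make_blunt_lens(0.5, 0.35, 1.2, 0.06), "band fraction")
  expect_error(make_blunt_lens(0.5, 0.35, 0.25, -1), "band_height")
  expect_error(make_blunt_lens(0.5, 0.35, 0.25, 1), "too large")
})
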