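# Outline detection: alpha-shape boundary, z lift, blunt correction,
# resampling to 1000 uniformly spaced coordinates.

test_that("lens boundary is the rim circle and lifts to z = 0", {
  a <- 0.4
  ln <- make_lens(0.5, 0.5, a, 20000)
  om <- orient_artifact(ln$mesh, diag(3))   # unscaled: rim radius stays 0.4
  b <- suppressWarnings(project_boundary(om))
  r <- sqrt(rowSums(b$polygon^2))
  expect_lt(max(abs(r - a)), 0.01)
  raw <- lift_boundary(om, b)
  expect_lt(max(abs(raw$coords[, 3])), 0.01)
})

test_that("octahedron boundary passes through the equatorial square corners", {
  oc <- make_octahedron(target_vertices = 20000)
  om <- orient_artifact(oc, diag(3))
  b <- suppressWarnings(project_boundary(om))
  corners <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  for (i in 1:4) {
    d <- sqrt(rowSums((b$polygon - matrix(corners[i, ], nrow(b$polygon), 2,
                                          byrow = TRUE))^2))
    expect_lt(min(d), 1e-9)
  }
})

test_that("alpha of infinity reduces the boundary to the convex hull", {
  ln <- make_lens(0.5, 0.5, 0.4, 5000)
  om <- orient_artifact(ln$mesh, diag(3))
  b <- suppressWarnings(project_boundary(om, alpha = Inf))
  v <- om$mesh$vertices
  hull <- grDevices::chull(v[, 1], v[, 2])
  hull_poly <- v[hull, 1:2, drop = FALSE]
  area_hull <- abs(sum(hull_poly[, 1] * c(hull_poly[-1, 2], hull_poly[1, 2]) -
                         c(hull_poly[-1, 1], hull_poly[1, 1]) * hull_poly[, 2]) / 2)
  area_b <- abs(sum(b$polygon[, 1] * c(b$polygon[-1, 2], b$polygon[1, 2]) -
                      c(b$polygon[-1, 1], b$polygon[1, 1]) * b$polygon[, 2]) / 2)
  # sub-spacing point collapsing may drop individual hull vertices, so the
  # areas agree to resolution rather than exactly
  expect_equal(area_b, area_hull, tolerance = 1e-3)
})

test_that("degenerate projections are rejected", {
  flat <- tri_mesh(cbind(seq(0, 1, length.out = 6), 0.0, runif(6)),
                   rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5), c(4, 5, 6)))
  om <- structure(list(mesh = flat, rotation = diag(3), auto = FALSE,
                       ambiguous = FALSE, scale = 1), class = "oriented_mesh")
  expect_error(suppressWarnings(project_boundary(om)), "degenerate projection")
})

test_that("blunt correction recenters band z, flags the band, and never touches x-y", {
  a <- 0.5 * sqrt(1 - 0.7^2)
  bl <- make_blunt_lens(0.5, a, f = 0.25, band_height = 0.06, n = 20000)
  om <- rescale_mesh(orient_artifact(bl$mesh, diag(3)))
  b <- suppressWarnings(project_boundary(om))
  raw <- lift_boundary(om, b)
  corrected <- correct_blunt_regions(om, raw, 20, 50)
  expect_identical(corrected$coords[, 1:2], raw$coords[, 1:2])  # bit-level
  expect_true(any(corrected$blunt_flag))
  expect_lt(max(abs(corrected$coords[corrected$blunt_flag, 3])), 0.02)
  # pre-correction z fluctuates within +/- half the band height
  h_scaled <- 0.06 * om$scale
  band_z_raw <- raw$coords[corrected$blunt_flag, 3]
  expect_lt(max(abs(band_z_raw)), h_scaled / 2 + 1e-6)
  expect_gt(max(abs(band_z_raw)), 0.05 * h_scaled)
})

test_that("blunt correction is the identity on a fully sharp lens", {
  ln <- make_lens(0.5, 0.5, 0.4, 15000)   # 106 deg edge: no vertical surface
  om <- rescale_mesh(orient_artifact(ln$mesh, diag(3)))
  raw <- lift_boundary(om, suppressWarnings(project_boundary(om)))
  corrected <- correct_blunt_regions(om, raw, 20, 50)
  expect_false(any(corrected$blunt_flag))
  expect_identical(corrected$coords, raw$coords)
})

test_that("a cylinder is blunt everywhere with z corrected to mid-height", {
  cy <- make_cylinder(0.35, 0.5, 15000)
  om <- rescale_mesh(orient_artifact(cy$mesh, diag(3)))
  out <- suppressWarnings(detect_outline(om))
  expect_true(all(out$blunt_flag))
  expect_lt(max(abs(out$coords[, 3])), 0.02)
})

test_that("resampling yields 1000 uniform coordinates starting at the tip, CCW", {
  square <- structure(list(
    coords = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0),
    vertex_index = 1:4, blunt_flag = rep(FALSE, 4)), class = "raw_outline")
  out <- resample_outline(square, 1000)
  expect_equal(nrow(out$coords), 1000L)
  expect_equal(outline_perimeter(out), 4, tolerance = 1e-6)
  gaps <- sqrt(rowSums(diff(rbind(out$coords, out$coords[1, ]))^2))
  expect_lt(stats::sd(gaps) / mean(gaps), 0.05)
  expect_equal(out$coords[1, 2], max(out$coords[, 2]))   # tip start
  # counter-clockwise in plan view
  x <- out$coords[, 1]; y <- out$coords[, 2]
  expect_gt(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2, 0)
  expect_equal(out$plan_centroid, c(0.5, 0.5), tolerance = 1e-6)
})

test_that("a dense circle resamples to the analytic circumference", {
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  circ <- structure(list(coords = cbind(0.4 * cos(th), 0.4 * sin(th), 0),
                         vertex_index = seq_along(th),
                         blunt_flag = rep(FALSE, length(th))),
                    class = "raw_outline")
  out <- resample_outline(circ, 1000)
  expect_equal(outline_perimeter(out), 2 * pi * 0.4, tolerance = 0.001 * 2 * pi * 0.4)
})

test_that("open or self-intersecting inputs are rejected", {
  bowtie <- structure(list(
    coords = cbind(c(0, 1, 1, 0), c(0, 1, 0, 1), 0),
    vertex_index = 1:4, blunt_flag = rep(FALSE, 4)), class = "raw_outline")
  expect_error(resample_outline(bowtie), "self-intersecting")
  tiny <- structure(list(coords = cbind(c(0, 1, 0), c(0, 0, 1), 0),
                         vertex_index = 1:3, blunt_flag = rep(FALSE, 3)),
                    class = "raw_outline")
  expect_error(resample_outline(tiny), "at least 4")
})

test_that("outline exports write CSV and OBJ polylines", {
  ln <- make_lens(0.5, 0.5, 0.4, 8000)
  out <- suppressWarnings(detect_outline(rescale_mesh(orient_artifact(ln$mesh, diag(3)))))
  pc <- tempfile(fileext = ".csv")
  outline_to_csv(out, pc)
  df <- utils::read.csv(pc)
  expect_equal(nrow(df), 1000L)
  expect_named(df, c("index", "x", "y", "z", "arc_pos", "blunt_flag"))
  po <- tempfile(fileext = ".obj")
  outline_to_obj(out, po)
  expect_true(any(startsWith(readLines(po), "l ")))
})
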