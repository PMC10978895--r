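# Continuous edge angle measurement: face assignment, per-vertex angles,
# outer band, KDE-mode aggregation, convergence with band size.

test_that("three-point angle formula is exact on a crafted configuration", {
  # v and o mirror images separated by 60 degrees, measured at e
  e <- matrix(c(0, 0, 0), 1)
  v <- matrix(c(cos(pi / 6), 0, sin(pi / 6)), 1)
  o <- matrix(c(cos(pi / 6), 0, -sin(pi / 6)), 1)
  a <- v - e; b <- o - e
  ang <- atan2(ceam:::row_norms(ceam:::cross3(a, b)), sum(a * b)) * 180 / pi
  expect_equal(ang, 60, tolerance = 1e-6)
  # opposite collinear vectors read 180
  b2 <- -a
  ang2 <- atan2(ceam:::row_norms(ceam:::cross3(a, b2)), sum(a * b2)) * 180 / pi
  expect_equal(ang2, 180, tolerance = 1e-6)
})

test_that("face assignment splits a lens into caps and a boundary ring", {
  st <- fixture("lens5_chain", function() {
    run_stage_chain(make_lens(0.5, 0.5, 0.4, 20000)$mesh)
  })
  tab <- table(st$faces)
  expect_gt(tab[["upper"]], 0.4 * sum(tab))
  expect_gt(tab[["lower"]], 0.4 * sum(tab))
  expect_lt(abs(tab[["upper"]] - tab[["lower"]]) / sum(tab), 0.02)
  up_z <- st$om$mesh$vertices[st$faces == "upper", 3]
  expect_true(all(up_z > 0))
})

test_that("a flat patch cannot be divided into two faces", {
  patch <- heightfield_patch(function(x, y) 0 * x, w = 0.5, m = 12)
  om <- structure(list(mesh = patch, rotation = diag(3), auto = FALSE,
                       ambiguous = FALSE, scale = 1), class = "oriented_mesh")
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  fake_outline <- structure(list(coords = cbind(0.45 * cos(th), 0.45 * sin(th), 0),
                                 arc_pos = seq_along(th), blunt_flag = rep(FALSE, 100),
                                 plan_centroid = c(0, 0)), class = "outline3d")
  expect_error(assign_faces(om, fake_outline), "face is empty")
})

test_that("the outer band hits the requested area fraction", {
  st <- fixture("lens5_chain", function() {
    run_stage_chain(make_lens(0.5, 0.5, 0.4, 20000)$mesh)
  })
  full <- outer_band(st$om, st$outline, 1)
  expect_true(all(full))
  b20 <- outer_band(st$om, st$outline, 0.2)
  expect_gte(attr(b20, "area_fraction"), 0.19)
  expect_lte(attr(b20, "area_fraction"), 0.21)
  # the band is an annulus near the rim: all band vertices far from the axis
  r <- sqrt(rowSums(st$om$mesh$vertices[b20, 1:2, drop = FALSE]^2))
  expect_gt(min(r), 0.25)
  expect_error(outer_band(st$om, st$outline, 0), "fraction")
  # a tiny band still yields a defined profile (median fallback path)
  b_tiny <- outer_band(st$om, st$outline, 0.001)
  expect_gt(sum(b_tiny), 0)
  prof <- suppressMessages(ceam_profile(st$va, st$om, st$outline, b_tiny, k = 100))
  expect_true(all(is.finite(prof$angle)))
})

test_that("KDE mode rejects outliers and resolves ties to the lowest angle", {
  expect_equal(kde_mode(c(rep(60, 99), 179), 0, 180, 0.1, 1), 60)
  # 1% outliers move the aggregate by < 0.5 degrees
  set.seed(3)
  base <- rnorm(99, 91, 1.5)
  expect_lt(abs(kde_mode(c(base, 180), 0, 180, 0.1, 1) -
                  kde_mode(base, 0, 180, 0.1, 1)), 0.5)
  # symmetric bimodal: exact tie resolves to the lower mode
  expect_lt(kde_mode(c(rep(60, 50), rep(120, 50)), 0, 180, 0.1, 1), 90)
})

test_that("lens profiles recover the analytic dihedral", {
  st <- fixture("lens5_chain", function() {
    run_stage_chain(make_lens(0.5, 0.5, 0.4, 20000)$mesh)
  })
  truth <- 2 * asin(0.4 / 0.5) * 180 / pi   # 106.26
  expect_lt(abs(mean(st$profile$angle) - truth), 2.5)
  expect_true(all(st$profile$angle > 0 & st$profile$angle < 180))
  expect_length(st$profile$angle, 1000L)
})

test_that("profiles are scale-invariant after renormalization", {
  a <- 0.4
  ln <- make_lens(0.5, 0.5, a, 15000)
  big <- tri_mesh(ln$mesh$vertices * 10, ln$mesh$faces)
  p1 <- run_stage_chain(ln$mesh)$profile
  p2 <- run_stage_chain(big)$profile
  expect_lt(max(abs(p1$angle - p2$angle)), 0.1)
})

test_that("rotating the artifact about z leaves the profile invariant up to a cyclic shift", {
  ln <- make_lens(0.5, 0.5, 0.4, 15000)
  th <- 37 * pi / 180
  rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, byrow = TRUE)
  p1 <- run_stage_chain(ln$mesh)$profile
  p2 <- run_stage_chain(tri_mesh(ln$mesh$vertices %*% t(rz), ln$mesh$faces))$profile
  expect_lt(aligned_max_diff(p1$angle, p2$angle), 1)
})

test_that("the mean angle converges once the band exceeds ~10% of the surface", {
  st <- fixture("lens5_chain", function() {
    run_stage_chain(make_lens(0.5, 0.5, 0.4, 20000)$mesh)
  })
  conv <- suppressMessages(band_convergence(st$om, st$outline,
                                            fractions = c(0.05, 0.10, 0.15, 0.20, 0.25)))
  plateau <- conv$mean_angle[conv$fraction >= 0.10]
  expect_lt(max(plateau) - min(plateau), 1)
  # a single-fraction call equals the standard profile mean
  one <- suppressMessages(band_convergence(st$om, st$outline, fractions = 0.2))
  expect_equal(one$mean_angle, mean(st$profile$angle), tolerance = 1e-9)
})
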