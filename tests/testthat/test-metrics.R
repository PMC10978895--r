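# Segment metrics: sharp threshold, classification, asymmetry, concavity,
# refinement, report assembly.

test_that("the pooled-angle trough splits a bimodal assemblage", {
  set.seed(5)
  x <- c(rnorm(500, 80, 10), rnorm(500, 150, 10))
  st <- sharp_threshold(x)
  expect_false(st$unimodal)
  expect_gte(st$trough, 105)
  expect_lte(st$trough, 125)
  expect_equal(st$rounded, floor(st$trough / 10) * 10)
  # oracle: brute-force argmin of the same KDE between the two modes
  bw <- max(stats::bw.nrd0(x), 2)
  d <- stats::density(x, bw = bw, from = 0, to = 180, n = 1801)
  lo <- which.min(abs(d$x - st$modes[1]))
  hi <- which.min(abs(d$x - st$modes[2]))
  expect_equal(st$trough, d$x[lo + which.min(d$y[lo:hi]) - 1L])
})

test_that("unimodal samples fall back to the 120-degree default", {
  set.seed(6)
  st <- sharp_threshold(rnorm(200, 90, 10))
  expect_true(st$unimodal)
  expect_equal(st$threshold, 120)
  expect_error(sharp_threshold(rnorm(10, 90, 5)), "at least 30")
})

test_that("segments classify sharp strictly below the threshold", {
  seg <- list(segment_means = c(65, 100, 160))
  expect_equal(classify_segments(seg, 120), c(TRUE, TRUE, FALSE))
  expect_false(classify_segments(list(segment_means = 120), 120))  # tie is blunt
})

test_that("percent sharp is a perimeter-weighted partition and monotone in threshold", {
  st <- fixture("lens7_small", function() {
    run_stage_chain(make_blunt_lens(0.5, 0.5 * sqrt(1 - 0.7^2), 0.25, 0.06, 20000)$mesh)
  })
  sp <- segment_profile(st$profile, 10, 25)
  lens_sum <- sum(ceam:::segment_arc_lengths(sp, st$outline))
  expect_equal(lens_sum, outline_perimeter(st$outline), tolerance = 1e-6)
  pct <- vapply(c(60, 100, 120, 175, 181), function(thr) {
    percent_sharp(st$outline, sp, classify_segments(sp, thr))
  }, 0)
  expect_true(all(diff(pct) >= 0))
  expect_equal(pct[5], 100)
  expect_equal(percent_sharp(st$outline, sp, rep(TRUE, length(sp$segment_means))), 100)
})

test_that("transverse asymmetry reads ~1 on mirror-symmetric lenses", {
  st <- fixture("lens_sym_asym", function() {
    run_stage_chain(make_lens(0.5, 0.5, 0.4, 20000)$mesh)
  })
  asym <- transverse_asymmetry_profile(st$om, st$outline, st$faces, st$band, k = 100)
  expect_gte(min(asym), 0.9)
  expect_true(all(asym <= 1))
})

test_that("asymmetric caps recover the arcsin half-angle ratio", {
  st <- fixture("lens_a32", function() {
    run_stage_chain(make_lens(0.4, 0.8, 0.32, 20000)$mesh)
  })
  oracle <- asin(0.32 / 0.4) / asin(0.32 / 0.8)   # ratio of half-angles
  expect_equal(unname(make_lens(0.4, 0.8, 0.32, 500)$oracle$asymmetry),
               1 / oracle, tolerance = 1e-9)
  asym <- transverse_asymmetry_profile(st$om, st$outline, st$faces, st$band, k = 100)
  expect_lt(abs(mean(asym) - 1 / oracle), 0.05)
  # mirror through the x-y plane: min/max ratio is face-order free
  mir <- tri_mesh(cbind(st$om$mesh$vertices[, 1:2], -st$om$mesh$vertices[, 3]),
                  st$om$mesh$faces)
  stm <- run_stage_chain(mir)
  asym_m <- transverse_asymmetry_profile(stm$om, stm$outline, stm$faces, stm$band, k = 100)
  expect_lt(abs(mean(asym_m) - mean(asym)), 0.02)
})

test_that("a plano-convex form is maximally asymmetric near the rim", {
  pc <- make_plano_convex(0.4, 0.462, 20000)
  st <- run_stage_chain(pc$mesh)
  asym <- transverse_asymmetry_profile(st$om, st$outline, st$faces, st$band, k = 100)
  expect_lt(mean(asym), 0.15)
})

test_that("vertex concavity separates convex, planar, and concave surfaces", {
  sph <- orient_artifact(make_sphere(1, 8000), diag(3))
  cv_sphere <- vertex_concavity(sph, k = 60, outer_m = 20)
  expect_gte(min(cv_sphere), 0.95)

  plane <- heightfield_patch(function(x, y) 0 * x, w = 0.5, m = 40)
  op <- structure(list(mesh = plane, rotation = diag(3), auto = FALSE,
                       ambiguous = FALSE, scale = 1), class = "oriented_mesh")
  cv_plane <- vertex_concavity(op, k = 60, outer_m = 20)
  expect_lt(max(abs(cv_plane - 0.5)), 0.05)

  bowl <- heightfield_patch(function(x, y) x^2 + y^2, w = 0.5, m = 40)
  ob <- structure(list(mesh = bowl, rotation = diag(3), auto = FALSE,
                       ambiguous = FALSE, scale = 1), class = "oriented_mesh")
  cv_bowl <- vertex_concavity(ob, k = 60, outer_m = 20)
  expect_lte(max(cv_bowl), 0.1)

  # scale invariance
  big <- structure(list(mesh = tri_mesh(bowl$vertices * 10, bowl$faces),
                        rotation = diag(3), auto = FALSE, ambiguous = FALSE,
                        scale = 1), class = "oriented_mesh")
  expect_lt(max(abs(vertex_concavity(big, 60, 20) - cv_bowl)), 0.01)
})

test_that("face concavity profiles label bowl-topped forms concave-convex", {
  st <- fixture("bowl_chain", function() {
    run_stage_chain(make_bowl_top(0.4, 1.2, 0.5, 20000)$mesh)
  })
  conc <- vertex_concavity(st$om, 60, 20, faces = st$faces)
  pair <- face_concavity_profile(conc, st$om, st$outline, st$faces, st$band, k = 100)
  expect_lt(mean(pair[, "upper"], na.rm = TRUE), 0.2)
  expect_gt(mean(pair[, "lower"], na.rm = TRUE), 0.9)
  expect_equal(concavity_label(c(mean(pair[, 1], na.rm = TRUE),
                                 mean(pair[, 2], na.rm = TRUE))), "concave-convex")
})

test_that("concavity labels use cutoffs and face-order-free naming", {
  expect_equal(concavity_label(c(0.2, 0.9)), "concave-convex")
  expect_equal(concavity_label(c(0.9, 0.2)), "concave-convex")
  expect_equal(concavity_label(c(0.5, 0.5)), "planar-planar")
  expect_equal(concavity_label(c(0.41, 0.39)), "concave-planar")
})

test_that("refinement is width over thickness and survives rescaling", {
  sp <- make_sphere(1, 4000)
  m <- tri_mesh(sp$vertices %*% diag(c(0.3, 0.5, 0.15)), sp$faces)
  om <- orient_artifact(m, diag(3))
  expect_equal(refinement(om), 2, tolerance = 1e-6)
  expect_equal(refinement(rescale_mesh(om)), 2, tolerance = 1e-6)
})

test_that("the artifact report assembles per-segment rows and totals", {
  st <- fixture("lens7_small", function() {
    run_stage_chain(make_blunt_lens(0.5, 0.5 * sqrt(1 - 0.7^2), 0.25, 0.06, 20000)$mesh)
  })
  sp <- segment_profile(st$profile, 10, 25)
  asym <- transverse_asymmetry_profile(st$om, st$outline, st$faces, st$band, 100)
  conc <- vertex_concavity(st$om, 60, 20, faces = st$faces)
  pair <- face_concavity_profile(conc, st$om, st$outline, st$faces, st$band, 100)
  rep_ <- build_report("blunt-lens", st$om, st$outline, st$profile, sp, asym, pair)
  expect_s3_class(rep_, "artifact_report")
  expect_equal(rep_$n_segments, sp$chosen_k + 1L)
  expect_lte(rep_$n_sharp_edges, rep_$n_segments)
  expect_gte(rep_$percent_sharp_perimeter, 0)
  expect_lte(rep_$percent_sharp_perimeter, 100)
  expect_equal(sum(rep_$segments$arc_length), outline_perimeter(st$outline),
               tolerance = 1e-6)
  expect_error(build_report("x", st$om, st$outline, NULL, sp, asym, pair),
               "missing stage")
})
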