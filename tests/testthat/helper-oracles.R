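# Shared oracles and fixture builders. Everything is generated in code;
# heavyweight meshes are memoized per test file run.

# Exhaustive change-point search: the independent oracle for the dynamic
# program. Prefix sums keep it fast enough for lengths up to ~30.
brute_breakpoints <- function(x, K, min_seg) {
  n <- length(x)
  s1 <- c(0, cumsum(x)); s2 <- c(0, cumsum(x^2))
  sse <- function(i, j) s2[j + 1] - s2[i] - (s1[j + 1] - s1[i])^2 / (j - i + 1)
  best <- list(residual = Inf, breakpoints = NULL)
  combs <- utils::combn(seq_len(n - 1L), K)
  for (ci in seq_len(ncol(combs))) {
    bp <- combs[, ci]
    bounds <- c(0L, bp, n)
    if (any(diff(bounds) < min_seg)) next
    r <- sum(vapply(seq_len(K + 1L), function(s) sse(bounds[s] + 1L, bounds[s + 1L]), 0))
    if (r < best$residual - 1e-12) best <- list(residual = r, breakpoints = bp)
  }
  best
}

# Piecewise signal with alternating-sign shifts (the sharp/blunt alternation
# pattern of biface perimeters): the study condition for elbow recovery.
recovery_signal <- function(seed, sd = 3) {
  set.seed(seed)
  K <- sample(0:5, 1)
  base <- floor(1000 / (K + 1))
  lens <- pmax(50L, round(base * runif(K + 1, 0.8, 1.2)))
  lens[K + 1] <- lens[K + 1] + 1000L - sum(lens)
  mns <- numeric(K + 1)
  mns[1] <- runif(1, 60, 100)
  if (K > 0) for (j in 2:(K + 1)) {
    mns[j] <- mns[j - 1] + (-1)^j * runif(1, 5, 10) * sd
  }
  sig <- make_piecewise_signal(mns, lens, sd, seed + 1000L)
  list(K = K, breakpoints = sig$truth$breakpoints, signal = sig$signal)
}

# Rectangular height-field patch z = f(x, y) on [-w, w]^2, triangulated with
# upward-consistent winding (normals +z for a flat patch).
heightfield_patch <- function(f, w = 0.5, m = 40) {
  g <- seq(-w, w, length.out = m)
  pts <- expand.grid(x = g, y = g)
  v <- cbind(pts$x, pts$y, f(pts$x, pts$y))
  idx <- function(i, j) (j - 1L) * m + i
  i <- rep(seq_len(m - 1L), m - 1L)
  j <- rep(seq_len(m - 1L), each = m - 1L)
  faces <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i, j + 1L)),
                 cbind(idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  tri_mesh(v, faces)
}

# Memoized heavyweight fixtures (built once per test file process).
.fix <- new.env(parent = emptyenv())
fixture <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- suppressWarnings(suppressMessages(build()))
  .fix[[name]]
}

# Small-size pipeline configuration used by orchestration tests.
small_config <- function(...) {
  ceam_config(target_vertices = 6000, outline_points = 400, k_profile = 60,
              k_blunt = 30, kmax = 5, min_seg = 20, concavity_k = 40,
              concavity_outer_m = 15, ...)
}

run_stage_chain <- function(mesh, n_outline = 1000, fraction = 0.2, k = 100) {
  om <- rescale_mesh(orient_artifact(mesh, diag(3)))
  outline <- suppressWarnings(detect_outline(om, n = n_outline))
  faces <- assign_faces(om, outline)
  va <- vertex_edge_angles(om, outline, faces)
  band <- outer_band(om, outline, fraction)
  profile <- suppressMessages(ceam_profile(va, om, outline, band, k = k))
  list(om = om, outline = outline, faces = faces, va = va, band = band,
       profile = profile)
}

# Best circular alignment of two profiles; returns the minimal point-wise
# maximum absolute difference over all shifts.
aligned_max_diff <- function(a, b) {
  n <- length(a)
  best <- Inf
  for (s in 0:(n - 1L)) {
    d <- max(abs(a - b[(seq_len(n) + s - 1L) %% n + 1L]))
    if (d < best) best <- d
  }
  best
}
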