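# Parametric test shapes with closed-form ground truth. Every generator is
# deterministic given its parameters (and seed, where noise is involved), so
# each pipeline stage can be validated without external scan data.
#
# The lens family is a solid of two spherical caps sharing a rim circle of
# radius a at z = 0. The tangent of the upper cap at the rim makes an angle
# arcsin(a / R_up) with the x-y plane (and likewise below), so the rim
# dihedral is arcsin(a/R_up) + arcsin(a/R_down) -- for equal caps,
# 2*arccos(c/R) with c = sqrt(R^2 - a^2).

# Generic solid of revolution on a structured grid. profile_fun(theta)
# returns an M x 2 matrix of (r, z) rows ordered from just below the top
# pole to just above the bottom pole; poles are added as single vertices.
revolve_grid <- function(profile_fun, n_theta, z_top, z_bot) {
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  profs <- lapply(theta, profile_fun)
  M <- nrow(profs[[1L]])
  verts <- matrix(NA_real_, 2L + n_theta * M, 3L)
  verts[1L, ] <- c(0, 0, z_top)
  verts[2L, ] <- c(0, 0, z_bot)
  for (i in seq_len(n_theta)) {
    pr <- profs[[i]]
    rows <- 2L + (i - 1L) * M + seq_len(M)
    # slight deterministic azimuthal stagger and radial perturbation break
    # the exact cocircularity of a perfect revolution grid
    th <- theta[i] + (pi / n_theta) * 0.3 * sin(3.7 * i + 1.3)
    # perturbation depends on (azimuth, |z|) only, so coincident degenerate
    # rows stay coincident and mirror-symmetric rows stay exact duplicates
    # in plan view (both collapse cleanly later)
    r <- pr[, 1] * (1 + 2e-4 * sin(7.3 * i + 211.7 * abs(pr[, 2])))
    verts[rows, ] <- cbind(r * cos(th), r * sin(th), pr[, 2])
  }
  g <- function(i, j) 2L + ((i - 1L) %% n_theta) * M + j
  i <- rep(seq_len(n_theta), each = M - 1L)
  j <- rep(seq_len(M - 1L), times = n_theta)
  quads1 <- cbind(g(i, j), g(i, j + 1L), g(i + 1L, j))
  quads2 <- cbind(g(i + 1L, j), g(i, j + 1L), g(i + 1L, j + 1L))
  ii <- seq_len(n_theta)
  fan_top <- cbind(1L, g(ii, 1L), g(ii + 1L, 1L))
  fan_bot <- cbind(2L, g(ii + 1L, M), g(ii, M))
  faces <- rbind(fan_top, quads1, quads2, fan_bot)
  clean_mesh(tri_mesh(verts, faces), quiet = TRUE)
}

# Solve for the azimuth count that lands the cleaned vertex count near the
# target (the grid is linear in n_theta; collapsed rows make it only
# approximately so).
calibrate_revolve <- function(build, n_theta0, target, passes = 3L) {
  n_theta <- n_theta0
  mesh <- build(n_theta)
  for (p in seq_len(passes)) {
    cnt <- nrow(mesh$vertices)
    if (abs(cnt - target) <= 0.015 * target) break
    n_theta <- max(16L, as.integer(round(n_theta * target / cnt)))
    mesh <- build(n_theta)
  }
  mesh
}

# Halton low-discrepancy sequence (radical inverse): deterministic
# quasi-uniform sampling without touching the RNG state.
halton <- function(i, base) {
  f <- rep(1, length(i)); r <- rep(0, length(i))
  k <- i
  while (any(k > 0)) {
    f <- f / base
    r <- r + f * (k %% base)
    k <- k %/% base
  }
  r
}

# Triangulate a spherical cap sampled quasi-uniformly by area, sharing a
# pre-built rim ring. Returns vertices (rim excluded) and faces indexed
# with rim vertices 1..n_rim and interior vertices offset0+1, ... The cap
# surface is a height field over the plan view, so a 2D Delaunay of the
# projected points is a valid surface triangulation.
triangulate_cap <- function(R, a, n_interior, rim_xy, offset0, halton_skip) {
  phim <- asin(a / R)
  cc <- sqrt(R^2 - a^2)
  ii <- halton_skip + seq_len(n_interior)
  th <- 2 * pi * halton(ii, 2)
  # area-uniform in the cap: F(phi) = (1 - cos phi) / (1 - cos phim)
  phi <- acos(1 - halton(ii, 3) * (1 - cos(phim)))
  r <- R * sin(phi)
  pts <- cbind(r * cos(th), r * sin(th))
  z <- R * cos(phi) - cc
  all_xy <- rbind(rim_xy, pts)
  tm <- interp::tri.mesh(all_xy[, 1], all_xy[, 2])
  tri <- interp::triangles(tm)[, 1:3, drop = FALSE]
  # counter-clockwise in plan view -> outward (+z) normals for an upper cap
  a1 <- all_xy[tri[, 1], ]; b1 <- all_xy[tri[, 2], ]; c1 <- all_xy[tri[, 3], ]
  cw <- (b1[, 1] - a1[, 1]) * (c1[, 2] - a1[, 2]) -
    (b1[, 2] - a1[, 2]) * (c1[, 1] - a1[, 1]) < 0
  tri[cw, ] <- tri[cw, c(1L, 3L, 2L), drop = FALSE]
  n_rim <- nrow(rim_xy)
  remap <- c(seq_len(n_rim), offset0 + seq_len(n_interior))
  list(vertices = cbind(pts, z), faces = matrix(remap[tri], ncol = 3L))
}

#' Biconvex lens with known rim dihedral
#'
#' Two spherical caps (radii `R_up`, `R_down`) sharing the rim circle of
#' radius `a` at z = 0. Cap surfaces are sampled quasi-uniformly by area
#' (deterministic Halton sequence) and triangulated, emulating the
#' irregular vertex placement of a real structured-light scan rather than
#' an artificial revolution grid. The oracle record carries the closed-form
#' edge angle `arcsin(a/R_up) + arcsin(a/R_down)` (degrees), the two
#' half-angles, and their min/max ratio (transverse asymmetry).
#'
#' @param R_up,R_down cap sphere radii (same units as `a`).
#' @param a rim radius; must satisfy `a < min(R_up, R_down)`.
#' @param n target vertex count (default 50000).
#' @return list with `mesh` (a watertight `tri_mesh`) and `oracle`.
#' @export
make_lens <- function(R_up, R_down, a, n = 50000) {
  if (a <= 0 || a >= min(R_up, R_down)) {
    stop("infeasible lens: need 0 < a < min(R_up, R_down)")
  }
  phi_u <- asin(a / R_up)
  phi_d <- asin(a / R_down)
  c_u <- sqrt(R_up^2 - a^2)
  c_d <- sqrt(R_down^2 - a^2)
  A_up <- 2 * pi * R_up * (R_up - c_u)
  A_dn <- 2 * pi * R_down * (R_down - c_d)
  delta <- sqrt((A_up + A_dn) / n)
  n_rim <- max(16L, as.integer(round(2 * pi * a / delta)))
  rim_ang <- 2 * pi * (seq_len(n_rim) - 1L) / n_rim
  rim_xy <- cbind(a * cos(rim_ang), a * sin(rim_ang))
  n_int <- n - n_rim
  n_up <- max(8L, as.integer(round(n_int * A_up / (A_up + A_dn))))
  n_dn <- max(8L, n_int - n_up)
  up <- triangulate_cap(R_up, a, n_up, rim_xy, n_rim, 0L)
  dn <- triangulate_cap(R_down, a, n_dn, rim_xy, n_rim + n_up, n_up)
  verts <- rbind(cbind(rim_xy, 0), up$vertices,
                 cbind(dn$vertices[, 1:2], -dn$vertices[, 3]))
  faces <- rbind(up$faces, dn$faces[, c(1L, 3L, 2L), drop = FALSE])
  mesh <- tri_mesh(verts, faces)
  half <- c(up = phi_u, down = phi_d) * 180 / pi
  list(mesh = mesh,
       oracle = list(kind = "lens", R_up = R_up, R_down = R_down, a = a,
                     half_angles = half,
                     edge_angle = sum(half),
                     asymmetry = min(half) / max(half),
                     height_up = R_up - c_u, height_down = R_down - c_d))
}

#' Plano-convex lens (nearly flat upper face)
#'
#' A lens whose upper cap radius is large (`flat_ratio` times the rim
#' radius), giving a highly asymmetric edge like a plano-convex handaxe.
#' @param a rim radius.
#' @param R_down lower cap radius.
#' @param n target vertex count.
#' @param flat_ratio upper cap radius as a multiple of `a` (default 10).
#' @return as [make_lens()].
#' @export
make_plano_convex <- function(a, R_down, n = 50000, flat_ratio = 10) {
  out <- make_lens(flat_ratio * a, R_down, a, n)
  out$oracle$kind <- "plano_convex"
  out
}

#' Blunt-banded lens
#'
#' An equal-cap lens whose sharp rim is replaced, over a contiguous arc
#' covering fraction `f` of the perimeter, by a vertical cylindrical band of
#' height `band_height` symmetric about z = 0 (emulating an un-knapped /
#' blunt stretch of perimeter). The band is centered at the base (-y) and
#' blends into the sharp rim over a linear taper of 2% of the perimeter at
#' each end; the taper is excluded from the oracle's band arc.
#'
#' @param R cap sphere radius (both caps).
#' @param a rim radius.
#' @param f blunt arc fraction in (0, 1).
#' @param band_height band height (same units; must be positive and small
#'   enough that the band stays inside both caps).
#' @param n target vertex count.
#' @return list with `mesh` and `oracle` (band fraction, arc interval,
#'   sharp-region edge angle).
#' @export
make_blunt_lens <- function(R, a, f = 0.25, band_height = 0.06, n = 50000) {
  if (f <= 0 || f >= 1) stop("band fraction f must lie in (0, 1)")
  if (band_height <= 0) stop("band_height must be positive")
  c_ <- sqrt(R^2 - a^2)
  if (c_ + band_height / 2 >= R) stop("band_height too large for this lens")
  phi0 <- asin(a / R)
  center <- -pi / 2                          # band centered at the base (-y)
  half_arc <- f * pi
  taper <- 0.02 * 2 * pi
  height_at <- function(th) {
    d <- abs(((th - center + pi) %% (2 * pi)) - pi)   # angular distance
    if (d >= half_arc) return(0)                      # modified arc spans exactly f
    core <- half_arc - taper
    if (d <= core) return(band_height)
    band_height * (1 - (d - core) / taper)            # blend inside the band ends
  }
  mu <- 40L; mw <- 10L; md <- 40L
  profile <- function(th) {
    h <- height_at(th)
    phi_w <- acos(pmin(1, (c_ + h / 2) / R))
    pu <- phi_w * seq_len(mu) / mu
    zw <- h / 2 - h * seq_len(mw) / (mw + 1L)
    rw <- R * sin(phi_w)
    pd <- phi_w * (md - (seq_len(md) - 1L)) / md
    rbind(cbind(R * sin(pu), R * cos(pu) - c_),
          cbind(rep(rw, mw), zw),
          cbind(R * sin(pd), c_ - R * cos(pd)))
  }
  M <- mu + mw + md
  build <- function(nt) revolve_grid(profile, nt, z_top = R - c_, z_bot = c_ - R)
  mesh <- calibrate_revolve(build, as.integer(round((n - 2) / M)), n)
  list(mesh = mesh,
       oracle = list(kind = "blunt_lens", R = R, a = a, f = f,
                     band_height = band_height,
                     band_center_angle = center, band_half_arc = half_arc,
                     taper_arc = taper,
                     sharp_edge_angle = 2 * asin(a / R) * 180 / pi,
                     band_mid_z = 0))
}

#' Closed cylinder (entirely blunt perimeter)
#' @param radius,height cylinder dimensions (height along z).
#' @param n target vertex count.
#' @return list with `mesh` and `oracle`.
#' @export
make_cylinder <- function(radius, height, n = 20000) {
  mc <- 25L; mw <- 12L
  profile_mat <- local({
    rt <- radius * seq_len(mc) / mc
    zw <- height / 2 - height * seq_len(mw) / (mw + 1L)
    rb <- radius * (mc - (seq_len(mc) - 1L)) / mc
    rbind(cbind(rt, height / 2),
          cbind(radius, zw),
          cbind(rb, -height / 2))
  })
  build <- function(nt) revolve_grid(function(th) profile_mat, nt,
                                     z_top = height / 2, z_bot = -height / 2)
  mesh <- calibrate_revolve(build, as.integer(round((n - 2) / nrow(profile_mat))), n)
  list(mesh = mesh,
       oracle = list(kind = "cylinder", radius = radius, height = height,
                     mid_z = 0))
}

#' Lens with a concave (bowl) upper face
#'
#' The upper face is a shallow spherical bowl (radius `R_bowl`) dipping below
#' the rim plane; the lower face is a convex cap. Used to validate the
#' concave/convex face classification.
#'
#' @param a rim radius.
#' @param R_bowl bowl sphere radius (larger = shallower; must keep the bowl
#'   above the lower cap).
#' @param R_down lower cap radius.
#' @param n target vertex count.
#' @return list with `mesh` and `oracle`.
#' @export
make_bowl_top <- function(a, R_bowl, R_down, n = 50000) {
  if (a >= min(R_bowl, R_down)) stop("need a < min(R_bowl, R_down)")
  c_b <- sqrt(R_bowl^2 - a^2)
  c_d <- sqrt(R_down^2 - a^2)
  depth <- R_bowl - c_b
  if (depth >= R_down - c_d) stop("bowl dips into the lower cap; increase R_bowl")
  phi_b <- asin(a / R_bowl)
  phi_d <- asin(a / R_down)
  mb <- 45L; md <- 45L
  profile_mat <- local({
    pb <- phi_b * seq_len(mb) / mb
    pd <- phi_d * (md - (seq_len(md) - 1L)) / md
    rbind(cbind(R_bowl * sin(pb), c_b - R_bowl * cos(pb)),  # bowl: center low
          cbind(R_down * sin(pd), c_d - R_down * cos(pd)))
  })
  build <- function(nt) revolve_grid(function(th) profile_mat, nt,
                                     z_top = c_b - R_bowl, z_bot = c_d - R_down)
  mesh <- calibrate_revolve(build, as.integer(round((n - 2) / nrow(profile_mat))), n)
  list(mesh = mesh,
       oracle = list(kind = "bowl_top", a = a, R_bowl = R_bowl,
                     R_down = R_down, bowl_depth = depth))
}

#' Regular octahedron with exactly planar subdivided faces
#'
#' The equatorial square lies in the x-y plane; every equatorial dihedral is
#' exactly arccos(-1/3) = 109.4712 degrees. Faces are subdivided as planar
#' triangular lattices (no reprojection), so the dihedral survives any
#' resolution. Shared lattice points are keyed combinatorially, making the
#' mesh exact and watertight.
#'
#' @param subdivision lattice divisions per edge as a power of two
#'   (`m = 2^subdivision`); ignored when `target_vertices` is given.
#' @param target_vertices choose `m` to approximate this vertex count
#'   (`V = 4 m^2 + 2`).
#' @return a `tri_mesh`.
#' @export
make_octahedron <- function(subdivision = 0, target_vertices = NULL) {
  if (!is.null(target_vertices)) {
    m <- max(1L, as.integer(round(sqrt((target_vertices - 2) / 4))))
  } else {
    if (subdivision < 0) stop("subdivision must be >= 0")
    m <- 2L^as.integer(subdivision)
  }
  base_v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  base_f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
                  c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  if (m == 1L) return(tri_mesh(base_v, base_f))
  key_env <- new.env(hash = TRUE, parent = emptyenv())
  verts <- list(); nv <- 0L
  get_idx <- function(corners, counts) {
    nz <- counts > 0L
    ord <- order(corners[nz])
    key <- paste(corners[nz][ord], counts[nz][ord], sep = ":", collapse = "|")
    idx <- key_env[[key]]
    if (is.null(idx)) {
      nv <<- nv + 1L
      verts[[nv]] <<- colSums(base_v[corners, , drop = FALSE] * counts) / m
      key_env[[key]] <- nv
      idx <- nv
    }
    idx
  }
  faces <- vector("list", nrow(base_f))
  for (fi in seq_len(nrow(base_f))) {
    corners <- base_f[fi, ]
    # lattice index grid: point (i, j) with i along A->B, j along A->C
    idx_grid <- matrix(NA_integer_, m + 1L, m + 1L)
    for (i in 0:m) for (j in 0:(m - i)) {
      idx_grid[i + 1L, j + 1L] <- get_idx(corners, c(m - i - j, i, j))
    }
    tris <- list(); t_ <- 0L
    for (i in 0:(m - 1L)) for (j in 0:(m - 1L - i)) {
      t_ <- t_ + 1L
      tris[[t_]] <- c(idx_grid[i + 1L, j + 1L], idx_grid[i + 2L, j + 1L],
                      idx_grid[i + 1L, j + 2L])
      if (j <= m - 2L - i) {
        t_ <- t_ + 1L
        tris[[t_]] <- c(idx_grid[i + 2L, j + 1L], idx_grid[i + 2L, j + 2L],
                        idx_grid[i + 1L, j + 2L])
      }
    }
    faces[[fi]] <- do.call(rbind, tris)
  }
  tri_mesh(do.call(rbind, verts), do.call(rbind, faces))
}

#' Sphere mesh (subdivided octahedron projected to the sphere)
#' @param radius sphere radius.
#' @param target_vertices approximate vertex count.
#' @return a `tri_mesh`.
#' @export
make_sphere <- function(radius = 1, target_vertices = 20000) {
  mesh <- make_octahedron(target_vertices = target_vertices)
  v <- mesh$vertices
  v <- v * (radius / row_norms(v))
  tri_mesh(v, mesh$faces)
}

#' Piecewise-constant signal with Gaussian noise
#'
#' Deterministic for a fixed seed; the RNG state of the session is restored
#' on exit.
#'
#' @param means segment means (degrees).
#' @param lengths segment lengths (same length as `means`).
#' @param noise_sd Gaussian noise standard deviation (degrees).
#' @param seed integer seed.
#' @return list with `signal` and `truth` (`breakpoints`, `means`,
#'   `lengths`).
#' @export
make_piecewise_signal <- function(means, lengths, noise_sd = 0, seed = 1) {
  if (length(means) != length(lengths)) stop("means and lengths must have equal length")
  if (any(lengths < 1L)) stop("all lengths must be at least 1")
  base <- rep(means, times = lengths)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    base <- base + stats::rnorm(length(base), 0, noise_sd)
  }
  list(signal = base,
       truth = list(breakpoints = cumsum(lengths)[-length(lengths)],
                    means = means, lengths = lengths))
}
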