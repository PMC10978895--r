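# Outline detection: the closed 3D perimeter dividing the artifact into its
# two faces. The plan-view (x-y) projection of the mesh vertices is bounded
# by its alpha shape; boundary vertices are lifted back to 3D using the z of
# their source vertex; near-vertical (blunt) stretches get their z replaced
# by a local average; the outline is resampled to a fixed number of
# uniformly spaced coordinates starting at the tip.

#' Plan-view boundary of an oriented mesh (alpha shape)
#'
#' Projects the mesh vertices to the x-y plane and extracts the boundary of
#' their alpha complex (Delaunay triangles with circumradius below alpha).
#' When `alpha` is `NULL` the smallest alpha on a geometric grid (factor 1.3
#' steps up from the mean nearest-neighbor spacing) that yields a single
#' closed loop covering all projected points is used. With an explicit alpha
#' that produces several loops, the largest-area loop is returned with a
#' warning.
#'
#' @param omesh an `oriented_mesh`.
#' @param alpha positive circumradius cutoff, or `NULL` for automatic
#'   selection (`Inf` gives the convex hull).
#' @return list with `polygon` (ordered b x 2 boundary coordinates),
#'   `vertex_index` (source mesh vertex per boundary coordinate) and
#'   `alpha` (value used).
#' @export
project_boundary <- function(omesh, alpha = NULL) {
  stopifnot(inherits(omesh, "oriented_mesh"))
  v <- mesh_vertices(omesh)
  p <- v[, 1:2, drop = FALSE]
  key <- paste(p[, 1], p[, 2])
  first <- !duplicated(key)
  pu <- p[first, , drop = FALSE]
  src <- which(first)                  # representative mesh vertex per point
  if (nrow(pu) < 3L) stop("degenerate projection: fewer than 3 distinct plan points")
  # Near-vertical surfaces project whole columns of vertices onto almost
  # the same plan point; such clusters (and any point pair far below the
  # typical spacing) destabilize the triangulation without adding outline
  # information, so they are collapsed onto a grid of a quarter of the
  # median nearest-neighbor spacing (keeping the first source vertex).
  ev <- eigen(stats::cov(pu), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 1e-12 * ev[1]) stop("degenerate projection: collinear plan points")
  med <- stats::median(RANN::nn2(pu, k = 2L)$nn.dists[, 2L])
  if (!is.finite(med) || med <= 0) stop("degenerate projection: coincident plan points")
  cell <- med / 4
  gkey <- paste(floor(pu[, 1] / cell), floor(pu[, 2] / cell))
  gfirst <- !duplicated(gkey)
  pu <- pu[gfirst, , drop = FALSE]
  src <- src[gfirst]
  if (nrow(pu) < 3L) stop("degenerate projection: fewer than 3 distinct plan points")
  nn <- RANN::nn2(pu, k = 2L)
  spacing <- mean(nn$nn.dists[, 2L])
  if (!is.finite(spacing) || spacing <= 0) {
    stop("degenerate projection: coincident plan points")
  }
  # Exactly cocircular / collinear point batteries (common on synthetic
  # solids of revolution) make the Delaunay step degenerate; a deterministic
  # sub-resolution jitter is applied to the triangulation input only. The
  # returned polygon always carries the original coordinates.
  jit <- spacing * 0.05
  ii <- seq_len(nrow(pu))
  px <- pu[, 1] + jit * sin(9871 * ii)
  py <- pu[, 2] + jit * sin(5413 * ii + 1)
  tm <- tryCatch(
    interp::tri.mesh(px, py),
    error = function(e) {
      stop("degenerate projection: triangulation failed (", conditionMessage(e), ")")
    })
  tri <- interp::triangles(tm)[, 1:3, drop = FALSE]
  ccr <- circumradius2d(pu, tri)
  # the triangulation may drop residual near-duplicate points internally;
  # coverage is judged against the points it actually used
  n_used <- length(unique(as.vector(tri)))
  # normalize triangle windings counter-clockwise so boundary directed
  # edges keep the complex on their left; the winding (and all walk
  # geometry) must live in the jittered space the triangulation was built
  # in, or sliver triangles flip orientation
  pj <- cbind(px, py)
  a1 <- pj[tri[, 1], , drop = FALSE]
  b1 <- pj[tri[, 2], , drop = FALSE]
  c1 <- pj[tri[, 3], , drop = FALSE]
  cw <- (b1[, 1] - a1[, 1]) * (c1[, 2] - a1[, 2]) -
    (b1[, 2] - a1[, 2]) * (c1[, 1] - a1[, 1]) < 0
  tri[cw, ] <- tri[cw, c(1L, 3L, 2L), drop = FALSE]

  # a point is treated as contained if it is inside the loop or within half
  # a spacing of it (points midway between boundary vertices of a convex
  # arc sit epsilon-outside the chord)
  n_escaped <- function(loop) {
    pip <- sp::point.in.polygon(pu[, 1], pu[, 2], pu[loop, 1], pu[loop, 2])
    outs <- which(pip == 0L)
    if (length(outs) == 0L) return(0L)
    poly3 <- cbind(pu[loop, , drop = FALSE], 0)
    feet <- nearest_on_polyline(poly3, cbind(pu[outs, , drop = FALSE], 0))
    sum(sqrt(rowSums((feet[, 1:2, drop = FALSE] - pu[outs, , drop = FALSE])^2)) >
          0.5 * spacing)
  }
  if (is.null(alpha)) {
    # Smallest alpha whose outer loop contains all points AND whose
    # perimeter is stable against the next alpha step (within 0.2%). An
    # alpha below the surface resolution can close a zigzag loop through
    # sub-surface points, which inflates the perimeter; a too-large alpha
    # cuts across genuinely concave stretches. Perimeter stability marks
    # the scale where the loop starts tracking the actual silhouette.
    chosen <- NULL
    prev <- NULL
    for (k in 0:45) {
      a <- spacing * 1.3^k
      loop <- outer_boundary_walk(tri, ccr, a, pj)$loop
      if (is.null(loop) || length(loop) < 4L || n_escaped(loop) > 0L) {
        prev <- NULL
        next
      }
      pol <- pu[loop, , drop = FALSE]
      perim <- sum(sqrt(rowSums((pol - pol[c(seq_len(nrow(pol))[-1L], 1L), ])^2)))
      cur <- list(alpha = a, loop = loop, perim = perim, k = k)
      if (!is.null(prev) && prev$perim <= 1.002 * perim) { chosen <- prev; break }
      prev <- cur
    }
    if (is.null(chosen)) chosen <- prev   # largest valid alpha as fallback
    if (is.null(chosen)) stop("no alpha on the search grid yields a single boundary loop")
    loop <- chosen$loop
    alpha <- chosen$alpha
  } else {
    loop <- outer_boundary_walk(tri, ccr, alpha, pj)$loop
    if (is.null(loop)) stop("alpha too small: no closed boundary loop")
    esc <- n_escaped(loop)
    if (esc > 0L) {
      warning(sprintf("alpha shape leaves %d points outside the outermost loop (disconnected complex); returning the outermost loop",
                      esc))
    }
  }
  list(polygon = pu[loop, , drop = FALSE], vertex_index = src[loop], alpha = alpha)
}

# Outer boundary loop of the alpha complex, traversed counter-clockwise.
# Boundary directed edges (undirected multiplicity 1 among kept CCW
# triangles) keep the complex on their left; starting from the point of
# maximum x (always on the outer face), the walk picks, at junction
# vertices, the sharpest clockwise turn, which keeps it on the outer face
# past pinch vertices. Returns point indices in walk order, or NULL when
# no closed loop exists at this alpha.
outer_boundary_walk <- function(tri, ccr, alpha, pu, report_clean = FALSE) {
  fail <- list(loop = NULL, clean = FALSE)
  kt <- tri[ccr <= alpha, , drop = FALSE]
  if (nrow(kt) == 0L) return(fail)
  e <- rbind(kt[, c(1, 2)], kt[, c(2, 3)], kt[, c(3, 1)])
  ukey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(ukey)
  bd <- cnt[ukey] == 1L
  be <- e[bd, , drop = FALSE]
  if (nrow(be) < 3L) return(fail)
  deg <- table(as.vector(be))
  clean <- all(deg == 2L)
  # outgoing boundary edges per origin vertex
  ord <- order(be[, 1])
  bes <- be[ord, , drop = FALSE]
  starts <- c(1L, which(diff(bes[, 1]) != 0L) + 1L)
  ends <- c(starts[-1L] - 1L, nrow(bes))
  out_first <- integer(max(bes[, 1]))
  out_first[bes[starts, 1]] <- starts
  out_last <- integer(max(bes[, 1]))
  out_last[bes[starts, 1]] <- ends
  has_out <- logical(max(bes[, 1]))
  has_out[bes[, 1]] <- TRUE

  verts_on_bd <- unique(as.vector(be))
  start_v <- verts_on_bd[which.max(pu[verts_on_bd, 1])]
  if (!has_out[start_v]) return(fail)
  used <- rep(FALSE, nrow(bes))
  loop <- integer(0)
  cur <- start_v
  prev_dir <- c(0, 1)    # incoming direction at the max-x point is upward-ish
  max_steps <- nrow(bes) + 1L
  for (step in seq_len(max_steps)) {
    if (cur > length(has_out) || !has_out[cur]) return(fail)
    rows <- out_first[cur]:out_last[cur]
    rows <- rows[!used[rows]]
    if (length(rows) == 0L) return(fail)
    if (length(rows) > 1L) {
      # sharpest clockwise turn relative to the incoming direction
      w <- pu[bes[rows, 2], , drop = FALSE] - matrix(pu[cur, ], length(rows), 2, byrow = TRUE)
      ang <- atan2(prev_dir[1] * w[, 2] - prev_dir[2] * w[, 1],
                   prev_dir[1] * w[, 1] + prev_dir[2] * w[, 2])
      rows <- rows[which.min(ang)]
    }
    used[rows] <- TRUE
    nxt <- bes[rows, 2]
    loop <- c(loop, cur)
    prev_dir <- pu[nxt, ] - pu[cur, ]
    cur <- nxt
    if (cur == start_v) return(list(loop = loop, clean = clean))
  }
  fail
}

circumradius2d <- function(p, tri) {
  a <- p[tri[, 1], , drop = FALSE]
  b <- p[tri[, 2], , drop = FALSE]
  c_ <- p[tri[, 3], , drop = FALSE]
  la <- sqrt(rowSums((b - c_)^2))
  lb <- sqrt(rowSums((a - c_)^2))
  lc <- sqrt(rowSums((a - b)^2))
  area2 <- abs((b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
                 (c_[, 1] - a[, 1]) * (b[, 2] - a[, 2]))   # 2 * area
  r <- la * lb * lc / (2 * pmax(area2, .Machine$double.xmin))
  r[area2 == 0] <- Inf
  # degenerate slivers carry an arbitrarily large circumradius but zero
  # measure: excluding them would punch permanent pinholes in the alpha
  # complex, so they are treated as always included
  r[area2 < 1e-4 * stats::median(area2)] <- 0
  r
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

polygon_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(p))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

#' Lift a plan-view boundary to 3D
#'
#' Each boundary coordinate takes the z of its source mesh vertex. Over blunt
#' (near-vertical) perimeter stretches this z fluctuates wildly and is later
#' repaired by [correct_blunt_regions()].
#'
#' @param omesh the `oriented_mesh` the boundary came from.
#' @param boundary result of [project_boundary()].
#' @return a `raw_outline`: list with `coords` (b x 3), `vertex_index`,
#'   `blunt_flag` (all `FALSE`).
#' @export
lift_boundary <- function(omesh, boundary) {
  v <- mesh_vertices(omesh)
  idx <- boundary$vertex_index
  if (is.null(idx) || any(idx < 1L) || any(idx > nrow(v))) {
    stop("boundary does not map back to mesh vertices")
  }
  if (max(abs(boundary$polygon - v[idx, 1:2, drop = FALSE])) > 1e-9) {
    stop("boundary vertices inconsistent with source mesh projection")
  }
  structure(list(coords = cbind(boundary$polygon, z = v[idx, 3]),
                 vertex_index = idx,
                 blunt_flag = rep(FALSE, length(idx))),
            class = "raw_outline")
}

#' Repair outline z over blunt (near-vertical) perimeter stretches
#'
#' For each outline coordinate the mean inclination of nearby face normals to
#' the z axis is computed (an angle of 90 degrees means the surface is
#' vertical, i.e. its normal lies in the x-y plane). Where this mean exceeds
#' `90 - parallel_threshold` degrees, the coordinate is flagged blunt and its
#' z is replaced by the mean z of the `k` plan-view (x-y) nearest mesh
#' vertices, which for a vertical band recovers the band mid-height. x and y
#' are never modified.
#'
#' @param omesh the `oriented_mesh`.
#' @param outline a `raw_outline` from [lift_boundary()].
#' @param parallel_threshold degrees from vertical at which a surface counts
#'   as blunt (default 20).
#' @param k neighborhood size for both the normal average and the z average
#'   (default 50).
#' @return the `raw_outline` with corrected `coords` and `blunt_flag` set.
#' @export
correct_blunt_regions <- function(omesh, outline, parallel_threshold = 20, k = 50) {
  stopifnot(inherits(outline, "raw_outline"))
  v <- mesh_vertices(omesh)
  if (k > nrow(v)) stop("k exceeds mesh vertex count")
  f <- mesh_faces(omesh)
  fn <- face_normals(omesh)
  # inclination of each face normal to the z axis, in degrees: 0 = horizontal
  # face, 90 = vertical face
  incl <- acos(pmin(1, abs(fn[, 3]))) * 180 / pi
  cent <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
             v[f[, 3], , drop = FALSE]) / 3
  kf <- min(k, nrow(f))
  nnf <- RANN::nn2(cent[, 1:2, drop = FALSE], outline$coords[, 1:2, drop = FALSE], k = kf)
  mean_incl <- rowMeans(matrix(incl[nnf$nn.idx], ncol = kf))
  blunt <- mean_incl > (90 - parallel_threshold)
  if (any(blunt)) {
    nnv <- RANN::nn2(v[, 1:2, drop = FALSE],
                     outline$coords[blunt, 1:2, drop = FALSE], k = k)
    zbar <- rowMeans(matrix(v[nnv$nn.idx, 3], ncol = k))
    outline$coords[blunt, 3] <- zbar
  }
  outline$blunt_flag <- blunt
  outline
}

#' Resample a raw outline to a fixed coordinate count
#'
#' Piecewise-linear interpolation at uniform 3D arc-length spacing. The
#' sequence is re-indexed to start at the tip (maximum y), ordered
#' counter-clockwise in plan view, and carries cumulative arc positions, the
#' plan centroid, and interpolated blunt flags.
#'
#' @param outline a `raw_outline` (closed; at least 4 coordinates).
#' @param n number of output coordinates (default 1000).
#' @return an `outline3d`: list with `coords` (n x 3), `arc_pos`,
#'   `blunt_flag`, `plan_centroid`.
#' @export
resample_outline <- function(outline, n = 1000) {
  stopifnot(inherits(outline, "raw_outline"))
  p <- outline$coords
  if (nrow(p) < 4L) stop("outline must have at least 4 coordinates")
  if (polygon_self_intersects(p[, 1:2, drop = FALSE])) {
    stop("outline polygon is self-intersecting")
  }
  closed <- rbind(p, p[1L, ])
  gaps <- sqrt(rowSums(diff(closed)^2))
  if (any(gaps == 0)) {
    keep <- c(TRUE, gaps[-length(gaps)] > 0)
    p <- p[keep, , drop = FALSE]
    outline$blunt_flag <- outline$blunt_flag[keep]
    closed <- rbind(p, p[1L, ])
    gaps <- sqrt(rowSums(diff(closed)^2))
  }
  arc <- c(0, cumsum(gaps))
  total <- arc[length(arc)]
  t_new <- seq(0, total, length.out = n + 1L)[seq_len(n)]
  coords <- vapply(1:3, function(j) stats::approx(arc, closed[, j], xout = t_new)$y,
                   numeric(n))
  # blunt flag: nearest source coordinate along the arc
  src_flag <- c(outline$blunt_flag, outline$blunt_flag[1L])
  bidx <- vapply(t_new, function(t) which.min(abs(arc - t)), 1L)
  bflag <- src_flag[bidx]

  # counter-clockwise in plan view
  if (polygon_area(coords[, 1:2, drop = FALSE]) < 0) {
    coords <- coords[c(1L, n:2L), , drop = FALSE]
    bflag <- bflag[c(1L, n:2L)]
  }
  # start at the tip
  tip <- which.max(coords[, 2])
  ord <- c(tip:n, seq_len(tip - 1L))
  coords <- coords[ord, , drop = FALSE]
  bflag <- bflag[ord]
  closed2 <- rbind(coords, coords[1L, ])
  arc_pos <- c(0, cumsum(sqrt(rowSums(diff(closed2)^2))))[seq_len(n)]
  structure(list(coords = coords, arc_pos = arc_pos, blunt_flag = bflag,
                 plan_centroid = polygon_centroid(coords[, 1:2, drop = FALSE])),
            class = "outline3d")
}

#' @export
print.outline3d <- function(x, ...) {
  cat(sprintf("<outline3d> %d coordinates, perimeter %.4f, %d blunt-corrected\n",
              nrow(x$coords), outline_perimeter(x), sum(x$blunt_flag)))
  invisible(x)
}

# O(m^2) segment-pair intersection test (non-adjacent segments only),
# chunked over the first index to bound memory. Very long loops are
# subsampled: the guard is a sanity check, not an exact predicate.
polygon_self_intersects <- function(p) {
  m <- nrow(p)
  if (m > 2000L) {
    p <- p[round(seq(1, m, length.out = 2000L)), , drop = FALSE]
    m <- nrow(p)
  }
  a <- p
  b <- p[c(2:m, 1L), , drop = FALSE]
  side <- function(p1x, p1y, p2x, p2y, qx, qy) {
    (p2x - p1x) * (qy - p1y) - (p2y - p1y) * (qx - p1x)
  }
  for (i in seq_len(m - 2L)) {
    j <- seq(i + 2L, m)
    if (i == 1L) j <- j[j != m]
    if (length(j) == 0L) next
    d1 <- side(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2]) *
      side(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
    d2 <- side(a[j, 1], a[j, 2], b[j, 1], b[j, 2], rep(a[i, 1], length(j)), a[i, 2]) *
      side(a[j, 1], a[j, 2], b[j, 1], b[j, 2], rep(b[i, 1], length(j)), b[i, 2])
    if (any(d1 < 0 & d2 < 0)) return(TRUE)
  }
  FALSE
}

#' Total 3D perimeter of an outline
#' @param outline an `outline3d`.
#' @return scalar: sum of consecutive 3D gaps including the closing gap.
#' @export
outline_perimeter <- function(outline) {
  p <- outline$coords
  closed <- rbind(p, p[1L, ])
  sum(sqrt(rowSums(diff(closed)^2)))
}

#' Detect the full outline of an oriented mesh
#'
#' Convenience wrapper chaining [project_boundary()], [lift_boundary()],
#' [correct_blunt_regions()] and [resample_outline()].
#'
#' @param omesh an `oriented_mesh` (normally resampled and rescaled).
#' @param alpha optional alpha passed to [project_boundary()].
#' @param n outline coordinate count.
#' @param parallel_threshold,k blunt-correction parameters.
#' @return an `outline3d`.
#' @export
detect_outline <- function(omesh, alpha = NULL, n = 1000,
                           parallel_threshold = 20, k = 50) {
  b <- project_boundary(omesh, alpha)
  raw <- lift_boundary(omesh, b)
  raw <- correct_blunt_regions(omesh, raw, parallel_threshold, k)
  resample_outline(raw, n)
}

#' Export an outline as CSV
#' @param outline an `outline3d`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
outline_to_csv <- function(outline, path) {
  df <- data.frame(index = seq_len(nrow(outline$coords)),
                   x = outline$coords[, 1], y = outline$coords[, 2],
                   z = outline$coords[, 3], arc_pos = outline$arc_pos,
                   blunt_flag = outline$blunt_flag)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export an outline as a closed OBJ polyline
#' @param outline an `outline3d`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
outline_to_obj <- function(outline, path) {
  p <- outline$coords
  n <- nrow(p)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", p[, 1], p[, 2], p[, 3]), con)
  writeLines(paste("l", paste(c(seq_len(n), 1L), collapse = " ")), con)
  invisible(path)
}
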