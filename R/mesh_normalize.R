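# Orientation, scale and resolution normalization. All artifacts are brought
# into a common convention before analysis: length axis = y (tip at +y),
# plan view = x-y plane, thickness axis = z, length rescaled to 1, and the
# mesh resampled to a canonical vertex count.

#' Orient an artifact mesh into the analysis convention
#'
#' If a rotation matrix is supplied it is applied verbatim (after centering
#' at the vertex centroid). Otherwise principal-axes alignment is used: the
#' first principal axis becomes y (length), the second x (width), the third z
#' (thickness). The y sign is chosen so the half with the smaller mean plan
#' width (the tip) points to +y; the z sign is fixed by the sign of the
#' third-moment of z (deterministic), and x completes a right-handed frame.
#'
#' Near-isotropic meshes (adjacent principal standard deviations within a
#' factor 1.01) are oriented all the same but flagged `ambiguous`.
#'
#' @param mesh a `tri_mesh`.
#' @param rotation optional 3 x 3 orthonormal matrix (determinant +1), applied
#'   as `v %*% t(rotation)`.
#' @return an `oriented_mesh`: list with `mesh` (rotated, centered
#'   `tri_mesh`), `rotation`, `auto`, `ambiguous`, `scale`.
#' @export
orient_artifact <- function(mesh, rotation = NULL) {
  if (inherits(mesh, "oriented_mesh")) mesh <- mesh$mesh
  v <- mesh$vertices
  ctr <- colMeans(v)
  vc <- sweep(v, 2L, ctr)
  ambiguous <- FALSE
  if (!is.null(rotation)) {
    rotation <- as.matrix(rotation)
    if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3 x 3")
    if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
        abs(det(rotation) - 1) > 1e-9) {
      stop("rotation must be orthonormal with determinant +1")
    }
    vr <- vc %*% t(rotation)
    auto <- FALSE
  } else {
    cv <- stats::cov(vc)
    scale2 <- max(diag(cv))
    sdevs_d <- sqrt(pmax(diag(cv), 0))
    already <- max(abs(cv[upper.tri(cv)])) < 1e-9 * scale2 &&
      sdevs_d[2] >= sdevs_d[1] && sdevs_d[1] >= sdevs_d[3]
    if (already) {
      # covariance already diagonal in the target convention: keep the
      # axes fixed (no eigenvector sign noise) so orientation is idempotent
      ey <- c(0, 1, 0); ez <- c(0, 0, 1)
      sdevs <- sdevs_d[c(2, 1, 3)]
    } else {
      eg <- eigen(cv, symmetric = TRUE)
      sdevs <- sqrt(pmax(eg$values, 0))
      ey <- eg$vectors[, 1]  # length
      ez <- eg$vectors[, 3]  # thickness
      # deterministic z sign: third moment of the projection
      if (sum((vc %*% ez)^3) < 0) ez <- -ez
    }
    if (any(sdevs[-3] / pmax(sdevs[-1], .Machine$double.eps) < 1.01)) {
      ambiguous <- TRUE
    }
    # tip = y-half with smaller mean plan (|x|) width
    proj_y <- vc %*% ey
    ex0 <- vc %*% (crossprod_vec(ey, ez))
    up <- proj_y > 0
    w_up <- mean(abs(ex0[up])); w_dn <- mean(abs(ex0[!up]))
    if (isTRUE(w_up > w_dn)) ey <- -ey
    ex <- crossprod_vec(ey, ez)
    rotation <- t(cbind(ex, ey, ez))   # rows = new axes
    vr <- vc %*% t(rotation)
    auto <- TRUE
  }
  out <- list(mesh = tri_mesh(vr, mesh$faces, mesh$provenance),
              rotation = rotation, auto = is.null(rotation) || auto,
              ambiguous = ambiguous, scale = 1)
  if (is.null(out$mesh$provenance)) out$mesh$provenance <- list()
  out$mesh$provenance$ambiguous_orientation <- ambiguous
  class(out) <- "oriented_mesh"
  out
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' @export
print.oriented_mesh <- function(x, ...) {
  cat("<oriented_mesh>", if (x$ambiguous) "(ambiguous principal axes)" else "", "\n")
  print(x$mesh)
  invisible(x)
}

#' Rescale an oriented mesh to unit length
#'
#' Uniform (isotropic) scaling so that the y extent (artifact length) is
#' exactly 1. Shape ratios are untouched.
#' @param omesh an `oriented_mesh`.
#' @return the rescaled `oriented_mesh` (`scale` records the factor applied).
#' @export
rescale_mesh <- function(omesh) {
  stopifnot(inherits(omesh, "oriented_mesh"))
  ext <- mesh_extents(omesh)
  if (ext[2] <= 0) stop("zero y-extent: cannot rescale")
  s <- 1 / ext[2]
  omesh$mesh$vertices <- omesh$mesh$vertices * s
  omesh$scale <- omesh$scale * s
  omesh
}

#' Resample a mesh to a canonical vertex count
#'
#' Scan resolution is a confounder of edge-angle measurement, so all meshes
#' are brought to the same vertex count (default 50,000, within 2%). Meshes
#' below the target are first midpoint-subdivided (shape-preserving: no
#' smoothing or reprojection), then decimated by vertex clustering on a
#' uniform grid whose cell size is found by bisection.
#'
#' @param mesh `tri_mesh` or `oriented_mesh`.
#' @param target_vertices target vertex count (default 50000, minimum 100).
#' @param tol relative tolerance on the achieved count (default 0.02).
#' @return mesh of the same class with ~`target_vertices` vertices.
#' @export
resample_mesh <- function(mesh, target_vertices = 50000, tol = 0.02) {
  if (target_vertices < 100) stop("target_vertices must be at least 100")
  omesh <- NULL
  if (inherits(mesh, "oriented_mesh")) {
    omesh <- mesh
    mesh <- mesh$mesh
  }
  n <- nrow(mesh$vertices)
  if (abs(n - target_vertices) <= tol * target_vertices) {
    out <- mesh
  } else if (n < target_vertices) {
    # upsample: full midpoint passes while they fit, then longest-edge
    # bisection up to the target (shape-preserving, no decimation)
    work <- mesh
    while (4L * nrow(work$vertices) <= (1 + tol) * target_vertices) {
      work <- subdivide_midpoint(work)
    }
    out <- refine_longest_edges(work, target_vertices)
  } else {
    out <- decimate_cluster(mesh, target_vertices, tol)
  }
  out$provenance$resampled_from <- n
  if (!is.null(omesh)) {
    omesh$mesh <- out
    return(omesh)
  }
  out
}

# One round of midpoint (1-to-4) subdivision. Planar faces stay planar.
subdivide_midpoint <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  eid <- match(key, unique(key))
  first <- !duplicated(eid)
  mid <- (v[e[first, 1], , drop = FALSE] + v[e[first, 2], , drop = FALSE]) / 2
  mid_idx <- nrow(v) + eid              # new-vertex index per half-edge
  m <- nrow(f)
  m12 <- mid_idx[seq_len(m)]
  m23 <- mid_idx[m + seq_len(m)]
  m31 <- mid_idx[2L * m + seq_len(m)]
  f2 <- rbind(cbind(f[, 1], m12, m31),
              cbind(m12, f[, 2], m23),
              cbind(m31, m23, f[, 3]),
              cbind(m12, m23, m31))
  tri_mesh(rbind(v, mid), f2, mesh$provenance)
}

# Longest-edge bisection: repeatedly split the longest edges (one new
# midpoint vertex per split; each incident face becomes two) until the
# vertex count reaches the target. Per pass, a face-disjoint set of the
# longest edges is split, so the updates batch cleanly.
refine_longest_edges <- function(mesh, target) {
  v <- mesh$vertices
  f <- mesh$faces
  while (nrow(v) < target) {
    need <- target - nrow(v)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    fid <- rep(seq_len(nrow(f)), 3L)
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    first <- !duplicated(key)
    lens <- row_norms(v[e[first, 1], , drop = FALSE] - v[e[first, 2], , drop = FALSE])
    ord <- order(lens, decreasing = TRUE)
    # greedily take the longest edges whose faces are still untouched
    face_used <- rep(FALSE, nrow(f))
    ekeys <- key[first][ord]
    incident <- split(fid, key)
    picked <- character(0)
    for (ek in ekeys) {
      fs <- incident[[ek]]
      if (any(face_used[fs])) next
      face_used[fs] <- TRUE
      picked <- c(picked, ek)
      if (length(picked) >= need) break
    }
    if (length(picked) == 0L) break
    epick <- e[first, , drop = FALSE][match(picked, key[first]), , drop = FALSE]
    mids <- (v[epick[, 1], , drop = FALSE] + v[epick[, 2], , drop = FALSE]) / 2
    mid_idx <- nrow(v) + seq_len(nrow(epick))
    v <- rbind(v, mids)
    new_faces <- list()
    drop_faces <- integer(0)
    edge_of_pick <- stats::setNames(mid_idx, picked)
    for (j in seq_len(nrow(epick))) {
      a <- epick[j, 1]; b <- epick[j, 2]; m <- mid_idx[j]
      for (fi in incident[[picked[j]]]) {
        fr <- f[fi, ]
        c_ <- fr[!(fr %in% c(a, b))][1]
        # preserve winding: replace the split edge endpoint in place
        f1 <- fr; f1[f1 == b] <- m
        f2 <- fr; f2[f2 == a] <- m
        new_faces[[length(new_faces) + 1L]] <- rbind(f1, f2)
        drop_faces <- c(drop_faces, fi)
      }
    }
    f <- rbind(f[-drop_faces, , drop = FALSE], do.call(rbind, new_faces))
  }
  tri_mesh(v, f, mesh$provenance)
}

# Vertex-clustering decimation: snap vertices to a uniform grid, replace each
# occupied cell by the centroid of its vertices, re-index faces, drop
# degenerates. Cell size is bisected until the vertex count hits the target.
decimate_cluster <- function(mesh, target, tol = 0.02) {
  v <- mesh$vertices
  ext <- mesh_extents(mesh)
  lo <- 0                               # cell size -> count = nrow(v)
  hi <- max(ext)                        # one cell -> tiny count
  count_at <- function(h) {
    if (h <= 0) return(nrow(v))
    length(unique(cell_ids(v, h)))
  }
  h <- hi / 2
  for (i in 1:60) {
    cnt <- count_at(h)
    if (abs(cnt - target) <= tol * target) break
    if (cnt > target) lo <- h else hi <- h
    h <- (lo + hi) / 2
  }
  ids <- cell_ids(v, h)
  uid <- match(ids, unique(ids))
  centroids <- rowsum(v, uid, reorder = TRUE) /
    as.vector(table(factor(uid, levels = sort(unique(uid)))))
  f2 <- matrix(uid[mesh$faces], ncol = 3L)
  keep <- f2[, 1] != f2[, 2] & f2[, 2] != f2[, 3] & f2[, 1] != f2[, 3]
  f2 <- f2[keep, , drop = FALSE]
  fsort <- t(apply(f2, 1L, sort))
  f2 <- f2[!duplicated(fsort), , drop = FALSE]
  clean_mesh(tri_mesh(centroids, f2, mesh$provenance), quiet = TRUE)
}

cell_ids <- function(v, h) {
  mins <- apply(v, 2L, min)
  g <- floor(sweep(v, 2L, mins) / h + 1e-12)
  paste(g[, 1], g[, 2], g[, 3])
}
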