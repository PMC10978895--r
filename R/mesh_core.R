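# Core triangle-mesh container and low-level geometry helpers.

#' Triangle mesh of a single artifact
#'
#' Constructs the basic mesh container used throughout the pipeline: a matrix
#' of 3D vertex coordinates plus a matrix of triangular faces (1-based vertex
#' indices). Input geometry is validated but not cleaned; see
#' [clean_mesh()].
#'
#' @param vertices numeric matrix, n x 3.
#' @param faces integer matrix, m x 3, 1-based indices into `vertices`.
#' @param provenance optional list recording source path/format and
#'   processing notes.
#' @return An object of class `tri_mesh` with elements `vertices`, `faces`,
#'   `provenance`.
#' @export
tri_mesh <- function(vertices, faces, provenance = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(vertices) < 4L) stop("mesh must have at least 4 vertices")
  if (anyNA(vertices)) stop("vertices contain NA")
  if (nrow(faces) < 1L || anyNA(faces)) stop("faces missing or contain NA")
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces, provenance = provenance),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  ext <- mesh_extents(x)
  cat(sprintf("  extents: x %.4g  y %.4g  z %.4g\n", ext[1], ext[2], ext[3]))
  if (!is.null(x$provenance$source)) {
    cat("  source:", x$provenance$source, "\n")
  }
  invisible(x)
}

# Axis-aligned bounding-box extents (x, y, z).
#' Bounding-box extents of a mesh
#' @param mesh a `tri_mesh` or `oriented_mesh`.
#' @return numeric length-3 vector of x, y, z extents.
#' @export
mesh_extents <- function(mesh) {
  v <- mesh_vertices(mesh)
  unname(apply(v, 2L, function(col) diff(range(col))))
}

# Uniform accessors so functions accept tri_mesh or oriented_mesh.
mesh_vertices <- function(mesh) {
  if (inherits(mesh, "oriented_mesh")) mesh$mesh$vertices else mesh$vertices
}
mesh_faces <- function(mesh) {
  if (inherits(mesh, "oriented_mesh")) mesh$mesh$faces else mesh$faces
}

row_norms <- function(m) sqrt(rowSums(m * m))

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Unnormalized face normals (cross product; length = 2 * face area).
face_cross <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  cross3(b - a, c_ - a)
}

#' Per-face unit normals
#' @param mesh a `tri_mesh` or `oriented_mesh`.
#' @return m x 3 matrix of unit normals (winding order convention).
#' @export
face_normals <- function(mesh) {
  fc <- face_cross(mesh_vertices(mesh), mesh_faces(mesh))
  n <- row_norms(fc)
  n[n == 0] <- 1
  fc / n
}

#' Total surface area of a mesh
#' @param mesh a `tri_mesh` or `oriented_mesh`.
#' @return scalar area (squared input units).
#' @export
mesh_area <- function(mesh) {
  sum(row_norms(face_cross(mesh_vertices(mesh), mesh_faces(mesh)))) / 2
}

#' Signed volume enclosed by a mesh
#'
#' Positive for a watertight mesh with outward-oriented faces.
#' @param mesh a `tri_mesh` or `oriented_mesh`.
#' @return scalar signed volume.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh_vertices(mesh)
  f <- mesh_faces(mesh)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(rowSums(a * cross3(b, c_))) / 6
}

#' Area-weighted per-vertex unit normals
#'
#' Face windings are first made globally consistent and outward (positive
#' enclosed volume) when the mesh is closed.
#' @param mesh a `tri_mesh` or `oriented_mesh`.
#' @return n x 3 matrix of unit vertex normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh_vertices(mesh)
  f <- orient_faces(v, mesh_faces(mesh))
  fc <- face_cross(v, f)            # length encodes 2x area: free weighting
  acc <- rowsum(fc[rep(seq_len(nrow(f)), 3L), , drop = FALSE],
                group = as.vector(f), reorder = TRUE)
  out <- matrix(0, nrow(v), 3L)
  out[as.integer(rownames(acc)), ] <- acc
  n <- row_norms(out)
  if (any(n == 0)) stop("unorientable or isolated vertices: cannot compute vertex normals")
  out / n
}

# Make face windings consistent across shared edges (breadth-first flip) and
# outward if the mesh encloses positive volume. Returns the face matrix.
orient_faces <- function(vertices, faces) {
  m <- nrow(faces)
  he <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  # consistent iff no undirected edge is traversed twice in the same direction
  dir_key <- paste(he[, 1], he[, 2])
  if (!anyDuplicated(dir_key)) {
    consistent <- TRUE
  } else {
    consistent <- FALSE
  }
  if (!consistent) {
    faces <- repair_windings(faces, he, key)
  }
  # the enclosed-volume sign disambiguates outward only for closed meshes;
  # open patches keep the winding they came with
  closed <- all(table(key) == 2L)
  if (closed) {
    vol <- sum(rowSums(vertices[faces[, 1], , drop = FALSE] *
                         cross3(vertices[faces[, 2], , drop = FALSE],
                                vertices[faces[, 3], , drop = FALSE]))) / 6
    if (vol < 0) faces <- faces[, c(1, 3, 2), drop = FALSE]
  }
  faces
}

# BFS over face adjacency, flipping faces whose shared edge runs the same
# direction as an already-fixed neighbor.
repair_windings <- function(faces, he, key) {
  m <- nrow(faces)
  ek <- match(key, unique(key))
  # map undirected edge id -> incident faces (at most 2 for manifold edges)
  fid <- rep(seq_len(m), 3L)
  ord <- order(ek)
  ek_s <- ek[ord]; fid_s <- fid[ord]
  starts <- c(1L, which(diff(ek_s) != 0L) + 1L)
  ends <- c(starts[-1L] - 1L, length(ek_s))
  adj <- vector("list", m)
  for (i in seq_along(starts)) {
    fs <- fid_s[starts[i]:ends[i]]
    if (length(fs) == 2L) {
      adj[[fs[1]]] <- c(adj[[fs[1]]], fs[2])
      adj[[fs[2]]] <- c(adj[[fs[2]]], fs[1])
    }
  }
  visited <- rep(FALSE, m)
  flipped <- rep(FALSE, m)
  for (seed in seq_len(m)) {
    if (visited[seed]) next
    queue <- seed
    visited[seed] <- TRUE
    while (length(queue)) {
      f0 <- queue[[1L]]; queue <- queue[-1L]
      e0 <- directed_edges_of(faces[f0, ], flipped[f0])
      for (f1 in adj[[f0]]) {
        if (visited[f1]) next
        e1 <- directed_edges_of(faces[f1, ], flipped[f1])
        shared_same_dir <- any(paste(e0[, 1], e0[, 2]) %in% paste(e1[, 1], e1[, 2]))
        if (shared_same_dir) flipped[f1] <- TRUE
        visited[f1] <- TRUE
        queue <- c(queue, f1)
      }
    }
  }
  if (any(flipped)) {
    faces[flipped, ] <- faces[flipped, c(1, 3, 2), drop = FALSE]
  }
  faces
}

directed_edges_of <- function(fr, flip) {
  if (flip) fr <- fr[c(1, 3, 2)]
  rbind(fr[c(1, 2)], fr[c(2, 3)], fr[c(3, 1)])
}

#' Clean a raw mesh
#'
#' Merges duplicate vertices (exact coordinates after rounding to
#' `digits` decimal places), drops degenerate (zero-area / repeated-index)
#' faces and duplicated faces, keeps the largest connected component, and
#' removes unreferenced vertices. Counts of dropped elements are recorded in
#' the provenance and reported via [message()].
#'
#' @param mesh a `tri_mesh`.
#' @param digits rounding used to key duplicate vertices (default 9).
#' @param quiet suppress messages.
#' @return cleaned `tri_mesh`.
#' @export
clean_mesh <- function(mesh, digits = 9, quiet = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  key <- paste(round(v[, 1], digits), round(v[, 2], digits), round(v[, 3], digits))
  uid <- match(key, key)              # representative = first occurrence
  keep_v <- sort(unique(uid))
  remap <- integer(nrow(v))
  remap[keep_v] <- seq_along(keep_v)
  f2 <- matrix(remap[uid[f]], ncol = 3L)
  v2 <- v[keep_v, , drop = FALSE]
  n_dup_vert <- nrow(v) - nrow(v2)

  # degenerate faces: repeated indices or (near) zero area
  degen <- f2[, 1] == f2[, 2] | f2[, 2] == f2[, 3] | f2[, 1] == f2[, 3]
  if (!all(degen)) {
    areas <- row_norms(face_cross(v2, f2)) / 2
    scale2 <- max(mesh_extents(list(vertices = v2, faces = f2)))^2
    degen <- degen | areas <= 1e-14 * max(scale2, .Machine$double.eps)
  }
  f2 <- f2[!degen, , drop = FALSE]
  n_degen <- sum(degen)
  # duplicated faces (same unordered triple)
  fsort <- t(apply(f2, 1L, sort))
  dupf <- duplicated(fsort)
  f2 <- f2[!dupf, , drop = FALSE]
  n_dupf <- sum(dupf)
  if (nrow(f2) == 0L) stop("mesh empty after cleanup")

  # largest connected component
  g <- igraph::graph_from_edgelist(
    rbind(f2[, c(1, 2)], f2[, c(2, 3)], f2[, c(3, 1)]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(v2) - igraph::vcount(g)))
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  in_big <- comp$membership == big
  keep_f <- in_big[f2[, 1]] & in_big[f2[, 2]] & in_big[f2[, 3]]
  n_comp_f <- sum(!keep_f)
  f2 <- f2[keep_f, , drop = FALSE]

  used <- sort(unique(as.vector(f2)))
  remap2 <- integer(nrow(v2))
  remap2[used] <- seq_along(used)
  f2 <- matrix(remap2[f2], ncol = 3L)
  v2 <- v2[used, , drop = FALSE]

  dropped <- c(duplicate_vertices = n_dup_vert, degenerate_faces = n_degen,
               duplicate_faces = n_dupf, off_component_faces = n_comp_f)
  if (!quiet && any(dropped > 0)) {
    message(sprintf(
      "clean_mesh: merged %d duplicate vertices; dropped %d degenerate, %d duplicate, %d off-component faces",
      n_dup_vert, n_degen, n_dupf, n_comp_f))
  }
  prov <- mesh$provenance
  prov$cleanup <- as.list(dropped)
  if (nrow(v2) < 4L) stop("mesh empty after cleanup (fewer than 4 vertices)")
  tri_mesh(v2, f2, prov)
}
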