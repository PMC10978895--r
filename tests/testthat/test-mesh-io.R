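# Mesh readers: OBJ, PLY (ascii + binary), STL (ascii + binary), VRML97.

tetra_obj <- function(path) {
  writeLines(c("# tetrahedron",
               "v 0 0 0", "v 1 0 0", "v 0 1 0", "v 0 0 1",
               "f 1 3 2", "f 1 2 4", "f 1 4 3", "f 2 3 4"), path)
  path
}

test_that("OBJ reader handles a minimal tetrahedron and face variants", {
  p <- tetra_obj(tempfile(fileext = ".obj"))
  m <- read_mesh(p, quiet = TRUE)
  expect_s3_class(m, "tri_mesh")
  expect_equal(nrow(m$vertices), 4L)
  expect_equal(nrow(m$faces), 4L)

  # v/vt/vn face tokens parse to the vertex index
  p2 <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "v 0 0 1",
               "f 1/1/1 3/2/2 2/3/3", "f 1/1 2/2 4/3",
               "f 1 4 3", "f 2 3 4"), p2)
  expect_equal(nrow(read_mesh(p2, quiet = TRUE)$faces), 4L)
})

test_that("degenerate faces are dropped with a message and duplicates merged", {
  p <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "v 0 0 1", "v 1 0 0",
               "f 1 3 2", "f 1 2 4", "f 1 4 3", "f 2 3 4",
               "f 2 5 3",      # vertices 2 and 5 coincide: zero area
               "f 1 1 2"), p)  # repeated index
  expect_message(m <- read_mesh(p), "degenerate")
  expect_equal(nrow(m$vertices), 4L)
  expect_equal(nrow(m$faces), 4L)
})

test_that("PLY round-trips in ascii and parses binary little-endian", {
  m0 <- read_mesh(tetra_obj(tempfile(fileext = ".obj")), quiet = TRUE)
  p <- tempfile(fileext = ".ply")
  write_mesh_ply(m0, p)
  m1 <- read_mesh(p, quiet = TRUE)
  expect_equal(m1$vertices, m0$vertices, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(nrow(m1$faces), 4L)

  # binary cube: 8 vertices, 12 triangles
  vb <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  fb <- rbind(c(1,3,2), c(2,3,4), c(5,6,7), c(6,8,7), c(1,2,5), c(2,6,5),
              c(3,7,4), c(4,7,8), c(1,5,3), c(3,5,7), c(2,4,6), c(4,8,6))
  pb <- tempfile(fileext = ".ply")
  con <- file(pb, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               "element vertex 8",
               "property float x", "property float y", "property float z",
               "element face 12",
               "property list uchar int vertex_indices", "end_header"), con)
  for (i in 1:8) writeBin(as.numeric(vb[i, ]), con, size = 4L, endian = "little")
  for (i in 1:12) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(fb[i, ] - 1L), con, size = 4L, endian = "little")
  }
  close(con)
  mc <- read_mesh(pb, quiet = TRUE)
  expect_equal(nrow(mc$vertices), 8L)
  expect_equal(nrow(mc$faces), 12L)
  expect_equal(abs(mesh_volume(mc)), 1, tolerance = 1e-9)
})

test_that("STL reads ascii and binary forms", {
  m0 <- read_mesh(tetra_obj(tempfile(fileext = ".obj")), quiet = TRUE)
  v <- m0$vertices; f <- m0$faces
  pa <- tempfile(fileext = ".stl")
  con <- file(pa, "w")
  writeLines("solid t", con)
  for (i in seq_len(nrow(f))) {
    writeLines("facet normal 0 0 0", con)
    writeLines(" outer loop", con)
    for (j in 1:3) writeLines(sprintf("  vertex %g %g %g",
                                      v[f[i, j], 1], v[f[i, j], 2], v[f[i, j], 3]), con)
    writeLines(" endloop", con)
    writeLines("endfacet", con)
  }
  writeLines("endsolid t", con)
  close(con)
  ma <- read_mesh(pa, quiet = TRUE)
  expect_equal(nrow(ma$vertices), 4L)   # duplicates merged on load
  expect_equal(nrow(ma$faces), 4L)

  pbin <- tempfile(fileext = ".stl")
  con <- file(pbin, "wb")
  writeBin(raw(80L), con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(f))) {
    writeBin(numeric(3), con, size = 4L, endian = "little")
    for (j in 1:3) writeBin(as.numeric(v[f[i, j], ]), con, size = 4L, endian = "little")
    writeBin(raw(2L), con)
  }
  close(con)
  mb <- read_mesh(pbin, quiet = TRUE)
  expect_equal(nrow(mb$vertices), 4L)
  expect_equal(nrow(mb$faces), 4L)
})

test_that("VRML97 IndexedFaceSet parses, including quads", {
  p <- tempfile(fileext = ".wrl")
  writeLines(c("#VRML V2.0 utf8",
               "Shape { geometry IndexedFaceSet {",
               " coord Coordinate { point [",
               "  0 0 0, 1 0 0, 1 1 0, 0 1 0, 0.5 0.5 1",
               " ] }",
               " coordIndex [",
               "  0 1 2 3 -1,",       # quad base: fan-triangulated
               "  0 4 1 -1, 1 4 2 -1, 2 4 3 -1, 3 4 0 -1",
               " ] } }"), p)
  m <- read_mesh(p, quiet = TRUE)
  expect_equal(nrow(m$vertices), 5L)
  expect_equal(nrow(m$faces), 6L)
  expect_gt(abs(mesh_volume(m)), 0)
})

test_that("unreadable input fails with a parse error naming the problem", {
  p <- tempfile(fileext = ".obj")
  writeLines(c("nothing", "to see"), p)
  expect_error(read_mesh(p), "parse error")
  expect_error(read_mesh(tempfile(fileext = ".obj")), "not found")
  p2 <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 x"), p2)
  expect_error(read_mesh(p2), "bad face token")
})

test_that("mesh writers round-trip through OBJ", {
  ln <- make_lens(0.5, 0.5, 0.4, 800)
  p <- tempfile(fileext = ".obj")
  write_mesh_obj(ln$mesh, p)
  m <- read_mesh(p, quiet = TRUE)
  expect_equal(nrow(m$vertices), nrow(ln$mesh$vertices))
  expect_equal(mesh_volume(m), mesh_volume(ln$mesh), tolerance = 1e-6)
})
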