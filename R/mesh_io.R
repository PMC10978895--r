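# Readers and writers for the mesh formats used by 3D artifact archives:
# OBJ, PLY (ascii + binary little/big endian), STL (ascii + binary), and a
# minimal VRML97 / WRL IndexedFaceSet dialect. Readers return cleaned meshes.

#' Read a triangle mesh from disk
#'
#' Supports Wavefront OBJ, PLY (ASCII and binary), STL (ASCII and binary) and
#' VRML97 `IndexedFaceSet` nodes with `Coordinate` points (the dialect used by
#' common artifact repositories). Polygonal faces are fan-triangulated. The
#' mesh is cleaned on load: duplicate vertices merged, degenerate and
#' duplicate faces dropped, and only the largest connected component kept.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"obj"`, `"ply"`, `"stl"`, `"wrl"`.
#' @param quiet suppress cleanup messages.
#' @return a cleaned [tri_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "obj", "ply", "stl", "wrl"), quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     obj = "obj", ply = "ply", stl = "stl",
                     wrl = "wrl", vrml = "wrl",
                     stop("cannot infer mesh format from extension: ", ext))
  }
  raw <- switch(format,
                obj = read_obj(path),
                ply = read_ply(path),
                stl = read_stl(path),
                wrl = read_wrl(path))
  raw$provenance <- list(source = path, format = format)
  mesh <- tri_mesh(raw$vertices, raw$faces, raw$provenance)
  clean_mesh(mesh, quiet = quiet)
}

fan_triangulate <- function(polys) {
  # polys: list of integer vectors (>= 3 vertices each) -> m x 3 matrix
  tris <- lapply(polys, function(p) {
    if (length(p) < 3L) return(NULL)
    cbind(p[1L], p[seq(2L, length(p) - 1L)], p[seq(3L, length(p))])
  })
  do.call(rbind, tris)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L || length(flines) == 0L) {
    stop("OBJ parse error in ", path, ": no 'v'/'f' records found")
  }
  v <- matrix(scan(text = gsub("^v\\s+", "", vlines), quiet = TRUE),
              ncol = 3L, byrow = TRUE)
  polys <- lapply(strsplit(sub("^f\\s+", "", flines), "\\s+"), function(tok) {
    idx <- suppressWarnings(as.integer(sub("/.*$", "", tok)))
    if (anyNA(idx)) stop("OBJ parse error: bad face token '", tok[which(is.na(idx))[1]], "'")
    idx
  })
  list(vertices = v, faces = fan_triangulate(polys))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("PLY parse error: unexpected end of header")
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
    if (length(header) > 500L) stop("PLY parse error: header not terminated")
  }
  if (!grepl("^ply", header[1])) stop("PLY parse error: missing 'ply' magic in ", path)
  fmt_line <- grep("^format ", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]

  # parse element/property declarations
  elems <- list(); cur <- NULL
  for (ln in header) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      elems[[cur]] <- list(count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      elems[[cur]]$props[[length(elems[[cur]]$props) + 1L]] <- tok[-1L]
    }
  }
  if (is.null(elems$vertex) || is.null(elems$face)) {
    stop("PLY parse error: need 'vertex' and 'face' elements")
  }
  nv <- elems$vertex$count
  nf <- elems$face$count

  if (fmt == "ascii") {
    rest <- readLines(con)
    rest <- rest[nzchar(trimws(rest))]
    vprops <- vapply(elems$vertex$props, function(p) p[2], "")
    vdat <- matrix(scan(text = rest[seq_len(nv)], quiet = TRUE),
                   ncol = length(vprops), byrow = TRUE)
    xyz <- vdat[, match(c("x", "y", "z"), vprops), drop = FALSE]
    polys <- lapply(strsplit(trimws(rest[nv + seq_len(nf)]), "\\s+"), function(tok) {
      n <- as.integer(tok[1])
      as.integer(tok[1 + seq_len(n)]) + 1L
    })
    return(list(vertices = xyz, faces = fan_triangulate(polys)))
  }

  endian <- if (fmt == "binary_big_endian") "big" else "little"
  size_of <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
               short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
               int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
               float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  read_scalar <- function(type, n) {
    sz <- size_of[[type]]
    if (type %in% c("float", "float32", "double", "float64")) {
      readBin(con, "double", n = n, size = sz, endian = endian)
    } else {
      readBin(con, "integer", n = n, size = sz, endian = endian,
              signed = !(sz < 4L && grepl("^u", type)))
    }
  }
  vtypes <- vapply(elems$vertex$props, function(p) p[1], "")
  vnames <- vapply(elems$vertex$props, function(p) p[length(p)], "")
  if (any(vtypes == "list")) stop("PLY parse error: list property on vertices unsupported")
  vdat <- matrix(NA_real_, nv, length(vtypes))
  # vertex records are interleaved: read record by record is slow; read the
  # whole block as raw and slice per property instead
  rec_sizes <- size_of[vtypes]
  rec_len <- sum(rec_sizes)
  blob <- readBin(con, "raw", n = rec_len * nv)
  if (length(blob) < rec_len * nv) stop("PLY parse error: truncated vertex block")
  off <- cumsum(c(0L, rec_sizes[-length(rec_sizes)]))
  for (j in seq_along(vtypes)) {
    idx <- as.vector(outer(seq_len(rec_sizes[j]), (seq_len(nv) - 1L) * rec_len + off[j], "+"))
    sub <- blob[idx]
    sz <- rec_sizes[j]
    if (vtypes[j] %in% c("float", "float32", "double", "float64")) {
      vdat[, j] <- readBin(sub, "double", n = nv, size = sz, endian = endian)
    } else {
      vdat[, j] <- readBin(sub, "integer", n = nv, size = sz, endian = endian,
                           signed = !(sz < 4L && grepl("^u", vtypes[j])))
    }
  }
  xyz <- vdat[, match(c("x", "y", "z"), vnames), drop = FALSE]

  fprop <- elems$face$props[[1]]
  if (fprop[1] != "list") stop("PLY parse error: face element must be a list property")
  cnt_type <- fprop[2]; idx_type <- fprop[3]
  polys <- vector("list", nf)
  for (i in seq_len(nf)) {
    n <- read_scalar(cnt_type, 1L)
    polys[[i]] <- read_scalar(idx_type, n) + 1L
  }
  list(vertices = xyz, faces = fan_triangulate(polys))
}

read_stl <- function(path) {
  # binary STL: 80-byte header, uint32 count, 50 bytes per facet
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", n = 80L)
  is_binary <- FALSE
  if (sz >= 84) {
    nf <- readBin(con, "integer", size = 4L, endian = "little")
    if (!is.na(nf) && sz == 84 + 50 * nf) is_binary <- TRUE
  }
  if (is_binary) {
    blob <- readBin(con, "raw", n = 50L * nf)
    keep <- as.vector(outer(13:48, (seq_len(nf) - 1L) * 50L, "+"))
    vals <- readBin(blob[keep], "double", n = 9L * nf, size = 4L, endian = "little")
    tri <- matrix(vals, ncol = 9L, byrow = TRUE)
    v <- rbind(tri[, 1:3], tri[, 4:6], tri[, 7:9])
    ord <- as.vector(t(matrix(seq_len(3L * nf), ncol = 3L)))
    v <- v[ord, , drop = FALSE]
    f <- matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE)
    return(list(vertices = v, faces = f))
  }
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L) {
    stop("STL parse error in ", path, ": vertex count not a multiple of 3")
  }
  v <- matrix(scan(text = sub("^\\s*vertex\\s+", "", vlines), quiet = TRUE),
              ncol = 3L, byrow = TRUE)
  f <- matrix(seq_len(nrow(v)), ncol = 3L, byrow = TRUE)
  list(vertices = v, faces = f)
}

read_wrl <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("#[^\n]*", "", txt)   # strip comments
  grab_block <- function(text, keyword) {
    # returns contents of the first [ ... ] following each keyword occurrence
    out <- list()
    starts <- gregexpr(keyword, text)[[1]]
    if (starts[1] == -1L) return(out)
    for (s in starts) {
      rest <- substr(text, s, nchar(text))
      open <- regexpr("\\[", rest)
      if (open == -1L) next
      depth <- 0L; i <- open
      chars <- strsplit(rest, "")[[1]]
      for (i in seq(open, length(chars))) {
        if (chars[i] == "[") depth <- depth + 1L
        if (chars[i] == "]") {
          depth <- depth - 1L
          if (depth == 0L) break
        }
      }
      out[[length(out) + 1L]] <- substr(rest, open + 1L, i - 1L)
    }
    out
  }
  pts_blocks <- grab_block(txt, "point")
  idx_blocks <- grab_block(txt, "coordIndex")
  if (length(pts_blocks) == 0L || length(idx_blocks) == 0L) {
    stop("VRML parse error in ", path, ": no IndexedFaceSet point/coordIndex found")
  }
  verts <- list(); faces <- list(); voffset <- 0L
  for (b in seq_along(pts_blocks)) {
    pv <- scan(text = gsub(",", " ", pts_blocks[[b]]), quiet = TRUE)
    if (length(pv) %% 3L != 0L) stop("VRML parse error: point list length not multiple of 3")
    v <- matrix(pv, ncol = 3L, byrow = TRUE)
    iv <- scan(text = gsub(",", " ", idx_blocks[[min(b, length(idx_blocks))]]), quiet = TRUE)
    iv <- as.integer(iv)
    polys <- split(iv, cumsum(iv == -1L))
    polys <- lapply(polys, function(p) p[p != -1L] + 1L + voffset)
    polys <- polys[vapply(polys, length, 1L) >= 3L]
    verts[[b]] <- v
    faces[[b]] <- fan_triangulate(polys)
    voffset <- voffset + nrow(v)
  }
  list(vertices = do.call(rbind, verts), faces = do.call(rbind, faces))
}

#' Write a mesh as ASCII OBJ
#' @param mesh `tri_mesh` or `oriented_mesh`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_mesh_obj <- function(mesh, path) {
  v <- mesh_vertices(mesh)
  f <- mesh_faces(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

#' Write a mesh as ASCII PLY
#' @param mesh `tri_mesh` or `oriented_mesh`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_mesh_ply <- function(mesh, path) {
  v <- mesh_vertices(mesh)
  f <- mesh_faces(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}
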