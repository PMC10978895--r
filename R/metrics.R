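# Per-segment and per-artifact edge measurements: the sharp/blunt threshold
# from the pooled angle distribution, percent of sharp perimeter, transverse
# asymmetry of the edge cross-section, surface concavity of each face, and
# refinement (width/thickness).

#' Data-driven sharp/blunt threshold from pooled segment angles
#'
#' A Gaussian KDE (Silverman bandwidth, floored at 2 degrees) of the pooled
#' segment mean angles is scanned for its two highest local maxima at least
#' `min_sep` degrees apart; the threshold is the density minimum between
#' them. If the distribution is unimodal the conventional 120-degree default
#' is returned with a flag.
#'
#' @param segment_mean_angles pooled mean angles (degrees) across an
#'   assemblage; at least 30 values.
#' @param min_sep minimum mode separation in degrees (default 15).
#' @return list with `trough` (degrees, `NA` if unimodal), `rounded`
#'   (trough floored to a multiple of 10), `modes` (two peak locations),
#'   `unimodal`, `threshold` (rounded trough, or 120 when unimodal).
#' @export
sharp_threshold <- function(segment_mean_angles, min_sep = 15) {
  x <- segment_mean_angles[is.finite(segment_mean_angles)]
  if (length(x) < 30L) {
    stop("need at least 30 pooled segment angles; use the default 120-degree threshold")
  }
  bw <- max(stats::bw.nrd0(x), 2)
  d <- stats::density(x, bw = bw, from = 0, to = 180, n = 1801L)
  y <- d$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1L
  locmax <- locmax[y[locmax] >= 0.1 * max(y)]   # genuine peaks, not tail wiggles
  if (length(locmax) >= 2L) {
    ord <- locmax[order(y[locmax], decreasing = TRUE)]
    pair <- NULL
    for (i in seq_along(ord)[-1]) {
      if (abs(d$x[ord[i]] - d$x[ord[1]]) >= min_sep) { pair <- c(ord[1], ord[i]); break }
    }
  } else pair <- NULL
  if (is.null(pair)) {
    return(list(trough = NA_real_, rounded = NA_real_, modes = NA_real_,
                unimodal = TRUE, threshold = 120))
  }
  lo <- min(pair); hi <- max(pair)
  tr_i <- lo + which.min(y[lo:hi]) - 1L
  trough <- d$x[tr_i]
  rounded <- floor(trough / 10) * 10
  list(trough = trough, rounded = rounded,
       modes = sort(d$x[pair]), unimodal = FALSE, threshold = rounded)
}

#' Classify segments as sharp or blunt
#'
#' A segment is sharp when its mean angle is strictly below the threshold;
#' a mean exactly at the threshold counts as blunt.
#'
#' @param seg a `segmentation`.
#' @param threshold degrees (default 120).
#' @return logical vector, one entry per segment.
#' @export
classify_segments <- function(seg, threshold = 120) {
  seg$segment_means < threshold
}

# Arc length of each segment: every inter-coordinate gap (including the
# closing gap) is assigned to the segment owning its first coordinate, so the
# segment lengths partition the perimeter exactly.
segment_arc_lengths <- function(seg, outline) {
  p <- outline$coords
  n <- nrow(p)
  closed <- rbind(p, p[1L, ])
  gaps <- sqrt(rowSums(diff(closed)^2))
  bounds <- c(0L, seg$breakpoints, n)
  vapply(seq_len(length(bounds) - 1L), function(s) {
    sum(gaps[(bounds[s] + 1L):bounds[s + 1L]])
  }, 0)
}

#' Percent of perimeter that is sharp
#' @param outline an `outline3d`.
#' @param seg a `segmentation` over that outline's profile.
#' @param sharp logical per segment, from [classify_segments()].
#' @return percentage in \[0, 100\].
#' @export
percent_sharp <- function(outline, seg, sharp) {
  lens <- segment_arc_lengths(seg, outline)
  100 * sum(lens[sharp]) / sum(lens)
}

#' Transverse asymmetry of the edge around the outline
#'
#' At each band vertex the edge angle is split by the horizontal vector `h`
#' from the nearest outline coordinate toward the plan-view centroid: the
#' upper half-angle is the angle between (v - e) and `h`, the lower between
#' (o - e) and `h`, and the per-vertex asymmetry is their min/max ratio
#' (1 = symmetric section, 0 = fully plano-convex). Ratios are aggregated
#' per outline coordinate by KDE mode over the k nearest band vertices.
#'
#' @param omesh an `oriented_mesh`.
#' @param outline an `outline3d`.
#' @param faces labels from [assign_faces()].
#' @param band_mask mask from [outer_band()].
#' @param k neighbors per outline coordinate (default 100).
#' @param bw_floor minimum KDE bandwidth on the ratio scale (default 0.01).
#' @return numeric vector of per-coordinate ratios in (0, 1].
#' @export
transverse_asymmetry_profile <- function(omesh, outline, faces, band_mask, k = 100,
                                         bw_floor = 0.01) {
  v <- mesh_vertices(omesh)
  up <- which(faces == "upper")
  dn <- which(faces == "lower")
  n <- nrow(v)
  opp <- integer(n)
  opp[up] <- dn[RANN::nn2(v[dn, 1:2, drop = FALSE], v[up, 1:2, drop = FALSE], k = 1L)$nn.idx[, 1]]
  opp[dn] <- up[RANN::nn2(v[up, 1:2, drop = FALSE], v[dn, 1:2, drop = FALSE], k = 1L)$nn.idx[, 1]]
  eidx <- RANN::nn2(outline$coords, v, k = 1L)$nn.idx[, 1]
  cand <- which(band_mask & faces != "boundary")
  e <- outline$coords[eidx[cand], , drop = FALSE]
  h <- cbind(outline$plan_centroid[1] - e[, 1],
             outline$plan_centroid[2] - e[, 2], 0)
  hn <- row_norms(h)
  usable <- hn > .Machine$double.eps
  if (!all(usable)) {
    message(sprintf("transverse_asymmetry_profile: %d vertices at the plan centroid skipped",
                    sum(!usable)))
  }
  cand <- cand[usable]; e <- e[usable, , drop = FALSE]
  h <- h[usable, , drop = FALSE] / hn[usable]
  a <- v[cand, , drop = FALSE] - e
  b <- v[opp[cand], , drop = FALSE] - e
  ang_of <- function(u) {
    un <- row_norms(u)
    acos(pmin(1, pmax(-1, rowSums(u * h) / pmax(un, .Machine$double.xmin)))) * 180 / pi
  }
  half_v <- ang_of(a)
  half_o <- ang_of(b)
  ratio <- pmin(half_v, half_o) / pmax(half_v, half_o, .Machine$double.xmin)
  nnk <- min(k, length(cand))
  nn <- RANN::nn2(v[cand, , drop = FALSE], outline$coords, k = nnk)
  vapply(seq_len(nrow(outline$coords)), function(i) {
    kde_mode(ratio[nn$nn.idx[i, ]], 0, 1, 0.001, bw_floor)
  }, 0)
}

#' Per-vertex surface concavity
#'
#' For each vertex, its `k` nearest neighbors are found and only the
#' `outer_m` farthest of them (the outer ring) are compared with the center:
#' a neighbor j counts as convex ("pointing away") when
#' s = (p_j - p_i) . (n_j - n_i) exceeds `planar_eps`, concave when below
#' `-planar_eps`, planar otherwise. The value is
#' (convex + 0.5 * planar) / outer_m: 0 = entirely concave, 0.5 = planar,
#' 1 = entirely convex.
#'
#' @param omesh an `oriented_mesh` (or `tri_mesh`).
#' @param k neighborhood size (default 60).
#' @param outer_m outer-ring size (default 20).
#' @param planar_eps planarity deadband on s (default 1e-4).
#' @param faces optional face labels from [assign_faces()]. When given,
#'   each vertex's neighborhood is restricted to its own face, so the
#'   concavity of one face is never contaminated by the opposing face
#'   across the sharp edge (vertices labeled boundary use the whole mesh).
#' @return numeric vector in \[0, 1\], one value per vertex.
#' @export
vertex_concavity <- function(omesh, k = 60, outer_m = 20, planar_eps = 1e-4,
                             faces = NULL) {
  v <- mesh_vertices(omesh)
  if (k >= nrow(v)) stop("k must be smaller than the vertex count")
  if (outer_m > k) stop("outer_m cannot exceed k")
  nrm <- vertex_normals(omesh)
  out <- numeric(nrow(v))
  groups <- if (is.null(faces)) list(seq_len(nrow(v))) else {
    c(lapply(c("upper", "lower"), function(side) which(faces == side)),
      list(which(faces == "boundary")))
  }
  for (gi in seq_along(groups)) {
    idx_g <- groups[[gi]]
    if (length(idx_g) == 0L) next
    # boundary vertices (and the unrestricted case) search the whole mesh
    pool <- if (is.null(faces) || gi == 3L) seq_len(nrow(v)) else idx_g
    kk <- min(k, length(pool) - 1L)
    mm <- min(outer_m, kk)
    nn <- RANN::nn2(v[pool, , drop = FALSE], v[idx_g, , drop = FALSE], k = kk + 1L)
    ring <- matrix(pool[nn$nn.idx[, (kk + 2L - mm):(kk + 1L)]], ncol = mm)
    away <- numeric(length(idx_g)); planar <- numeric(length(idx_g))
    for (j in seq_len(mm)) {
      idx <- ring[, j]
      s <- rowSums((v[idx, , drop = FALSE] - v[idx_g, , drop = FALSE]) *
                     (nrm[idx, , drop = FALSE] - nrm[idx_g, , drop = FALSE]))
      away <- away + (s > planar_eps)
      planar <- planar + (abs(s) <= planar_eps)
    }
    out[idx_g] <- (away + 0.5 * planar) / mm
  }
  out
}

#' Surface concavity of both faces around the outline
#'
#' Per outline coordinate and per face, the KDE-mode aggregate of the
#' concavity values of the `k` nearest band vertices of that face.
#'
#' @param concavity per-vertex values from [vertex_concavity()].
#' @param omesh the `oriented_mesh`.
#' @param outline an `outline3d`.
#' @param faces labels from [assign_faces()].
#' @param band_mask mask from [outer_band()].
#' @param k neighbors per coordinate (default 100).
#' @param bw_floor minimum KDE bandwidth on the concavity scale (default 0.01).
#' @return matrix n x 2 with columns `upper`, `lower` (`NA` where a face has
#'   no band vertices).
#' @export
face_concavity_profile <- function(concavity, omesh, outline, faces, band_mask, k = 100,
                                   bw_floor = 0.01) {
  v <- mesh_vertices(omesh)
  out <- matrix(NA_real_, nrow(outline$coords), 2L,
                dimnames = list(NULL, c("upper", "lower")))
  for (side in c("upper", "lower")) {
    cand <- which(band_mask & faces == side)
    if (length(cand) == 0L) {
      message("face_concavity_profile: no band vertices on the ", side, " face")
      next
    }
    nnk <- min(k, length(cand))
    nn <- RANN::nn2(v[cand, , drop = FALSE], outline$coords, k = nnk)
    col <- if (side == "upper") 1L else 2L
    cv <- concavity[cand]
    out[, col] <- vapply(seq_len(nrow(outline$coords)), function(i) {
      kde_mode(cv[nn$nn.idx[i, ]], 0, 1, 0.001, bw_floor)
    }, 0)
  }
  out
}

#' Categorical concavity label for a pair of face values
#'
#' Values below `low` are concave, above `high` convex, otherwise planar.
#' The pair is reported in sorted order (concave before planar before
#' convex) so the label does not depend on which face is which.
#'
#' @param pair numeric length-2 (upper, lower) in \[0, 1\].
#' @param low,high category cutoffs (defaults 0.4 and 0.6).
#' @return single string such as `"concave-convex"`.
#' @export
concavity_label <- function(pair, low = 0.4, high = 0.6) {
  lab <- ifelse(pair < low, "concave", ifelse(pair > high, "convex", "planar"))
  rank <- c(concave = 1L, planar = 2L, convex = 3L)
  paste(lab[order(rank[lab])], collapse = "-")
}

#' Refinement (width / thickness) of an oriented artifact
#' @param omesh an `oriented_mesh`.
#' @return scalar x-extent / z-extent.
#' @export
refinement <- function(omesh) {
  ext <- mesh_extents(omesh)
  if (ext[3] <= 0) stop("zero thickness: cannot compute refinement")
  ext[1] / ext[3]
}

#' Assemble the per-artifact report
#'
#' Combines segmentation, per-coordinate asymmetry and concavity profiles and
#' whole-artifact summaries into one exportable record. Per-segment
#' asymmetry/concavity are means of the per-coordinate values over the
#' segment's coordinates.
#'
#' @param artifact_id identifier string.
#' @param omesh the `oriented_mesh` analyzed.
#' @param outline the `outline3d`.
#' @param profile the `edge_angle_profile`.
#' @param seg the `segmentation`.
#' @param asymmetry per-coordinate asymmetry from
#'   [transverse_asymmetry_profile()].
#' @param concavity_pair per-coordinate matrix from
#'   [face_concavity_profile()].
#' @param threshold sharp/blunt threshold in degrees (default 120).
#' @param concavity_low,concavity_high cutoffs passed to
#'   [concavity_label()].
#' @param config optional configuration snapshot to embed.
#' @return an `artifact_report`: list with `segments` (data.frame),
#'   `n_segments`, `n_sharp_edges`, `percent_sharp_perimeter`, `refinement`,
#'   `threshold`, `terminal_means_close` and `provenance`.
#' @export
build_report <- function(artifact_id, omesh, outline, profile, seg,
                         asymmetry, concavity_pair, threshold = 120,
                         concavity_low = 0.4, concavity_high = 0.6,
                         config = NULL) {
  stages <- list(omesh = omesh, outline = outline, profile = profile,
                 seg = seg, asymmetry = asymmetry,
                 concavity_pair = concavity_pair)
  missing <- names(stages)[vapply(stages, is.null, TRUE)]
  if (length(missing)) {
    stop("cannot assemble report; missing stage(s): ", paste(missing, collapse = ", "))
  }
  n <- seg$n
  bounds <- c(0L, seg$breakpoints, n)
  sharp <- classify_segments(seg, threshold)
  lens <- segment_arc_lengths(seg, outline)
  nseg <- length(seg$segment_means)
  rows <- lapply(seq_len(nseg), function(s) {
    idx <- (bounds[s] + 1L):bounds[s + 1L]
    cp <- c(mean(concavity_pair[idx, 1L], na.rm = TRUE),
            mean(concavity_pair[idx, 2L], na.rm = TRUE))
    data.frame(segment = s,
               start = bounds[s] + 1L, end = bounds[s + 1L],
               start_arc = outline$arc_pos[bounds[s] + 1L],
               arc_length = lens[s],
               mean_angle = seg$segment_means[s],
               is_sharp = sharp[s],
               asymmetry = mean(asymmetry[idx], na.rm = TRUE),
               concavity_upper = cp[1L], concavity_lower = cp[2L],
               concavity_label = concavity_label(cp, concavity_low, concavity_high))
  })
  segments <- do.call(rbind, rows)
  terminal_close <- nseg >= 2L &&
    abs(seg$segment_means[1L] - seg$segment_means[nseg]) < 5
  structure(list(
    artifact_id = artifact_id,
    segments = segments,
    n_segments = nseg,
    n_sharp_edges = sum(sharp),
    percent_sharp_perimeter = percent_sharp(outline, seg, sharp),
    refinement = refinement(omesh),
    threshold = threshold,
    mean_edge_angle = mean(profile$angle),
    perimeter = outline_perimeter(outline),
    terminal_means_close = terminal_close,
    provenance = list(config = config, ambiguous_orientation =
                        isTRUE(omesh$mesh$provenance$ambiguous_orientation))),
    class = "artifact_report")
}

#' @export
print.artifact_report <- function(x, ...) {
  cat(sprintf("<artifact_report> %s: %d segment(s), %d sharp, %.1f%% sharp perimeter\n",
              x$artifact_id, x$n_segments, x$n_sharp_edges,
              x$percent_sharp_perimeter))
  print(x$segments[, c("segment", "arc_length", "mean_angle", "is_sharp",
                       "asymmetry", "concavity_label")], row.names = FALSE)
  invisible(x)
}
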