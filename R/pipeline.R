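# Pipeline orchestration: one configuration object drives every stage from
# raw mesh to artifact report.

#' Analysis configuration
#'
#' All tunables of the pipeline in one serializable object. Every parameter
#' referenced anywhere in the pipeline appears here.
#'
#' @param target_vertices canonical mesh vertex count (default 50000).
#' @param outline_points outline coordinate count (default 1000).
#' @param band_fraction outer surface-area fraction used by CEAM
#'   (default 0.20).
#' @param k_profile neighbors per outline coordinate for profile
#'   aggregation (default 100).
#' @param k_blunt neighborhood size for blunt-region detection and z
#'   averaging (default 50).
#' @param parallel_threshold degrees from vertical at which perimeter
#'   surface counts as blunt (default 20).
#' @param alpha alpha-shape circumradius cutoff; `NULL` = automatic.
#' @param kmax maximum change points considered (default 10).
#' @param min_seg minimum segment length in coordinates (default 25).
#' @param drop_floor minimum relative residual drop to accept any change
#'   point (default 0.08).
#' @param min_mean_gap minimum spread (degrees) between segment means for a
#'   segmentation to stand; below it the profile counts as constant
#'   (default 5).
#' @param sharp_threshold sharp/blunt angle threshold in degrees
#'   (default 120).
#' @param concavity_k,concavity_outer_m,planar_eps surface concavity
#'   parameters.
#' @param concavity_low,concavity_high concave/planar/convex cutoffs.
#' @param kde_bw_floor minimum KDE bandwidth (degrees) for angle-mode
#'   aggregation (default 1).
#' @param kde_ratio_bw_floor minimum KDE bandwidth for asymmetry/concavity
#'   ratio aggregation (default 0.01).
#' @param boundary_tol face-assignment boundary tolerance.
#' @param seed integer seed recorded with every report.
#' @return a `ceam_config` (named list).
#' @export
ceam_config <- function(target_vertices = 50000,
                        outline_points = 1000,
                        band_fraction = 0.20,
                        k_profile = 100,
                        k_blunt = 50,
                        parallel_threshold = 20,
                        alpha = NULL,
                        kmax = 10,
                        min_seg = 25,
                        drop_floor = 0.08,
                        min_mean_gap = 5,
                        sharp_threshold = 120,
                        concavity_k = 60,
                        concavity_outer_m = 20,
                        planar_eps = 1e-4,
                        concavity_low = 0.4,
                        concavity_high = 0.6,
                        kde_bw_floor = 1,
                        kde_ratio_bw_floor = 0.01,
                        boundary_tol = 1e-3,
                        seed = 1) {
  cfg <- list(target_vertices = target_vertices, outline_points = outline_points,
              band_fraction = band_fraction, k_profile = k_profile,
              k_blunt = k_blunt, parallel_threshold = parallel_threshold,
              alpha = alpha, kmax = kmax, min_seg = min_seg,
              drop_floor = drop_floor, min_mean_gap = min_mean_gap,
              sharp_threshold = sharp_threshold,
              concavity_k = concavity_k, concavity_outer_m = concavity_outer_m,
              planar_eps = planar_eps, concavity_low = concavity_low,
              concavity_high = concavity_high, kde_bw_floor = kde_bw_floor,
              kde_ratio_bw_floor = kde_ratio_bw_floor,
              boundary_tol = boundary_tol, seed = seed)
  stopifnot(cfg$band_fraction > 0, cfg$band_fraction <= 1,
            cfg$outline_points >= 100, cfg$min_seg >= 1,
            cfg$kmax >= 0, cfg$sharp_threshold > 0)
  structure(cfg, class = "ceam_config")
}

#' Serialize / restore a configuration
#' @param config a `ceam_config`.
#' @param path JSON file path.
#' @return `config_to_json` returns the path invisibly; `config_from_json`
#'   returns a `ceam_config`.
#' @export
config_to_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname config_to_json
#' @export
config_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(ceam_config, raw)
}

#' Analyze a single artifact end to end
#'
#' Chains orientation, resolution and scale normalization, outline
#' detection, CEAM, segmentation, and all segment metrics.
#'
#' @param mesh a `tri_mesh`, or a file path readable by [read_mesh()].
#' @param config a [ceam_config()].
#' @param rotation optional 3 x 3 orthonormal matrix applied instead of
#'   automatic orientation.
#' @param artifact_id identifier; defaults to the file name or "artifact".
#' @return list with `report` (an `artifact_report`) and the intermediate
#'   stages (`omesh`, `outline`, `profile`, `segmentation`, `asymmetry`,
#'   `concavity_pair`, `faces`, `band`).
#' @export
analyze_artifact <- function(mesh, config = ceam_config(), rotation = NULL,
                             artifact_id = NULL) {
  if (is.character(mesh)) {
    if (is.null(artifact_id)) artifact_id <- basename(mesh)
    mesh <- read_mesh(mesh, quiet = TRUE)
  }
  if (is.null(artifact_id)) artifact_id <- "artifact"
  omesh <- orient_artifact(mesh, rotation)
  omesh <- resample_mesh(omesh, config$target_vertices)
  omesh <- rescale_mesh(omesh)
  outline <- detect_outline(omesh, alpha = config$alpha,
                            n = config$outline_points,
                            parallel_threshold = config$parallel_threshold,
                            k = config$k_blunt)
  faces <- assign_faces(omesh, outline, tol = config$boundary_tol)
  va <- vertex_edge_angles(omesh, outline, faces)
  band <- outer_band(omesh, outline, config$band_fraction)
  va$band_mask <- band
  profile <- ceam_profile(va, omesh, outline, band, k = config$k_profile,
                          bw_floor = config$kde_bw_floor)
  seg <- segment_profile(profile, kmax = config$kmax, min_seg = config$min_seg,
                         drop_floor = config$drop_floor,
                         min_mean_gap = config$min_mean_gap)
  asym <- transverse_asymmetry_profile(omesh, outline, faces, band,
                                       k = config$k_profile,
                                       bw_floor = config$kde_ratio_bw_floor)
  conc <- vertex_concavity(omesh, k = config$concavity_k,
                           outer_m = config$concavity_outer_m,
                           planar_eps = config$planar_eps, faces = faces)
  cpair <- face_concavity_profile(conc, omesh, outline, faces, band,
                                  k = config$k_profile,
                                  bw_floor = config$kde_ratio_bw_floor)
  report <- build_report(artifact_id, omesh, outline, profile, seg,
                         asym, cpair, threshold = config$sharp_threshold,
                         concavity_low = config$concavity_low,
                         concavity_high = config$concavity_high,
                         config = unclass(config))
  list(report = report, omesh = omesh, outline = outline, profile = profile,
       segmentation = seg, asymmetry = asym, concavity_pair = cpair,
       faces = faces, band = band)
}
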