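#' Specify a synthetic nurse-cell-like scene
#'
#' A `scene_spec` fixes everything the generator needs: field geometry,
#' condensate number and shape statistics, organelle geometry, the planted
#' fraction of organelle-associated condensates, motion and fission
#' parameters for time series, paired 5'/3' probe parameters, an optional
#' bleach event, the optical blur, and the noise model. Defaults follow the
#' acquisition this pipeline emulates: anisotropic voxels with 0.3 um
#' optical Z sections, a 15 s frame cadence, condensate volumes in the
#' 0.05-1 um^3 range, and 0.2 um diameter diffraction-limited spots.
#'
#' @param field_size_um physical field size `(z, y, x)` in um.
#' @param voxel_size_um voxel pitch `(z, y, x)` in um; Z defaults to 0.3.
#' @param n_condensates number of condensates to plant.
#' @param volume_dist log-normal volume distribution: `mean_um3`, `sd_um3`,
#'   truncated to `[min_um3, max_um3]`.
#' @param aspect_ratio_dist log-normal aspect-ratio distribution (`mean`,
#'   `sd`), truncated at 1 (prolate spheroids, long axis random).
#' @param texture_roughness amplitude of multiplicative band-limited
#'   intensity speckle inside condensates, relative to the mean (0 =
#'   perfectly smooth).
#' @param organelle list: `geometry` one of `"tubular_network"`, `"puncta"`,
#'   `"none"`, plus density parameters (`n_puncta`, `radius_um` for puncta;
#'   `n_tubes`, `tube_radius_um`, `tube_step_um`, `n_steps` for tubes).
#' @param association_fraction planted fraction of condensates touching the
#'   organelle mask (exact count `round(fraction * n)`).
#' @param motion list: `fraction_directed`, `speed_directed_um_s`,
#'   `diffusion_coeff_um2_s`, `frame_interval_s` (default 15),
#'   `n_frames` (default 20, at most 120).
#' @param fission_rate fission events per object per frame.
#' @param probe_spec list: `n_transcripts`, `intact_fraction`,
#'   `orphan5_fraction`, `orphan3_fraction` (must sum to 1),
#'   `spot_sigma_um`.
#' @param bleach optional list: `roi` (named list of `z_um`, `y_um`, `x_um`
#'   ranges), `frame`, `residual` (default 0.05).
#' @param psf_sigma_um Gaussian PSF sigma `(z, y, x)` in um.
#' @param noise list: `poisson_scale` (shot noise; intensity I becomes
#'   `Poisson(scale * I) / scale`) and `gaussian_sd` (read noise).
#' @param intensity list of ideal intensity levels (`background`,
#'   `condensate`, `organelle`, `spot`), in camera counts.
#' @param placement_clearance_um minimum bounding-sphere gap between
#'   planted condensates (default twice the largest voxel pitch); raise it
#'   in sparse time-lapse scenes so diffusing objects cannot drift into
#'   apparent contact.
#' @param seed integer; the single seed every stochastic draw flows from.
#' @return a validated list of class `scene_spec`.
#' @export
scene_spec <- function(field_size_um = c(3, 20, 20),
                       voxel_size_um = c(0.3, 0.1, 0.1),
                       n_condensates = 40,
                       volume_dist = list(),
                       aspect_ratio_dist = list(),
                       texture_roughness = 0.05,
                       organelle = list(),
                       association_fraction = 0.3,
                       motion = list(),
                       fission_rate = 0,
                       probe_spec = list(),
                       bleach = NULL,
                       psf_sigma_um = c(0.25, 0.08, 0.08),
                       noise = list(),
                       intensity = list(),
                       placement_clearance_um = NULL,
                       seed = 1L) {
  spec <- list(
    field_size_um = as.numeric(field_size_um),
    voxel_size_um = as.numeric(voxel_size_um),
    n_condensates = as.integer(n_condensates),
    volume_dist = modifyList(
      list(mean_um3 = 0.3, sd_um3 = 0.25, min_um3 = 0.06, max_um3 = 1.0),
      as.list(volume_dist)),
    aspect_ratio_dist = modifyList(list(mean = 1.3, sd = 0.25),
                                   as.list(aspect_ratio_dist)),
    texture_roughness = as.numeric(texture_roughness),
    organelle = modifyList(
      list(geometry = "puncta", n_puncta = 60, radius_um = 0.25,
           n_tubes = 6, tube_radius_um = 0.15, tube_step_um = 0.5,
           n_steps = 60),
      as.list(organelle)),
    association_fraction = as.numeric(association_fraction),
    motion = modifyList(
      list(fraction_directed = 0.5, speed_directed_um_s = 0.05,
           diffusion_coeff_um2_s = 0.002, frame_interval_s = 15,
           n_frames = 20L),
      as.list(motion)),
    fission_rate = as.numeric(fission_rate),
    probe_spec = modifyList(
      list(n_transcripts = 300L, intact_fraction = 0.9,
           orphan5_fraction = 0.05, orphan3_fraction = 0.05,
           spot_sigma_um = 0.1),
      as.list(probe_spec)),
    bleach = bleach,
    psf_sigma_um = as.numeric(psf_sigma_um),
    noise = modifyList(list(poisson_scale = 0.25, gaussian_sd = 8),
                       as.list(noise)),
    intensity = modifyList(
      list(background = 100, condensate = 3000, organelle = 2500,
           spot = 3000),
      as.list(intensity)),
    placement_clearance_um =
      if (is.null(placement_clearance_um)) 2 * max(as.numeric(voxel_size_um))
      else as.numeric(placement_clearance_um),
    seed = as.integer(seed))
  validate_scene_spec(spec)
  structure(spec, class = "scene_spec")
}

validate_scene_spec <- function(spec) {
  if (length(spec$field_size_um) != 3 || any(spec$field_size_um <= 0))
    stop("field_size_um must be 3 positive values (z, y, x)")
  if (length(spec$voxel_size_um) != 3 || any(spec$voxel_size_um <= 0))
    stop("voxel_size_um must be 3 positive values (z, y, x)")
  if (spec$n_condensates < 0) stop("n_condensates must be >= 0")
  fr <- c(spec$association_fraction, spec$motion$fraction_directed,
          spec$probe_spec$intact_fraction, spec$probe_spec$orphan5_fraction,
          spec$probe_spec$orphan3_fraction)
  if (any(fr < 0 | fr > 1)) stop("all fractions must be in [0, 1]")
  ps <- spec$probe_spec
  if (abs(ps$intact_fraction + ps$orphan5_fraction + ps$orphan3_fraction -
          1) > 1e-9)
    stop("intact + orphan5 + orphan3 fractions must sum to 1")
  if (spec$motion$frame_interval_s <= 0) stop("frame_interval_s must be > 0")
  if (spec$motion$n_frames < 1 || spec$motion$n_frames > 120)
    stop("n_frames must be in [1, 120]")
  if (!spec$organelle$geometry %in% c("tubular_network", "puncta", "none"))
    stop("organelle geometry must be tubular_network, puncta or none")
  if (spec$texture_roughness < 0) stop("texture_roughness must be >= 0")
  if (spec$fission_rate < 0) stop("fission_rate must be >= 0")
  if (!is.null(spec$bleach)) {
    b <- spec$bleach
    if (is.null(b$roi) || is.null(b$frame))
      stop("bleach needs `roi` and `frame`")
    if (is.null(b$residual)) spec$bleach$residual <- 0.05
  }
  invisible(spec)
}

#' Write / read a scene specification as YAML
#'
#' @param spec a [scene_spec].
#' @param path file path.
#' @return `read_scene_spec` returns a validated `scene_spec`.
#' @export
write_scene_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(scene_spec, y)
}
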