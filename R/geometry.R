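#' Fan-beam acquisition geometry
#'
#' Describes the rotating-gantry fan-beam acquisition shared by the forward
#' projector and the reconstructor: source-to-isocenter and source-to-detector
#' distances, gantry arc, number of views, and the flat detector (bin count
#' and pitch). The default detector width is collimated so that the field of
#' view (FOV) at the isocenter is 208 mm; the full 1024-bin panel remains
#' available by passing `detector_bins = 1024`.
#'
#' @param source_to_isocenter mm (default 1172).
#' @param source_to_detector mm (default 1672).
#' @param arc_degrees gantry sweep (default 220); must satisfy the short-scan
#'   condition `arc >= 180 + 2 * half-fan-angle`.
#' @param n_views number of projections over the arc (default 500).
#' @param detector_pitch detector bin pitch in mm (default 0.388).
#' @param detector_bins number of active detector bins; default collimates
#'   the panel to a 208-mm isocenter FOV.
#' @return an object of class `cbct_geometry` with derived fields:
#'   `sdet` (virtual-detector bin coordinates at the isocenter, mm),
#'   `view_angles_deg`, `fov_mm` (FOV diameter at isocenter), and
#'   `half_fan_deg`.
#' @export
cbct_geometry <- function(source_to_isocenter = 1172,
                          source_to_detector = 1672,
                          arc_degrees = 220,
                          n_views = 500,
                          detector_pitch = 0.388,
                          detector_bins = NULL) {
  if (source_to_detector <= source_to_isocenter || source_to_isocenter <= 0)
    stop("need source_to_detector > source_to_isocenter > 0")
  mag <- source_to_isocenter / source_to_detector
  if (is.null(detector_bins)) {
    active_width <- 208 / mag            # panel width giving a 208-mm FOV
    detector_bins <- round(active_width / detector_pitch)
  }
  pitch_iso <- detector_pitch * mag      # bin pitch on the virtual detector
  sdet <- (seq_len(detector_bins) - (detector_bins + 1) / 2) * pitch_iso
  half_fan <- atan(max(abs(sdet)) / source_to_isocenter)
  if (arc_degrees < 180 + 2 * half_fan * 180 / pi)
    stop(sprintf("arc %g deg below short-scan minimum %.1f deg", arc_degrees,
                 180 + 2 * half_fan * 180 / pi))
  view_angles <- (seq_len(n_views) - 1) * arc_degrees / n_views
  structure(list(source_to_isocenter = source_to_isocenter,
                 source_to_detector = source_to_detector,
                 arc_degrees = arc_degrees, n_views = n_views,
                 detector_pitch = detector_pitch,
                 detector_bins = detector_bins,
                 pitch_iso = pitch_iso, sdet = sdet,
                 view_angles_deg = view_angles,
                 half_fan_deg = half_fan * 180 / pi,
                 fov_mm = 2 * max(abs(sdet))),
            class = "cbct_geometry")
}

#' @export
print.cbct_geometry <- function(x, ...) {
  cat(sprintf(paste0("<cbct_geometry> SID %g mm, SDD %g mm, arc %g deg, ",
                     "%d views, %d bins @ %.3f mm (FOV %.1f mm)\n"),
              x$source_to_isocenter, x$source_to_detector, x$arc_degrees,
              x$n_views, x$detector_bins, x$detector_pitch, x$fov_mm))
  invisible(x)
}

#' Projection-domain physics configuration
#'
#' Parametric scatter / beam-hardening / noise model applied to clean
#' line-integral projections. `(0, 1, 0)` is the exact identity.
#'
#' @param scatter_factor amplitude of the additive low-frequency scatter
#'   intensity term (default 0.001).
#' @param beam_hardening_factor exponent parameter of the compressive
#'   power-law on post-log attenuation (default 1.005; 1 is a no-op).
#' @param noise_factor SD of Gaussian intensity noise relative to the open
#'   field I0 (default 0.001).
#' @param scatter_kernel_width Gaussian smoothing width (mm, at the virtual
#'   detector) of the scatter term (default 100).
#' @param intensity_floor lower clip for intensities before the log, as a
#'   fraction of I0.
#' @return a list of class `physics_config`.
#' @export
physics_config <- function(scatter_factor = 0.001,
                           beam_hardening_factor = 1.005,
                           noise_factor = 0.001,
                           scatter_kernel_width = 100,
                           intensity_floor = 1e-6) {
  if (scatter_factor < 0 || noise_factor < 0)
    stop("scatter_factor and noise_factor must be >= 0")
  if (beam_hardening_factor < 1)
    stop("beam_hardening_factor must be >= 1")
  structure(list(scatter_factor = scatter_factor,
                 beam_hardening_factor = beam_hardening_factor,
                 noise_factor = noise_factor,
                 scatter_kernel_width = scatter_kernel_width,
                 intensity_floor = intensity_floor),
            class = "physics_config")
}
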