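#' Parametric carotid-bifurcation parameters
#'
#' The full parameter set describing a planar-symmetric carotid artery
#' bifurcation (CAB): a tapering common carotid (CCA) that splits into the
#' internal carotid (ICA), carrying the sinus bulge, and the external carotid
#' (ECA). All lengths in meters, angles in degrees from the CCA axis.
#'
#' Defaults not fixed by anatomy literature are explicit, documented
#' choices: the sinus peaks at 1.1x the CCA inlet diameter over a length of
#' 3 ICA diameters, the CCA tapers linearly to 0.9x its inlet diameter, the
#' ECA is 0.7x the CCA inlet, the entry extension is 3 inlet diameters and
#' each exit extension 8 local diameters (long enough to keep outlet effects
#' away from the bifurcation).
#'
#' @param cca_inlet_diameter CCA inlet diameter (m); 6.5 mm default.
#' @param ica_cca_diameter_ratio ICA/CCA diameter ratio (ICA measured
#'   downstream of the sinus, CCA at the inlet), in (0, 1].
#' @param ica_branch_angle,eca_branch_angle branch angles from the CCA axis
#'   (degrees), in (0, 90).
#' @param sinus_max_diameter maximum sinus diameter (m); must be >= the ICA
#'   downstream diameter.
#' @param sinus_length axial length of the sinus bulge (m).
#' @param cca_taper_ratio CCA diameter ratio bifurcation/inlet, in (0, 1].
#' @param entry_length,ica_exit_length,eca_exit_length extension lengths (m).
#' @param eca_diameter ECA diameter (m).
#' @param sinus_offset arc distance from the apex to the sinus start (m).
#' @param fillet_radius smoothing length of the branch blend at the apex (m).
#' @return Object of class `cab_parameters` (a validated named list).
#' @export
cab_parameters <- function(cca_inlet_diameter = 6.5e-3,
                           ica_cca_diameter_ratio = 0.7,
                           ica_branch_angle = 30,
                           eca_branch_angle = 30,
                           sinus_max_diameter = 1.1 * cca_inlet_diameter,
                           sinus_length = 3 * ica_cca_diameter_ratio * cca_inlet_diameter,
                           cca_taper_ratio = 0.9,
                           entry_length = 3 * cca_inlet_diameter,
                           ica_exit_length = 8 * ica_cca_diameter_ratio * cca_inlet_diameter,
                           eca_exit_length = 8 * eca_diameter,
                           eca_diameter = 0.7 * cca_inlet_diameter,
                           sinus_offset = 0.6 * cca_inlet_diameter,
                           fillet_radius = 0.2 * cca_inlet_diameter / 2) {
  p <- list(cca_inlet_diameter = cca_inlet_diameter,
            ica_cca_diameter_ratio = ica_cca_diameter_ratio,
            ica_branch_angle = ica_branch_angle,
            eca_branch_angle = eca_branch_angle,
            sinus_max_diameter = sinus_max_diameter,
            sinus_length = sinus_length,
            cca_taper_ratio = cca_taper_ratio,
            entry_length = entry_length,
            ica_exit_length = ica_exit_length,
            eca_exit_length = eca_exit_length,
            eca_diameter = eca_diameter,
            sinus_offset = sinus_offset,
            fillet_radius = fillet_radius)
  validate_cab_parameters(p)
  structure(p, class = "cab_parameters")
}

#' @rdname cab_parameters
#' @param p a parameter list to validate.
#' @export
validate_cab_parameters <- function(p) {
  lens <- c("cca_inlet_diameter", "sinus_max_diameter", "sinus_length",
            "entry_length", "ica_exit_length", "eca_exit_length",
            "eca_diameter", "sinus_offset", "fillet_radius")
  for (f in lens) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) || p[[f]] <= 0) {
      stop("invalid parameter `", f, "`: must be a positive length (m)")
    }
  }
  if (!(p$ica_cca_diameter_ratio > 0 && p$ica_cca_diameter_ratio <= 1)) {
    stop("invalid parameter `ica_cca_diameter_ratio`: must be in (0, 1]")
  }
  if (!(p$cca_taper_ratio > 0 && p$cca_taper_ratio <= 1)) {
    stop("invalid parameter `cca_taper_ratio`: must be in (0, 1]")
  }
  for (f in c("ica_branch_angle", "eca_branch_angle")) {
    if (!(p[[f]] > 0 && p[[f]] < 90)) {
      stop("invalid parameter `", f, "`: must be in (0, 90) degrees")
    }
  }
  d_ica <- p$ica_cca_diameter_ratio * p$cca_inlet_diameter
  if (p$sinus_max_diameter < d_ica) {
    stop("invalid parameter `sinus_max_diameter`: must be >= the ICA ",
         "downstream diameter (", format(d_ica), " m)")
  }
  invisible(TRUE)
}

#' Packaged anatomical presets
#'
#' `"healthy"`: symmetric 60 degree total bifurcation (ICA and ECA at 30
#' degrees each) with ICA/CCA diameter ratio 0.7. `"predisposed"`: the
#' anatomy with the two clinical risk factors, an ICA angle widened to 45
#' degrees (75 degrees total) and the ICA/CCA ratio reduced to 0.5; CCA and
#' ECA are unchanged.
#'
#' @param name `"healthy"` or `"predisposed"`.
#' @param ... overrides forwarded to [cab_parameters()].
#' @return A `cab_parameters` object.
#' @export
cab_preset <- function(name = c("healthy", "predisposed"), ...) {
  name <- match.arg(name)
  if (name == "healthy") {
    cab_parameters(ica_branch_angle = 30, eca_branch_angle = 30,
                   ica_cca_diameter_ratio = 0.7, ...)
  } else {
    cab_parameters(ica_branch_angle = 45, eca_branch_angle = 30,
                   ica_cca_diameter_ratio = 0.5, ...)
  }
}

#' @export
print.cab_parameters <- function(x, ...) {
  cat(sprintf(paste0("CAB parameters: inlet %.2f mm, ICA/CCA ratio %.2f, ",
                     "ICA %g deg / ECA %g deg (total %g deg), sinus max %.2f mm\n"),
              1e3 * x$cca_inlet_diameter, x$ica_cca_diameter_ratio,
              x$ica_branch_angle, x$eca_branch_angle,
              x$ica_branch_angle + x$eca_branch_angle,
              1e3 * x$sinus_max_diameter))
  invisible(x)
}
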