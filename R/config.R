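# Run configuration. Flat list of documented keys with stable defaults;
# unknown keys are rejected so typos fail loudly.

#' Analysis configuration
#'
#' All tunable numerics and policies of the pipeline. Keys mirror the
#' dotted names used in YAML config files (`fit.tolerance` etc.).
#'
#' @param fit.tolerance convergence tolerance of the geometric fits.
#' @param fit.max_iter iteration cap of the geometric fits.
#' @param mesh.merge_eps_mm vertex merge tolerance on mesh read (mm).
#' @param center.femoral_intersection_scope `"bone"` (default) intersects the
#'   condylar axis with the whole femur; `"condyle_regions"` restricts to the
#'   labeled condyles.
#' @param extension.tolerance_deg convergence tolerance of virtual extension
#'   (degrees).
#' @param extension.max_iter iteration cap of virtual extension.
#' @param angles.extension_policy `"auto"` runs virtual extension when the
#'   sagittal residual exceeds `angles.extension_threshold_deg`; `"strict"`
#'   errors instead; `"ignore"` computes with a warning.
#' @param angles.extension_threshold_deg residual (degrees) above which the
#'   extension policy engages.
#' @param sfj.mode `"three_point"` (figure construction: one most-proximal
#'   point per region) or `"border_band"` (least-squares plane on the top 2%
#'   z-band of each region).
#' @param orientation.hint 3 x 3 matrix; rows are the approximate patient
#'   right, anterior and cranial directions of the scanner frame.
#' @param units.scale multiplicative rescale applied to input coordinates
#'   (inputs are assumed millimetres; this only rescales, never guesses).
#' @return a `legalign_config` list.
#' @export
legalign_config <- function(fit.tolerance = 1e-10,
                            fit.max_iter = 200L,
                            mesh.merge_eps_mm = 1e-6,
                            center.femoral_intersection_scope = c("bone", "condyle_regions"),
                            extension.tolerance_deg = 0.01,
                            extension.max_iter = 50L,
                            angles.extension_policy = c("auto", "strict", "ignore"),
                            angles.extension_threshold_deg = 0.5,
                            sfj.mode = c("three_point", "border_band"),
                            orientation.hint = diag(3),
                            units.scale = 1) {
  cfg <- list(
    fit.tolerance = fit.tolerance,
    fit.max_iter = as.integer(fit.max_iter),
    mesh.merge_eps_mm = mesh.merge_eps_mm,
    center.femoral_intersection_scope = match.arg(center.femoral_intersection_scope),
    extension.tolerance_deg = extension.tolerance_deg,
    extension.max_iter = as.integer(extension.max_iter),
    angles.extension_policy = match.arg(angles.extension_policy),
    angles.extension_threshold_deg = angles.extension_threshold_deg,
    sfj.mode = match.arg(sfj.mode),
    orientation.hint = validate_hint(orientation.hint),
    units.scale = units.scale
  )
  structure(cfg, class = "legalign_config")
}

validate_hint <- function(hint) {
  hint <- as.matrix(hint)
  if (!all(dim(hint) == c(3, 3)) || !all(is.finite(hint))) {
    stop_legalign("orientation.hint must be a finite 3x3 matrix (rows: right, anterior, cranial)",
                  "legalign_config_error")
  }
  if (abs(det(hint)) < 1e-6) {
    stop_legalign("orientation.hint rows must be linearly independent",
                  "legalign_config_error")
  }
  hint
}

#' Build a configuration from a named list (e.g. parsed YAML)
#'
#' Unknown keys are rejected. The orientation hint may be given as nine
#' numbers, row-wise right/anterior/cranial.
#'
#' @param x named list of config keys.
#' @return a [legalign_config()].
#' @export
as_legalign_config <- function(x = list()) {
  if (inherits(x, "legalign_config")) return(x)
  defaults <- legalign_config()
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown)) {
    stop_legalign(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
                  "legalign_config_error")
  }
  if (!is.null(x$orientation.hint)) {
    x$orientation.hint <- matrix(as.numeric(unlist(x$orientation.hint)), 3, 3,
                                 byrow = TRUE)
  }
  do.call(legalign_config, x)
}

config_digest <- function(cfg) {
  digest::digest(unclass(cfg), algo = "sha256")
}
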