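# Alignment report: the eight consensus angles plus residuals and provenance.

ANGLE_NAMES <- c("HKAA", "mLDFA", "mMPTA", "mPDFA", "mMPPTA", "mLPPTA", "FVA", "TTA")
REPORT_SCHEMA <- "legalign-report-1"

new_report <- function(angles, directions, extension_residual_deg,
                       initial_extension_residual_deg, side, fit_residuals,
                       femur = NULL, tibfib = NULL, config = NULL,
                       assembly = NULL, orientations = NULL,
                       metadata = NULL) {
  angles <- angles[ANGLE_NAMES]
  metadata <- metadata %||% list(
    tool = "legalign",
    version = as.character(packageVersion("legalign")),
    side = side,
    femur_digest = if (!is.null(femur)) digest::digest(femur[c("mesh", "regions")]),
    tibfib_digest = if (!is.null(tibfib)) digest::digest(tibfib[c("mesh", "regions")]),
    config_digest = if (!is.null(config)) config_digest(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  report <- structure(list(
    angles_deg = angles,
    directions = directions,
    extension_residual_deg = extension_residual_deg,
    initial_extension_residual_deg = initial_extension_residual_deg,
    side = side,
    fit_residuals_mm = fit_residuals,
    metadata = metadata,
    assembly = assembly,
    orientations = orientations
  ), class = "legalign_report")
  validate_report(report)
  report
}

validate_report <- function(report) {
  a <- report$angles_deg
  if (any(!is.finite(a))) {
    stop_legalign("report contains non-finite angles", "legalign_validation_error")
  }
  checks <- list(
    HKAA = c(90, 270), mLDFA = c(45, 135), mMPTA = c(45, 135),
    FVA = c(0, 90), TTA = c(0, 90)
  )
  for (nm in names(checks)) {
    lo <- checks[[nm]][1]; hi <- checks[[nm]][2]
    ok <- if (nm %in% c("FVA", "TTA")) a[nm] >= lo && a[nm] <= hi
          else a[nm] > lo && a[nm] < hi
    if (!ok) {
      stop_legalign(sprintf("%s = %.2f deg outside plausible range (%g, %g)",
                            nm, a[nm], lo, hi), "legalign_validation_error")
    }
  }
  if (report$extension_residual_deg < 0) {
    stop_legalign("extension residual must be non-negative", "legalign_validation_error")
  }
  invisible(report)
}

#' @export
print.legalign_report <- function(x, ...) {
  cat(sprintf("3D leg alignment report (%s leg)\n", tolower(x$side)))
  cat(sprintf("  extension residual: %.3f deg\n\n", x$extension_residual_deg))
  lab <- c(HKAA = "hip-knee-ankle angle", mLDFA = "lateral distal femoral angle",
           mMPTA = "medial proximal tibial angle",
           mPDFA = "posterior distal femoral angle",
           mMPPTA = "medial posterior proximal tibial angle",
           mLPPTA = "lateral posterior proximal tibial angle",
           FVA = "femoral version", TTA = "tibial torsion")
  for (nm in ANGLE_NAMES) {
    extra <- ""
    if (nm == "FVA") extra <- sprintf(" (%s)", x$directions[["FVA"]])
    if (nm == "TTA") extra <- sprintf(" (%s)", x$directions[["TTA"]])
    cat(sprintf("  %-7s %7.2f deg%s  [%s]\n", nm, x$angles_deg[[nm]], extra, lab[[nm]]))
  }
  invisible(x)
}

#' Tidy an alignment report
#'
#' @param x a `legalign_report` from [analyze_leg()].
#' @param ... unused.
#' @return a tibble with one row per angle: `angle`, `value_deg`, `direction`
#'   (version/torsion labels, `NA` otherwise).
#' @method tidy legalign_report
#' @export
tidy.legalign_report <- function(x, ...) {
  tibble::tibble(
    angle = ANGLE_NAMES,
    value_deg = as.numeric(x$angles_deg[ANGLE_NAMES]),
    direction = c(rep(NA_character_, 6), x$directions[["FVA"]], x$directions[["TTA"]])
  )
}

#' @rdname tidy.legalign_report
#' @return `glance()`: a one-row tibble with all angles, labels, the extension
#'   residual and the worst fit rms.
#' @method glance legalign_report
#' @export
glance.legalign_report <- function(x, ...) {
  out <- tibble::as_tibble(as.list(x$angles_deg))
  out$FVA_direction <- x$directions[["FVA"]]
  out$TTA_direction <- x$directions[["TTA"]]
  out$extension_residual_deg <- x$extension_residual_deg
  out$max_fit_rms_mm <- max(x$fit_residuals_mm)
  out$side <- x$side
  out
}

#' Plot an alignment report
#'
#' Dot plot of the measured angles against their neutral references
#' (180 for HKAA, 90 for the joint-orientation angles; version/torsion have
#' no neutral reference line).
#'
#' @param object a `legalign_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot legalign_report
#' @export
autoplot.legalign_report <- function(object, ...) {
  df <- tidy(object)
  df$neutral <- c(180, 90, 90, 90, 90, 90, NA, NA)
  df$angle <- factor(df$angle, levels = rev(ANGLE_NAMES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value_deg, y = .data$angle)) +
    ggplot2::geom_segment(
      data = df[!is.na(df$neutral), ],
      ggplot2::aes(x = .data$neutral, xend = .data$value_deg,
                   y = .data$angle, yend = .data$angle),
      linewidth = 0.4, colour = "grey55") +
    ggplot2::geom_point(size = 2.4, colour = "#2166ac") +
    ggplot2::geom_point(data = df[!is.na(df$neutral), ],
                        ggplot2::aes(x = .data$neutral), shape = 3,
                        colour = "grey40") +
    ggplot2::labs(x = "angle (degrees)", y = NULL,
                  title = sprintf("Leg alignment (%s)", tolower(object$side)),
                  subtitle = "crosses mark neutral references") +
    ggplot2::theme_minimal()
}

# --- report I/O -------------------------------------------------------------

report_to_list <- function(report) {
  list(
    schema = REPORT_SCHEMA,
    angles_deg = as.list(report$angles_deg),
    directions = as.list(report$directions),
    extension_residual_deg = report$extension_residual_deg,
    initial_extension_residual_deg = report$initial_extension_residual_deg,
    side = report$side,
    fit_residuals_mm = as.list(report$fit_residuals_mm),
    metadata = report$metadata
  )
}

#' Write an alignment report
#'
#' JSON re-reads bit-exactly (full double precision); the CSV twin has one
#' data row with the documented header.
#'
#' @param report a `legalign_report`.
#' @param path output file.
#' @param format `"JSON"` or `"CSV"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = NULL) {
  validate_report(report)
  format <- toupper(format %||% tools::file_ext(path))
  if (!format %in% c("JSON", "CSV")) {
    stop_legalign(sprintf("unsupported report format '%s'", format),
                  "legalign_format_error")
  }
  ok <- tryCatch({
    if (format == "JSON") {
      # digits = I(17) keeps IEEE doubles bit-exact across the round trip
      jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                           digits = I(17), null = "null", pretty = TRUE)
    } else {
      row <- c(as.list(report$angles_deg),
               FVA_direction = report$directions[["FVA"]],
               TTA_direction = report$directions[["TTA"]],
               extension_residual_deg = report$extension_residual_deg,
               side = report$side,
               as.list(setNames(report$fit_residuals_mm,
                                paste0("rms_", names(report$fit_residuals_mm)))))
      write.csv(as.data.frame(row, check.names = FALSE), path, row.names = FALSE)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_legalign(sprintf("cannot write report to %s: %s", path,
                          conditionMessage(ok)), "legalign_io_error")
  }
  invisible(path)
}

#' Read a JSON alignment report
#'
#' @param path report JSON file.
#' @return a `legalign_report` (without the in-memory assembly).
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, REPORT_SCHEMA)) {
    stop_legalign(sprintf("report file %s has schema '%s', expected '%s'",
                          path, doc$schema %||% "<none>", REPORT_SCHEMA),
                  "legalign_format_error")
  }
  new_report(angles = unlist(doc$angles_deg),
             directions = unlist(doc$directions),
             extension_residual_deg = doc$extension_residual_deg,
             initial_extension_residual_deg = doc$initial_extension_residual_deg,
             side = doc$side,
             fit_residuals = unlist(doc$fit_residuals_mm),
             metadata = doc$metadata)
}
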