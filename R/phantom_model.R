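#' Material HU window
#'
#' A named HU threshold window used to segment one pin material. One side may
#' be unbounded (`-Inf`/`Inf`); membership is closed on finite sides.
#'
#' @param material_name label, e.g. "Bone"
#' @param lower_hu lower threshold (HU) or -Inf
#' @param upper_hu upper threshold (HU) or Inf
#' @param nominal_hu expected CT number (HU), or NA when the phantom
#'   documentation gives none
#' @param expected_angle_deg approximate polar angle of the pin in the
#'   phantom layout (degrees, counter-clockwise from +col axis about the body
#'   center), or NA; used to disambiguate materials whose HU windows overlap
#' @return object of class `material_window`
#' @export
material_window <- function(material_name, lower_hu, upper_hu,
                            nominal_hu = NA_real_,
                            expected_angle_deg = NA_real_) {
  if (!is.finite(lower_hu) && !is.finite(upper_hu))
    stop_ttfqa("at least one of lower_hu/upper_hu must be finite",
               "ttfqa_bad_template")
  if (is.finite(lower_hu) && is.finite(upper_hu) && lower_hu >= upper_hu)
    stop_ttfqa("lower_hu must be < upper_hu", "ttfqa_bad_template")
  structure(list(material_name = material_name,
                 lower_hu = lower_hu, upper_hu = upper_hu,
                 nominal_hu = nominal_hu,
                 expected_angle_deg = expected_angle_deg),
            class = "material_window")
}

new_phantom_template <- function(name, windows, body_threshold_hu = -200,
                                 nominal_pin_radius_mm = 12) {
  nm <- vapply(windows, `[[`, "", "material_name")
  if (anyDuplicated(nm))
    stop_ttfqa("material names must be distinct", "ttfqa_bad_template")
  structure(list(name = name, windows = windows,
                 expected_pin_count = length(windows),
                 body_threshold_hu = body_threshold_hu,
                 nominal_pin_radius_mm = nominal_pin_radius_mm),
            class = "phantom_template")
}

#' @export
print.phantom_template <- function(x, ...) {
  cat(sprintf("<phantom_template> %s: %d pins, body threshold %g HU\n",
              x$name, x$expected_pin_count, x$body_threshold_hu))
  for (w in x$windows)
    cat(sprintf("  %-22s [%s, %s] HU%s\n", w$material_name,
                format(w$lower_hu), format(w$upper_hu),
                if (is.finite(w$nominal_hu))
                  sprintf(" (nominal %g)", w$nominal_hu) else ""))
  invisible(x)
}

# Segmentation windows for the four supported phantom families. The
# computational phantom mirrors the ACR 464 multi-pin module. Catphan 604
# Delrin: the vendor CT-number range is printed inconsistently in some
# documentation; the operative values here are the threshold columns
# (300-430 HU).
.template_registry <- function() {
  acr_windows <- list(
    material_window("Bone",          750,  1300, nominal_hu = 955),
    material_window("Polyethylene", -120,   -70, nominal_hu = -95),
    material_window("Air",          -Inf,  -800, nominal_hu = -1000),
    material_window("Acrylic",       100,   150, nominal_hu = 120))
  aapm_windows <- list(
    material_window("Acrylic",        80, 165, expected_angle_deg = 90),
    material_window("Polycarbonate", 100, 114, expected_angle_deg = 162),
    material_window("Polyethylene", -110, -60, expected_angle_deg = 234),
    material_window("Polystyrene",   -55, -20, expected_angle_deg = 306),
    material_window("Nylon",          80, 115, expected_angle_deg = 18))
  catphan_windows <- list(
    material_window("Air",         -Inf, -900, nominal_hu = -1016),
    material_window("PMP",         -250, -160, nominal_hu = -196),
    material_window("LDPE",        -121,  -87, nominal_hu = -104),
    material_window("Polystyrene",  -65,  -10, nominal_hu = -47),
    material_window("Acrylic",       80,  150, nominal_hu = 114.5),
    material_window("Bone 20%",     200,  280, nominal_hu = 237),
    material_window("Delrin",       300,  430, nominal_hu = 365),
    material_window("Bone 50%",     600,  800, nominal_hu = 725),
    material_window("Teflon",       900,  Inf, nominal_hu = 1000))
  list(
    computational_acr = new_phantom_template(
      "computational_acr", acr_windows, nominal_pin_radius_mm = 12.5),
    acr464 = new_phantom_template(
      "acr464", acr_windows, nominal_pin_radius_mm = 12.5),
    aapm = new_phantom_template(
      "aapm", aapm_windows, nominal_pin_radius_mm = 12),
    catphan604 = new_phantom_template(
      "catphan604", catphan_windows, nominal_pin_radius_mm = 10))
}

#' Look up a built-in phantom template
#'
#' Four phantom families are registered: `computational_acr` and `acr464`
#' (4 pins: Bone, Polyethylene, Air, Acrylic), `aapm` (5 pins) and
#' `catphan604` (9 pins). Each carries the material-specific HU segmentation
#' windows, the expected pin count and the body segmentation threshold
#' (-200 HU).
#'
#' @param name one of `"computational_acr"`, `"acr464"`, `"aapm"`,
#'   `"catphan604"`
#' @return a `phantom_template`
#' @export
get_template <- function(name) {
  reg <- .template_registry()
  if (!name %in% names(reg))
    stop_ttfqa(sprintf("unknown phantom '%s'; valid names: %s", name,
                       paste(names(reg), collapse = ", ")),
               "ttfqa_unknown_template")
  reg[[name]]
}

#' @rdname get_template
#' @export
list_templates <- function() names(.template_registry())

#' Materials whose HU window contains a value
#'
#' Windows may overlap (the AAPM Acrylic/Polycarbonate/Nylon windows do), so
#' the result is a set; spatial layout, not HU alone, disambiguates such
#' materials during segmentation.
#'
#' @param template a `phantom_template`
#' @param hu a single HU value
#' @return character vector of material names (possibly empty)
#' @export
classify_hu <- function(template, hu) {
  stopifnot(inherits(template, "phantom_template"), length(hu) == 1L)
  hit <- vapply(template$windows,
                function(w) hu >= w$lower_hu && hu <= w$upper_hu, logical(1))
  vapply(template$windows[hit], `[[`, "", "material_name")
}

#' Serialize / read a phantom template as YAML
#'
#' Lets users define vendor-specific phantoms in a human-editable file.
#' Unbounded window sides are written as `.inf` / `-.inf`.
#'
#' @param template a `phantom_template`
#' @param path file path
#' @return `write_template`: `path` invisibly; `read_template`: a
#'   `phantom_template`
#' @export
write_template <- function(template, path) {
  obj <- list(name = template$name,
              body_threshold_hu = template$body_threshold_hu,
              nominal_pin_radius_mm = template$nominal_pin_radius_mm,
              windows = lapply(template$windows, function(w)
                list(material_name = w$material_name,
                     lower_hu = w$lower_hu, upper_hu = w$upper_hu,
                     nominal_hu = w$nominal_hu,
                     expected_angle_deg = w$expected_angle_deg)))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  obj <- yaml::read_yaml(path)
  windows <- lapply(obj$windows, function(w)
    material_window(w$material_name,
                    as.numeric(w$lower_hu %||% -Inf),
                    as.numeric(w$upper_hu %||% Inf),
                    as.numeric(w$nominal_hu %||% NA_real_),
                    as.numeric(w$expected_angle_deg %||% NA_real_)))
  new_phantom_template(obj$name, windows,
                       body_threshold_hu = obj$body_threshold_hu %||% -200,
                       nominal_pin_radius_mm =
                         obj$nominal_pin_radius_mm %||% 12)
}
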