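# Shared fixtures, all generated in code.

# a single-pin phantom: one disk on a water body, controllable blur/noise
single_pin_spec <- function(hu = 955, radius_mm = 12.5, blur = list(type = "none"),
                            noise_sd_hu = 0, grid_px = 512, fov_mm = 200,
                            body_diameter_mm = 200, seed = 1L) {
  phantom_spec(
    body_diameter_mm = body_diameter_mm, fov_mm = fov_mm, grid_px = grid_px,
    pins = data.frame(material = "Bone", drow_mm = 0, dcol_mm = 45,
                      radius_mm = radius_mm, hu = hu,
                      stringsAsFactors = FALSE),
    blur = blur, noise_sd_hu = noise_sd_hu, seed = seed)
}

# a hand-built ESF sample cloud from the logistic model on the inward axis
logistic_cloud <- function(a, b, c = 0, d = 0, n = 3000, half_range = 8,
                           noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xin <- seq(-half_range, half_range, length.out = n)
  vals <- a / (1 + exp(-b * (xin - c))) + d
  if (noise_sd > 0) vals <- vals + rnorm(n, sd = noise_sd)
  structure(list(distances_mm = -xin, values_hu = vals,
                 angles_deg = seq(0, 360, length.out = n + 1)[-1],
                 material_name = "synthetic", pin_radius_mm = 12),
            class = "esf_sample")
}

fake_fit <- function(a, b, c = 0, d = 0) {
  structure(list(a = a, b = b, c = c, d = d, rmse_hu = 0, n = 0,
                 material_name = "synthetic", flags = character(0)),
            class = "fitted_esf")
}

preset_template <- c(acr_like = "computational_acr", aapm_like = "aapm",
                     catphan_like = "catphan604")

centroid_errors_px <- function(res, truth) {
  got <- do.call(rbind, lapply(res$rois, function(x)
    data.frame(material = x$material_name, r = x$centroid_mm[1],
               c = x$centroid_mm[2], stringsAsFactors = FALSE)))
  m <- merge(truth$pins, got, by = "material")
  pmax(abs(m$row_mm - m$r), abs(m$col_mm - m$c)) / truth$spacing_mm
}
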