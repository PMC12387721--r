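# Stage-1 contracts on constructed geometry.

sharp_disk_image <- function(diameter_mm, fov_mm = 280, grid_px = 560,
                             body_hu = 0) {
  spec <- phantom_spec(body_diameter_mm = diameter_mm, fov_mm = fov_mm,
                       grid_px = grid_px,
                       pins = data.frame(material = "Bone", drow_mm = 0,
                                         dcol_mm = diameter_mm / 5,
                                         radius_mm = diameter_mm / 18,
                                         hu = 955),
                       blur = list(type = "none"), noise_sd_hu = 0)
  render_phantom(spec)
}

test_that("body diameter of analytic disks is recovered within one pixel", {
  for (d in c(100, 175, 250)) {
    r <- sharp_disk_image(d)
    body <- segment_body(r$image)
    expect_lt(abs(body$diameter_mm - d), r$truth$spacing_mm)
    expect_lt(max(abs(body$center_mm - r$truth$body_center_mm)),
              r$truth$spacing_mm)
  }
})

test_that("largest component is kept and interior holes are filled", {
  r <- sharp_disk_image(200)
  px <- r$image$pixels
  # a disconnected 5-pixel speck in a corner
  px[3, 3:7] <- 100
  img <- hu_image(px, r$image$spacing_mm)
  body <- segment_body(img)
  expect_false(any(body$mask[1:10, 1:10]))
  # an air pin (-1000 HU) inside the body must stay inside the mask
  spec <- phantom_spec(body_diameter_mm = 200, fov_mm = 280, grid_px = 560,
                       pins = data.frame(material = "Air", drow_mm = 0,
                                         dcol_mm = 40, radius_mm = 12,
                                         hu = -1000),
                       blur = list(type = "none"), noise_sd_hu = 0)
  r2 <- render_phantom(spec)
  body2 <- segment_body(r2$image)
  expect_lt(abs(body2$area_mm2 - pi * 100^2) / (pi * 100^2), 0.01)
})

test_that("an empty threshold result is a segmentation error", {
  img <- hu_image(matrix(-1000, 32, 32), 1)
  expect_error(segment_body(img), class = "ttfqa_segmentation_error")
})

test_that("a cropped phantom triggers the FOV warning", {
  # body much larger than the FOV: foreground crosses every border
  spec <- phantom_spec(body_diameter_mm = 200, fov_mm = 200, grid_px = 128,
                       pins = data.frame(material = "Bone", drow_mm = 0,
                                         dcol_mm = 40, radius_mm = 10,
                                         hu = 955),
                       blur = list(type = "none"), noise_sd_hu = 0)
  r <- render_phantom(spec)
  cropped <- hu_image(r$image$pixels[20:110, 20:110], r$image$spacing_mm)
  expect_warning(segment_body(cropped), class = "ttfqa_suspicious_fov")
})

test_that("masking zeroes the exterior exactly and keeps the interior", {
  r <- sharp_disk_image(200)
  body <- segment_body(r$image)
  masked <- apply_body_mask(r$image, body)
  expect_true(all(masked$pixels[!body$mask] == 0))
  expect_identical(masked$pixels[body$mask], r$image$pixels[body$mask])
  # an all-foreground mask is the identity
  body_all <- body; body_all$mask[] <- TRUE
  expect_identical(apply_body_mask(r$image, body_all)$pixels,
                   r$image$pixels)
  small <- hu_image(matrix(0, 10, 10), 1)
  expect_error(apply_body_mask(small, body), class = "ttfqa_alignment_error")
})

test_that("pins are localized within one pixel across pixel spacings", {
  for (grid in c(640, 512, 256, 200)) {   # 0.31 to 1.0 mm/px
    r <- render_phantom(phantom_preset("acr_like", grid_px = grid, seed = 5))
    res <- measure_slice(r$image, "computational_acr")
    expect_equal(nrow(res$rows), 4)
    expect_lt(max(centroid_errors_px(res, r$truth)), 1)
  }
})

test_that("all pins are found on every preset and a missing pin is named", {
  for (p in names(preset_template)) {
    r <- render_phantom(phantom_preset(p, seed = 2))
    res <- measure_slice(r$image, preset_template[[p]])
    expect_setequal(res$rows$material, r$truth$pins$material)
    expect_lt(max(centroid_errors_px(res, r$truth)), 1)
  }
  spec <- phantom_preset("acr_like", seed = 2)
  spec$pins <- spec$pins[spec$pins$material != "Acrylic", ]
  r <- render_phantom(spec)
  body <- segment_body(r$image)
  masked <- apply_body_mask(r$image, body)
  err <- expect_error(
    segment_pins(masked, body, get_template("acr464")),
    class = "ttfqa_pin_not_found")
  expect_match(conditionMessage(err), "Acrylic")
})

test_that("two materials claiming the same component is an ambiguity error", {
  r <- render_phantom(single_pin_spec(hu = 955))
  body <- segment_body(r$image)
  masked <- apply_body_mask(r$image, body)
  template <- ttfqa:::new_phantom_template(
    "twins", list(material_window("Bone", 750, 1300),
                  material_window("AlsoBone", 700, 1300)),
    nominal_pin_radius_mm = 12.5)
  expect_error(segment_pins(masked, body, template),
               class = "ttfqa_ambiguous_pin")
})

single_pin_rois <- function(hu = 955, noise_sd_hu = 0, seed = 1,
                            blur = list(type = "none")) {
  r <- render_phantom(single_pin_spec(hu = hu, blur = blur,
                                      noise_sd_hu = noise_sd_hu, seed = seed))
  body <- segment_body(r$image)
  masked <- apply_body_mask(r$image, body)
  template <- ttfqa:::new_phantom_template(
    "one_pin", list(material_window("Bone", 750, 1300, nominal_hu = 955)),
    nominal_pin_radius_mm = 12.5)
  pins <- segment_pins(masked, body, template)
  list(body = body, masked = masked,
       roi = place_rois(masked, body, pins)[[1]])
}

test_that("ROI diameter is 1:10 of the phantom diameter", {
  s <- single_pin_rois()
  expect_equal(s$roi$roi_diameter_mm, s$body$diameter_mm / 10,
               tolerance = 1e-6)
})

test_that("noiseless pins give exact ROI means and a zero-noise CNR flag", {
  s <- single_pin_rois(hu = 955, noise_sd_hu = 0)
  expect_equal(s$roi$inner_mean_hu, 955)
  expect_equal(s$roi$outer_mean_hu, 0)
  expect_true(is.infinite(s$roi$cnr))
  expect_true("zero_background_noise" %in% s$roi$flags)
})

test_that("CNR matches the analytic contrast/noise ratio", {
  s <- single_pin_rois(hu = 955, noise_sd_hu = 4.85, seed = 31)
  expect_lt(abs(s$roi$cnr - 955 / 4.85) / (955 / 4.85), 0.05)
})

test_that("CNR is invariant to a constant HU offset", {
  r <- render_phantom(single_pin_spec(hu = 955, noise_sd_hu = 4.85,
                                      seed = 8))
  get_cnr <- function(img) {
    body <- segment_body(img)
    masked <- apply_body_mask(img, body)
    template <- ttfqa:::new_phantom_template(
      "one_pin", list(material_window("Bone", 750, 1400, nominal_hu = 955)),
      nominal_pin_radius_mm = 12.5)
    place_rois(masked, body, segment_pins(masked, body, template))[[1]]$cnr
  }
  c0 <- get_cnr(r$image)
  c1 <- get_cnr(hu_image(r$image$pixels + 100, r$image$spacing_mm))
  expect_equal(c1, c0, tolerance = 0.02)
})

test_that("doubling the noise halves the CNR", {
  cnr_at <- function(sd) mean(vapply(1:3, function(s)
    single_pin_rois(noise_sd_hu = sd, seed = s)$roi$cnr, numeric(1)))
  ratio <- cnr_at(4.85) / cnr_at(9.7)
  expect_lt(abs(ratio - 2), 0.3)
})
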