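# Circular-edge ESF extraction, phase alignment and the logistic fit.

sharp_pin_setup <- function(blur = list(type = "none"), noise_sd_hu = 0,
                            seed = 1, hu = 955) {
  r <- render_phantom(single_pin_spec(hu = hu, blur = blur,
                                      noise_sd_hu = noise_sd_hu,
                                      seed = seed))
  body <- segment_body(r$image)
  masked <- apply_body_mask(r$image, body)
  template <- ttfqa:::new_phantom_template(
    "one_pin",
    list(material_window("Bone", if (hu > 0) 750 else -Inf,
                         if (hu > 0) 1300 else -800, nominal_hu = hu)),
    nominal_pin_radius_mm = 12.5)
  pins <- segment_pins(masked, body, template)
  roi <- place_rois(masked, body, pins)[[1]]
  list(masked = masked, roi = roi, truth = r$truth)
}

test_that("a sharp edge separates cleanly at half a pixel", {
  s <- sharp_pin_setup()
  esf <- extract_esf(s$masked, s$roi)
  px <- min(s$masked$spacing_mm)
  expect_gt(length(esf$distances_mm), 200)
  expect_lt(min(esf$distances_mm), 0)
  expect_gt(max(esf$distances_mm), 0)
  inside <- esf$distances_mm < -0.75 * px
  outside <- esf$distances_mm > 0.75 * px
  expect_true(all(abs(esf$values_hu[inside] - 955) < 1))
  expect_true(all(abs(esf$values_hu[outside] - 0) < 1))
})

test_that("too small a sampling window is a sampling error", {
  spec <- phantom_spec(body_diameter_mm = 60, fov_mm = 70, grid_px = 70,
                       pins = data.frame(material = "Bone", drow_mm = 0,
                                         dcol_mm = 12, radius_mm = 3,
                                         hu = 955),
                       blur = list(type = "none"), noise_sd_hu = 0)
  r <- render_phantom(spec)
  body <- segment_body(r$image)
  masked <- apply_body_mask(r$image, body)
  roi <- structure(list(material_name = "Bone",
                        centroid_mm = r$truth$pins[1, c("row_mm", "col_mm")] |>
                          as.numeric(),
                        pin_radius_mm = 3, roi_diameter_mm = 5,
                        inner_mean_hu = 955, outer_mean_hu = 0,
                        outer_sd_hu = 0, cnr = Inf, flags = character(0)),
                   class = "pin_roi")
  expect_error(extract_esf(masked, roi, added_size_mm = 1),
               class = "ttfqa_sampling_error")
  expect_error(extract_esf(masked, roi, added_size_mm = 0),
               class = "ttfqa_sampling_error")
})

test_that("a Gaussian-blurred edge matches the erf profile", {
  sigma <- 0.5
  s <- sharp_pin_setup(blur = list(type = "gaussian", sigma_mm = sigma))
  esf <- extract_esf(s$masked, s$roi)
  # binned radial means vs the 1-D convolution oracle (valid since R >> sigma)
  b <- round(esf$distances_mm / 0.25)
  bm <- tapply(esf$values_hu, b, mean)
  d <- as.numeric(names(bm)) * 0.25
  keep <- abs(d) < 5
  oracle <- 955 * stats::pnorm(-d[keep] / sigma)
  expect_lt(max(abs(bm[keep] - oracle)), 0.03 * 955)
})

test_that("phase alignment is near-identity for a centered circular edge", {
  s <- sharp_pin_setup(blur = list(type = "gaussian", sigma_mm = 0.5))
  esf <- extract_esf(s$masked, s$roi)
  ali <- align_phase(esf)
  f0 <- fit_logistic_esf(esf)
  f1 <- fit_logistic_esf(ali)
  expect_lt(abs(f1$c - f0$c), 0.1)
  expect_lt(abs(f1$b - f0$b) / f0$b, 0.05)
})

test_that("alignment absorbs a deliberate centroid offset", {
  s <- sharp_pin_setup(blur = list(type = "gaussian", sigma_mm = 0.5))
  px <- min(s$masked$spacing_mm)
  roi_off <- s$roi
  roi_off$centroid_mm <- s$roi$centroid_mm + c(0.7 * px, 0)
  c_ref <- fit_logistic_esf(align_phase(extract_esf(s$masked, s$roi)))$c
  c_off <- fit_logistic_esf(align_phase(extract_esf(s$masked, roi_off)))$c
  expect_lt(abs(c_off - c_ref), 0.05)
})

test_that("alignment lowers the fit residual for an elliptical pin", {
  # analytic cloud: edge radius modulated by 2% at second harmonic
  set.seed(99)
  n <- 6000
  th <- runif(n, 0, 360)
  r_edge <- 12 * (1 + 0.02 * cos(2 * th * pi / 180))
  r <- runif(n, 6, 18)
  vals <- 500 / (1 + exp(-6 * (r_edge - r))) + rnorm(n, sd = 2)
  cloud <- structure(list(distances_mm = r - 12, values_hu = vals,
                          angles_deg = th, material_name = "ellipse",
                          pin_radius_mm = 12), class = "esf_sample")
  f_raw <- fit_logistic_esf(cloud)
  f_ali <- fit_logistic_esf(align_phase(cloud))
  expect_lt(f_ali$rmse_hu, f_raw$rmse_hu)
})

test_that("alignment fails cleanly when most sectors have no edge", {
  set.seed(5)
  flat <- structure(list(distances_mm = runif(2000, -10, 10),
                         values_hu = rnorm(2000, 100, 1),
                         angles_deg = runif(2000, 0, 360),
                         material_name = "flat", pin_radius_mm = 12),
                    class = "esf_sample")
  expect_error(align_phase(flat), class = "ttfqa_alignment_error")
})

test_that("exact logistic samples are recovered to machine precision", {
  cloud <- logistic_cloud(1000, 3, c = 0.2, d = 5)
  f <- fit_logistic_esf(cloud)
  expect_equal(f$a, 1000, tolerance = 1e-6)
  expect_equal(f$b, 3, tolerance = 1e-6)
  expect_equal(f$c, 0.2, tolerance = 1e-6)
  expect_equal(f$d, 5, tolerance = 1e-6)
  expect_lt(f$rmse_hu, 1e-8)
})

test_that("b is recovered within 2% under 5 HU noise (Monte Carlo)", {
  errs <- vapply(1:100, function(s) {
    f <- fit_logistic_esf(logistic_cloud(1000, 3, n = 2000, noise_sd = 5,
                                         seed = s))
    abs(f$b - 3) / 3
  }, numeric(1))
  expect_lt(max(errs), 0.02)
})

test_that("dark pins fit with negative amplitude", {
  s <- sharp_pin_setup(blur = list(type = "gaussian", sigma_mm = 0.5),
                       noise_sd_hu = 4.85, seed = 3, hu = -1000)
  f <- fit_logistic_esf(align_phase(extract_esf(s$masked, s$roi)))
  expect_lt(f$a, 0)
  expect_lt(abs(abs(f$a) - 1000) / 1000, 0.02)
})

test_that("degenerate and low-contrast clouds are rejected or flagged", {
  flat <- logistic_cloud(0, 3, d = 100)
  expect_error(fit_logistic_esf(flat), class = "ttfqa_fit_error")
  weak <- logistic_cloud(10, 3, d = 0, noise_sd = 5, seed = 1)
  expect_warning(f <- fit_logistic_esf(weak, noise_sd_hu = 5),
                 class = "ttfqa_low_contrast")
  expect_true("low_contrast" %in% f$flags)
})
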