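## Stage 1: body segmentation, masking, pin segmentation, ROI placement.

# Exact 8-connected labeling: 4-connected labels from EBImage::bwlabel,
# then union of labels that touch diagonally.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  d <- dim(lab)
  pairs <- NULL
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(d[1] - 1L), , drop = FALSE]
    b <- lab[-1L, , drop = FALSE]
    if (sh[2] == 1L) {
      a <- a[, seq_len(d[2] - 1L), drop = FALSE]
      b <- b[, -1L, drop = FALSE]
    } else {
      a <- a[, -1L, drop = FALSE]
      b <- b[, seq_len(d[2] - 1L), drop = FALSE]
    }
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  if (!is.null(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Segment the phantom body
#'
#' Thresholds the slice at `threshold_hu` (default -200 HU), keeps the largest
#' connected foreground component, fills interior holes (so air or low-HU pins
#' stay part of the body), and measures the equivalent-circle diameter
#' \eqn{2\sqrt{A/\pi}} from the mask area.
#'
#' @param img an [hu_image]
#' @param threshold_hu body segmentation threshold in HU
#' @return object of class `body_mask` with fields `mask` (logical matrix),
#'   `diameter_mm`, `center_mm` (row, col in mm), `area_mm2`, `spacing_mm`
#' @export
segment_body <- function(img, threshold_hu = -200) {
  stopifnot(inherits(img, "hu_image"))
  fg <- img$pixels > threshold_hu
  if (!any(fg))
    stop_ttfqa(sprintf("no pixels above %g HU: cannot segment body",
                       threshold_hu), "ttfqa_segmentation_error")
  lab <- label8(fg)
  areas <- tabulate(lab[lab > 0])
  keep <- which.max(areas)
  mask <- lab == keep
  mask <- EBImage::fillHull(mask * 1) > 0
  d <- dim(mask)
  border_frac <- c(mean(mask[1, ]), mean(mask[d[1], ]),
                   mean(mask[, 1]), mean(mask[, d[2]]))
  # substantial foreground on every border (a tangential touch of an
  # inscribed body is normal and does not warn)
  if (all(border_frac > 0.10))
    warn_ttfqa("phantom crosses all four image borders; FOV may be too small",
               "ttfqa_suspicious_fov")
  px_area <- prod(img$spacing_mm)
  area_mm2 <- sum(mask) * px_area
  pc <- pixel_centers(img)
  center_mm <- c(mean(pc$row_mm[mask]), mean(pc$col_mm[mask]))
  structure(list(mask = mask,
                 diameter_mm = 2 * sqrt(area_mm2 / pi),
                 center_mm = center_mm,
                 area_mm2 = area_mm2,
                 spacing_mm = img$spacing_mm),
            class = "body_mask")
}

#' @export
print.body_mask <- function(x, ...) {
  cat(sprintf("<body_mask> diameter %.1f mm, center (%.1f, %.1f) mm\n",
              x$diameter_mm, x$center_mm[1], x$center_mm[2]))
  invisible(x)
}

#' Mask out the air outside the phantom
#'
#' Element-wise multiplication of the image with the body mask: every pixel
#' outside the phantom becomes exactly 0 HU, pixels inside are unchanged.
#'
#' @param img an [hu_image]
#' @param body a [segment_body()] result aligned to `img`
#' @return an [hu_image]
#' @export
apply_body_mask <- function(img, body) {
  stopifnot(inherits(img, "hu_image"), inherits(body, "body_mask"))
  if (!identical(dim(img$pixels), dim(body$mask)))
    stop_ttfqa("mask and image dimensions differ", "ttfqa_alignment_error")
  out <- img
  out$pixels <- img$pixels * body$mask
  out
}

ang_deg <- function(drow, dcol) {
  a <- atan2(-drow, dcol) * 180 / pi
  (a + 360) %% 360
}

circ_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Segment the material pins of a multi-pin module
#'
#' Applies each material's HU window to the masked image, labels connected
#' components (8-connectivity) within an interior search disk (radius 0.8 x
#' body radius, which keeps the phantom shell out of the bone/teflon windows),
#' rejects components whose area is outside 25-400% of the template's nominal
#' pin area, and keeps the largest valid component per material. Materials
#' with overlapping HU windows (the AAPM Acrylic/Polycarbonate/Nylon trio) are
#' disambiguated by the template's expected polar angles. Centroids are
#' computed from the binary component masks.
#'
#' @param masked output of [apply_body_mask()]
#' @param body the owning [segment_body()] result
#' @param template a [get_template()] phantom template
#' @return data.frame with one row per material: `material`, `row_mm`,
#'   `col_mm` (binary-mask centroid), `radius_mm` (equivalent-circle radius),
#'   `area_px`
#' @export
segment_pins <- function(masked, body, template) {
  stopifnot(inherits(masked, "hu_image"), inherits(body, "body_mask"),
            inherits(template, "phantom_template"))
  pc <- pixel_centers(masked)
  d2c <- (pc$row_mm - body$center_mm[1])^2 + (pc$col_mm - body$center_mm[2])^2
  search <- body$mask & (d2c < (0.4 * body$diameter_mm)^2)
  px_area <- prod(masked$spacing_mm)
  nominal_area_px <- pi * template$nominal_pin_radius_mm^2 / px_area
  rows <- list(); comp_keys <- character(0)
  for (w in template$windows) {
    bin <- search & masked$pixels >= w$lower_hu & masked$pixels <= w$upper_hu
    lab <- label8(bin)
    n <- max(lab)
    found <- FALSE
    if (n > 0) {
      areas <- tabulate(lab, nbins = n)
      valid <- which(areas >= 0.25 * nominal_area_px &
                     areas <= 4 * nominal_area_px)
      if (length(valid)) {
        stats <- lapply(valid, function(k) {
          sel <- lab == k
          cen <- c(mean(pc$row_mm[sel]), mean(pc$col_mm[sel]))
          list(k = k, area = areas[k], cen = cen,
               angle = ang_deg(cen[1] - body$center_mm[1],
                               cen[2] - body$center_mm[2]))
        })
        pick <- if (is.finite(w$expected_angle_deg)) {
          stats[[which.min(vapply(stats, function(s)
            circ_diff(s$angle, w$expected_angle_deg), numeric(1)))]]
        } else {
          stats[[which.max(vapply(stats, `[[`, numeric(1), "area"))]]
        }
        key <- sprintf("%.0f_%.0f", pick$cen[1] / masked$spacing_mm[1],
                       pick$cen[2] / masked$spacing_mm[2])
        if (key %in% comp_keys)
          stop_ttfqa(sprintf(
            "materials resolve to the same component near (%.1f, %.1f) mm (ambiguous windows: %s)",
            pick$cen[1], pick$cen[2], w$material_name),
            "ttfqa_ambiguous_pin")
        comp_keys <- c(comp_keys, key)
        rows[[w$material_name]] <- data.frame(
          material = w$material_name,
          row_mm = pick$cen[1], col_mm = pick$cen[2],
          radius_mm = sqrt(pick$area * px_area / pi),
          area_px = pick$area,
          stringsAsFactors = FALSE)
        found <- TRUE
      }
    }
    if (!found)
      stop_ttfqa(sprintf("pin not found for material '%s' (window [%s, %s] HU)",
                         w$material_name, format(w$lower_hu),
                         format(w$upper_hu)),
                 "ttfqa_pin_not_found")
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Refine a pin's edge radius from the binned radial profile: the radius where
# the profile crosses the midpoint between the inner and outer plateau
# medians. Threshold-window segmentation under/over-shoots the true edge when
# the HU window is asymmetric about the pin HU; the profile crossing is not
# biased that way. Also returns the 25-75% transition width as a blur proxy.
refine_pin_edge <- function(masked, center_mm, r0, exclude) {
  d2 <- dist2_to(masked, center_mm)
  sel <- d2 <= (2 * r0)^2 & !exclude
  r <- sqrt(d2[sel]); v <- masked$pixels[sel]
  h <- min(masked$spacing_mm) / 2
  nb <- ceiling(2 * r0 / h)
  bin <- pmin(1L + floor(r / h), nb)
  by <- vapply(split(v, factor(bin, levels = seq_len(nb))),
               function(z) if (length(z)) mean(z) else NA_real_, numeric(1))
  bx <- (seq_len(nb) - 0.5) * h
  ok <- !is.na(by)
  bx <- bx[ok]; by <- by[ok]
  inner_med <- stats::median(by[bx < 0.6 * r0])
  outer_med <- stats::median(by[bx > 1.4 * r0 & bx < 1.9 * r0])
  lv <- function(f) outer_med + f * (inner_med - outer_med)
  r_edge <- crossing_at(bx - r0, by, lv(0.5))
  if (is.na(r_edge)) return(list(r_edge = r0, width = h))
  r25 <- crossing_at(bx - r0, by, lv(0.25))
  r75 <- crossing_at(bx - r0, by, lv(0.75))
  width <- if (is.na(r25) || is.na(r75)) h else max(abs(r25 - r75), h)
  list(r_edge = r_edge + r0, width = width)
}

#' Place inner and background ROIs at each pin
#'
#' The pin edge radius is first refined from the binned radial profile
#' (midpoint crossing between the plateau medians). The inner ROI is a disk
#' of diameter 1/10 of the phantom diameter centered at the pin centroid
#' (capped at 0.8 x the pin radius so it never crosses the edge of a small
#' pin). The background ROI is a concentric annulus between `annulus_inner`
#' and `annulus_outer` pin radii; its inner radius additionally keeps a guard
#' band of 2.5 x the measured 25-75% edge width beyond the edge, so the
#' blurred transition never leaks into the noise estimate. The annulus is
#' clipped to the body and away from the other pins. CNR is
#' |inner mean - outer mean| / outer SD.
#'
#' @param masked output of [apply_body_mask()]
#' @param body the owning [segment_body()] result
#' @param pins data.frame from [segment_pins()]
#' @param annulus_inner,annulus_outer background annulus radii as multiples of
#'   the (refined) pin radius
#' @return list of `pin_roi` objects with fields `material_name`,
#'   `centroid_mm`, `pin_radius_mm` (refined edge radius),
#'   `edge_width_mm`, `roi_diameter_mm`, `inner_mean_hu`, `outer_mean_hu`,
#'   `outer_sd_hu`, `cnr`, `flags`
#' @export
place_rois <- function(masked, body, pins,
                       annulus_inner = 1.1, annulus_outer = 1.5) {
  stopifnot(inherits(masked, "hu_image"), inherits(body, "body_mask"))
  roi_d_mm <- body$diameter_mm / 10
  lapply(seq_len(nrow(pins)), function(i) {
    p <- pins[i, ]
    exclude <- !body$mask
    for (j in setdiff(seq_len(nrow(pins)), i)) {
      q <- pins[j, ]
      exclude <- exclude |
        dist2_to(masked, c(q$row_mm, q$col_mm)) <=
          (annulus_outer * q$radius_mm)^2
    }
    edge <- refine_pin_edge(masked, c(p$row_mm, p$col_mm), p$radius_mm,
                            exclude)
    r_pin <- edge$r_edge
    d2 <- dist2_to(masked, c(p$row_mm, p$col_mm))
    roi_r <- min(roi_d_mm / 2, 0.8 * r_pin)
    roi_r <- max(min(roi_r, r_pin - 2 * edge$width), 0.4 * r_pin)
    inner <- d2 <= roi_r^2
    lo <- max(annulus_inner * r_pin, r_pin + 2.5 * edge$width)
    hi <- annulus_outer * r_pin
    if (lo >= hi - min(masked$spacing_mm)) lo <- annulus_inner * r_pin
    outer <- !exclude & d2 >= lo^2 & d2 <= hi^2
    if (sum(outer) < 50)
      stop_ttfqa(sprintf(
        "fewer than 50 background pixels remain for '%s'", p$material),
        "ttfqa_insufficient_background")
    im <- mean(masked$pixels[inner])
    om <- mean(masked$pixels[outer])
    osd <- stats::sd(masked$pixels[outer])
    flags <- character(0)
    if (osd < 1e-9) {
      cnr <- Inf
      flags <- c(flags, "zero_background_noise")
    } else cnr <- abs(im - om) / osd
    structure(list(material_name = p$material,
                   centroid_mm = c(p$row_mm, p$col_mm),
                   pin_radius_mm = r_pin,
                   edge_width_mm = edge$width,
                   roi_diameter_mm = 2 * roi_r,
                   inner_mean_hu = im, outer_mean_hu = om,
                   outer_sd_hu = osd, cnr = cnr, flags = flags),
              class = "pin_roi")
  })
}

#' @export
print.pin_roi <- function(x, ...) {
  cat(sprintf(
    "<pin_roi> %s @ (%.1f, %.1f) mm, ROI %.1f mm, in %.1f / out %.1f HU, CNR %.1f\n",
    x$material_name, x$centroid_mm[1], x$centroid_mm[2], x$roi_diameter_mm,
    x$inner_mean_hu, x$outer_mean_hu, x$cnr))
  invisible(x)
}
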