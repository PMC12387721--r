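## Stage 2a: radial ESF sampling, phase alignment, single-logistic fit.
##
## Distance convention: samples carry the signed radial distance r - R
## (negative inside the pin, positive outside). The logistic model is
## parameterized on the inward axis x = -(r - R), so that the baseline d is
## the background plateau and the amplitude a is pin minus background
## (a < 0 for pins darker than the background, e.g. air).

#' Extract a circular-edge ESF sample cloud
#'
#' Every pixel whose center lies within `pin_radius + added_size_mm` of the
#' pin centroid contributes one (distance, HU) pair; the distance is the
#' Euclidean distance from the centroid minus the estimated pin edge radius,
#' so the edge sits near distance 0. The polar angle of each sample is kept
#' for sector-wise phase alignment.
#'
#' @param masked output of [apply_body_mask()]
#' @param roi a `pin_roi` from [place_rois()]
#' @param added_size_mm how far beyond the pin edge to sample (mm); default
#'   one pin radius
#' @return object of class `esf_sample` with fields `distances_mm`,
#'   `values_hu`, `angles_deg`, `material_name`, `pin_radius_mm`
#' @export
extract_esf <- function(masked, roi, added_size_mm = NULL) {
  stopifnot(inherits(masked, "hu_image"), inherits(roi, "pin_roi"))
  added_size_mm <- added_size_mm %||% roi$pin_radius_mm
  if (added_size_mm <= 0)
    stop_ttfqa("added_size_mm must be positive", "ttfqa_sampling_error")
  pc <- pixel_centers(masked)
  dr <- pc$row_mm - roi$centroid_mm[1]
  dc <- pc$col_mm - roi$centroid_mm[2]
  r <- sqrt(dr^2 + dc^2)
  sel <- r <= roi$pin_radius_mm + added_size_mm
  if (sum(sel) < 200)
    stop_ttfqa(sprintf(
      "only %d ESF samples for '%s'; increase added_size", sum(sel),
      roi$material_name), "ttfqa_sampling_error")
  structure(list(distances_mm = r[sel] - roi$pin_radius_mm,
                 values_hu = masked$pixels[sel],
                 angles_deg = ang_deg(dr[sel], dc[sel]),
                 material_name = roi$material_name,
                 pin_radius_mm = roi$pin_radius_mm),
            class = "esf_sample")
}

#' @export
print.esf_sample <- function(x, ...) {
  cat(sprintf("<esf_sample> %s: %d samples, distance [%.2f, %.2f] mm\n",
              x$material_name, length(x$distances_mm),
              min(x$distances_mm), max(x$distances_mm)))
  invisible(x)
}

# robust plateau medians of a sample cloud (on the signed outward distance)
plateau_medians <- function(dist, val) {
  qs <- stats::quantile(dist, c(0.15, 0.85))
  list(inner = stats::median(val[dist <= qs[1]]),
       outer = stats::median(val[dist >= qs[2]]))
}

# first crossing (nearest to distance 0) of level m in an ordered profile
crossing_at <- function(x, y, m) {
  s <- y - m
  idx <- which(s[-length(s)] * s[-1] <= 0 & s[-length(s)] != s[-1])
  if (!length(idx)) return(NA_real_)
  cr <- x[idx] + (x[idx + 1] - x[idx]) * (m - y[idx]) / (y[idx + 1] - y[idx])
  cr[which.min(abs(cr))]
}

#' Phase-align radial ESF samples sector by sector
#'
#' Estimates the local edge-crossing radius in each angular sector as the
#' radius where the sector's smoothed profile crosses the midpoint between
#' the robust inner/outer plateau medians, and shifts each sector's distances
#' so its crossing sits at 0. This removes edge-phase dispersion caused by
#' centroid error or slight pin ellipticity before fitting.
#'
#' @param samples an [extract_esf()] result
#' @param sectors number of angular sectors (default 32)
#' @return an `esf_sample` with per-sector aligned distances; sectors with no
#'   detectable crossing are dropped
#' @export
align_phase <- function(samples, sectors = 32) {
  stopifnot(inherits(samples, "esf_sample"))
  pm <- plateau_medians(samples$distances_mm, samples$values_hu)
  # an edge must be detectable above the background noise before its
  # crossing radius can mean anything
  qs <- stats::quantile(samples$distances_mm, 0.85)
  noise_mad <- stats::mad(samples$values_hu[samples$distances_mm >= qs])
  if (abs(pm$inner - pm$outer) < max(3 * noise_mad, 1e-9))
    stop_ttfqa("no detectable edge contrast; cannot phase-align",
               "ttfqa_alignment_error")
  m <- (pm$inner + pm$outer) / 2
  sec <- pmin(floor(samples$angles_deg / (360 / sectors)) + 1L, sectors)
  keep <- logical(length(sec))
  dist_out <- samples$distances_mm
  dropped <- 0L
  for (k in seq_len(sectors)) {
    in_k <- which(sec == k)
    if (length(in_k) < 8L) { dropped <- dropped + 1L; next }
    o <- in_k[order(samples$distances_mm[in_k])]
    x <- samples$distances_mm[o]
    y <- samples$values_hu[o]
    ks <- min(7L, 2L * (length(y) %/% 2L) - 1L)
    ys <- if (ks >= 3L) stats::runmed(y, ks) else y
    cr <- crossing_at(x, ys, m)
    if (is.na(cr)) { dropped <- dropped + 1L; next }
    dist_out[o] <- x - cr
    keep[o] <- TRUE
  }
  if (dropped > sectors / 2)
    stop_ttfqa(sprintf(
      "phase alignment failed: %d of %d sectors have no edge crossing",
      dropped, sectors), "ttfqa_alignment_error")
  out <- samples
  out$distances_mm <- dist_out[keep]
  out$values_hu <- samples$values_hu[keep]
  out$angles_deg <- samples$angles_deg[keep]
  out
}

logistic_model <- function(p, x) {
  z <- pmin(pmax(-p[2] * (x - p[3]), -700), 700)
  p[1] / (1 + exp(z)) + p[4]
}

logistic_jac <- function(p, x) {
  z <- pmin(pmax(-p[2] * (x - p[3]), -700), 700)
  e <- exp(z)
  s <- 1 / (1 + e)
  cbind(s,
        p[1] * s^2 * e * (x - p[3]),
        -p[1] * s^2 * e * p[2],
        1)
}

#' Fit the single-logistic edge model to an ESF sample cloud
#'
#' Fits \eqn{ESF(x) = a / (1 + e^{-b(x-c)}) + d} on the inward axis
#' \eqn{x = -(r - R)} by trust-region non-linear least squares
#' (Levenberg-Marquardt with analytic Jacobian and bounded restarts).
#' Initialization: plateau medians give `a` and `d`, the midpoint crossing
#' gives `c`, and the 25-75% transition width gives `b` via
#' \eqn{b_0 = 2\ln 3 / w}. `a` is negative for pins darker than the
#' background (air).
#'
#' @param samples an (ideally phase-aligned) [extract_esf()] result
#' @param noise_sd_hu optional background noise SD; if given and
#'   `|a| < 3 * noise_sd_hu`, a low-contrast flag is attached
#' @return object of class `fitted_esf`: `a` (HU), `b` (1/mm), `c` (mm, on
#'   the inward axis), `d` (HU), `rmse_hu`, `n`, `flags`
#' @export
fit_logistic_esf <- function(samples, noise_sd_hu = NULL) {
  stopifnot(inherits(samples, "esf_sample"))
  x <- -samples$distances_mm          # inward axis
  y <- samples$values_hu
  pm <- plateau_medians(samples$distances_mm, samples$values_hu)
  a0 <- pm$inner - pm$outer
  d0 <- pm$outer
  # binned profile for width-based initialization of b
  br <- range(x)
  nb <- 100L
  bin <- pmin(pmax(1L, 1L + floor((x - br[1]) / diff(br) * nb)), nb)
  bx <- br[1] + (seq_len(nb) - 0.5) * diff(br) / nb
  by <- vapply(split(y, factor(bin, levels = seq_len(nb))),
               function(v) if (length(v)) mean(v) else NA_real_, numeric(1))
  ok <- !is.na(by)
  x25 <- crossing_at(bx[ok], by[ok], d0 + 0.25 * a0)
  x75 <- crossing_at(bx[ok], by[ok], d0 + 0.75 * a0)
  b0 <- if (!is.na(x25) && !is.na(x75) && abs(x75 - x25) > 1e-6)
    2 * log(3) / abs(x75 - x25) else 2 / stats::median(diff(sort(unique(bx))))
  c0 <- crossing_at(bx[ok], by[ok], d0 + 0.5 * a0)
  if (is.na(c0)) c0 <- 0
  starts <- list(c(a0, b0, c0, d0),
                 c(a0, 3 * b0, c0, d0),
                 c(a0, b0 / 3, c0, d0),
                 c(a0, b0, 0, d0))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(suppressWarnings(minpack.lm::nls.lm(
      par = p0,
      fn = function(p) logistic_model(p, x) - y,
      jac = function(p) logistic_jac(p, x),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    p <- unname(fit$par)
    if (any(!is.finite(p)) || p[2] <= 0) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = p, rss = rss)
  }
  if (is.null(best))
    stop_ttfqa(sprintf(
      "logistic fit did not converge for '%s' (n=%d, a0=%.1f, b0=%.2f)",
      samples$material_name, length(x), a0, b0), "ttfqa_fit_error")
  p <- best$par
  if (abs(p[1]) < 1e-3)
    stop_ttfqa(sprintf("degenerate zero-contrast fit for '%s' (|a|=%.2g HU)",
                       samples$material_name, abs(p[1])), "ttfqa_fit_error")
  flags <- character(0)
  if (!is.null(noise_sd_hu) && is.finite(noise_sd_hu) &&
      abs(p[1]) < 3 * noise_sd_hu) {
    flags <- c(flags, "low_contrast")
    warn_ttfqa(sprintf("'%s': edge amplitude %.1f HU < 3 x noise SD %.1f HU",
                       samples$material_name, abs(p[1]), noise_sd_hu),
               "ttfqa_low_contrast")
  }
  structure(list(a = p[1], b = p[2], c = p[3], d = p[4],
                 rmse_hu = sqrt(best$rss / length(x)),
                 n = length(x),
                 material_name = samples$material_name,
                 flags = flags),
            class = "fitted_esf")
}

#' @export
print.fitted_esf <- function(x, ...) {
  cat(sprintf(
    "<fitted_esf> %s: a=%.1f HU, b=%.3f /mm, c=%.3f mm, d=%.1f HU, rmse=%.2f HU (n=%d)\n",
    x$material_name %||% "?", x$a, x$b, x$c, x$d, x$rmse_hu, x$n))
  invisible(x)
}
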