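## Stage 2b: LSF construction, FFT, TTF summary metrics.

#' Processing configuration for TTF measurement
#'
#' @param added_size_mm ESF sample length beyond the pin edge (mm); `NULL`
#'   (default) means one pin radius per pin
#' @param enable_phase_alignment run sector-wise edge phase alignment
#'   before fitting (default TRUE)
#' @param enable_curve_fit fit the single-logistic edge model (default TRUE);
#'   when FALSE the TTF is computed from the binned empirical ESF derivative
#' @param lsf_grid_spacing_mm resampling grid for the analytic LSF (mm,
#'   default 0.02, must be <= 0.1)
#' @param fft_length minimum zero-padded FFT length (default 4096)
#' @param sector_count angular sectors for phase alignment (default 32)
#' @param annulus_inner,annulus_outer background annulus (pin radii)
#' @return a list of class `ttf_config`
#' @export
ttf_config <- function(added_size_mm = NULL,
                       enable_phase_alignment = TRUE,
                       enable_curve_fit = TRUE,
                       lsf_grid_spacing_mm = 0.02,
                       fft_length = 4096,
                       sector_count = 32,
                       annulus_inner = 1.1,
                       annulus_outer = 1.5) {
  if (lsf_grid_spacing_mm > 0.1)
    stop_ttfqa("lsf_grid_spacing_mm must be <= 0.1 mm", "ttfqa_bad_config")
  structure(list(added_size_mm = added_size_mm,
                 enable_phase_alignment = enable_phase_alignment,
                 enable_curve_fit = enable_curve_fit,
                 lsf_grid_spacing_mm = lsf_grid_spacing_mm,
                 fft_length = fft_length,
                 sector_count = sector_count,
                 annulus_inner = annulus_inner,
                 annulus_outer = annulus_outer),
            class = "ttf_config")
}

#' Read a processing configuration from a YAML file
#'
#' Keys mirror the arguments of [ttf_config()]; unknown keys are an error.
#'
#' @param path YAML file
#' @return a `ttf_config`
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  known <- names(formals(ttf_config))
  bad <- setdiff(names(obj), known)
  if (length(bad))
    stop_ttfqa(paste0("unknown config keys: ", paste(bad, collapse = ", ")),
               "ttfqa_bad_config")
  do.call(ttf_config, obj)
}

#' Analytic LSF of a fitted logistic ESF
#'
#' Differentiates the fitted edge model analytically:
#' \eqn{LSF(x) = a b e^{-b(x-c)} / (1 + e^{-b(x-c)})^2}, evaluated on a
#' uniform grid wide enough that the tails fall below 1e-6 of the peak
#' ("zeroed"), sign-normalized to a positive peak and area-normalized to
#' sum 1 ("normalized").
#'
#' @param fit a [fit_logistic_esf()] result
#' @param grid_spacing_mm uniform grid spacing (mm, <= 0.1)
#' @return list of class `lsf_grid`: `x_mm`, `lsf`, `spacing_mm`
#' @export
esf_to_lsf <- function(fit, grid_spacing_mm = 0.02) {
  stopifnot(inherits(fit, "fitted_esf"))
  if (grid_spacing_mm > 0.1)
    stop_ttfqa("grid_spacing_mm must be <= 0.1 mm", "ttfqa_bad_config")
  half_width <- 20 / fit$b        # sech^2 tail ~ 4 e^{-b w} < 1e-6 peak
  x <- seq(-half_width, half_width, by = grid_spacing_mm)
  z <- pmin(pmax(-fit$b * x, -700), 700)
  e <- exp(z)
  lsf <- abs(fit$a) * fit$b * e / (1 + e)^2
  lsf <- lsf / sum(lsf)
  structure(list(x_mm = x + fit$c, lsf = lsf,
                 spacing_mm = grid_spacing_mm),
            class = "lsf_grid")
}

first_downward_crossing <- function(freq, ttf, level) {
  below <- ttf < level
  i <- which(!below[-length(below)] & below[-1])
  if (!length(i)) return(list(f = NA_real_, ambiguous = FALSE))
  i <- i[1]
  f <- freq[i] + (freq[i + 1] - freq[i]) * (ttf[i] - level) /
    (ttf[i] - ttf[i + 1])
  list(f = f, ambiguous = any(ttf[-seq_len(i)] > level))
}

#' TTF from a sampled LSF by FFT
#'
#' Zero-pads the LSF to at least `fft_length` points, takes the DFT modulus,
#' and normalizes so TTF(0) = 1. f50 and f10 are read off by linear
#' interpolation at the first downward crossings of 0.5 and 0.1; a flag is
#' set if the curve re-crosses the level afterwards (non-monotonic TTF).
#'
#' @param lsf an [esf_to_lsf()] result (or any area-normalized uniform-grid
#'   LSF as an `lsf_grid`)
#' @param fft_length minimum FFT length (zero-padded)
#' @return object of class `ttf_result`: `frequencies_inv_mm`, `ttf`,
#'   `f50_inv_mm`, `f10_inv_mm`, `material_name`, `cnr`, `flags`
#' @export
lsf_to_ttf <- function(lsf, fft_length = 4096) {
  stopifnot(inherits(lsf, "lsf_grid"))
  n <- length(lsf$lsf)
  nfft <- max(fft_length, 2^ceiling(log2(n)))
  padded <- c(lsf$lsf, numeric(nfft - n))
  mod <- Mod(stats::fft(padded))
  ttf <- mod / mod[1]
  freq <- (seq_len(nfft) - 1) / (nfft * lsf$spacing_mm)
  nyq <- 1 / (2 * lsf$spacing_mm)
  keep <- freq <= nyq
  ttf <- ttf[keep]; freq <- freq[keep]
  c50 <- first_downward_crossing(freq, ttf, 0.5)
  c10 <- first_downward_crossing(freq, ttf, 0.1)
  flags <- character(0)
  if (c50$ambiguous || c10$ambiguous) flags <- c(flags, "nonmonotonic_ttf")
  if (is.na(c50$f) || is.na(c10$f)) flags <- c(flags, "no_crossing")
  structure(list(frequencies_inv_mm = freq, ttf = ttf,
                 f50_inv_mm = c50$f, f10_inv_mm = c10$f,
                 material_name = NA_character_, cnr = NA_real_,
                 flags = flags),
            class = "ttf_result")
}

#' @export
print.ttf_result <- function(x, ...) {
  cat(sprintf("<ttf_result> %s: f50 = %.3f /mm, f10 = %.3f /mm, CNR = %.1f%s\n",
              x$material_name, x$f50_inv_mm, x$f10_inv_mm, x$cnr,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}

# Model-free fallback: binned empirical ESF derivative on the inward axis.
empirical_lsf <- function(samples, bin_width_mm = 0.1) {
  x <- -samples$distances_mm
  y <- samples$values_hu
  br <- range(x)
  nb <- max(16L, ceiling(diff(br) / bin_width_mm))
  h <- diff(br) / nb
  bin <- pmin(pmax(1L, 1L + floor((x - br[1]) / h)), nb)
  by <- vapply(split(y, factor(bin, levels = seq_len(nb))),
               function(v) if (length(v)) mean(v) else NA_real_, numeric(1))
  bx <- br[1] + (seq_len(nb) - 0.5) * h
  ok <- !is.na(by)
  by <- stats::approx(bx[ok], by[ok], xout = bx, rule = 2)$y
  by <- stats::runmed(by, 5)
  lsf <- diff(by) / h
  if (sum(lsf) < 0) lsf <- -lsf
  # zero the tails: remove the residual baseline, clamp negatives
  ntail <- max(2L, round(0.1 * length(lsf)))
  lsf <- lsf - stats::median(c(utils::head(lsf, ntail),
                               utils::tail(lsf, ntail)))
  lsf[lsf < 0] <- 0
  if (sum(lsf) <= 0)
    stop_ttfqa(sprintf("empirical LSF is empty for '%s'",
                       samples$material_name), "ttfqa_fit_error")
  structure(list(x_mm = (bx[-1] + bx[-nb]) / 2, lsf = lsf / sum(lsf),
                 spacing_mm = h),
            class = "lsf_grid")
}

#' Measure the TTF of every pin
#'
#' Runs the stage-2 chain per pin: radial ESF extraction, optional sector
#' phase alignment, optional single-logistic fit, analytic differentiation to
#' the LSF (or binned empirical derivative when fitting is disabled), FFT,
#' and f50/f10 extraction. Per-pin failures do not stop the batch; they are
#' collected in the `"errors"` attribute of the returned list.
#'
#' @param masked output of [apply_body_mask()]
#' @param rois list of `pin_roi` from [place_rois()]
#' @param config a [ttf_config()]
#' @return list of `ttf_result` (one per succeeding pin) with attribute
#'   `errors`: named character vector of per-material failure messages
#' @export
measure_ttf <- function(masked, rois, config = ttf_config()) {
  stopifnot(inherits(masked, "hu_image"))
  results <- list()
  errors <- character(0)
  for (roi in rois) {
    res <- tryCatch({
      samples <- extract_esf(masked, roi, config$added_size_mm)
      if (config$enable_phase_alignment)
        samples <- align_phase(samples, config$sector_count)
      extra_flags <- character(0)
      lsf <- if (config$enable_curve_fit) {
        fit <- withCallingHandlers(
          fit_logistic_esf(samples, noise_sd_hu = roi$outer_sd_hu),
          ttfqa_low_contrast = function(w) invokeRestart("muffleWarning"))
        extra_flags <- fit$flags
        esf_to_lsf(fit, config$lsf_grid_spacing_mm)
      } else {
        empirical_lsf(samples)
      }
      ttf <- lsf_to_ttf(lsf, config$fft_length)
      ttf$material_name <- roi$material_name
      ttf$cnr <- roi$cnr
      ttf$flags <- unique(c(ttf$flags, extra_flags, roi$flags))
      if (config$enable_curve_fit) ttf$fit <- fit
      ttf
    }, ttfqa_error = function(e) e)
    if (inherits(res, "ttfqa_error"))
      errors[roi$material_name] <- conditionMessage(res)
    else results[[roi$material_name]] <- res
  }
  attr(results, "errors") <- errors
  results
}
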