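## One-command batch driver and report writers.

REPORT_SCHEMA_VERSION <- "1"

config_hash <- function(config) {
  canon <- paste(names(config),
                 vapply(config, function(v)
                   paste(format(v %||% "NULL"), collapse = ","), ""),
                 sep = "=", collapse = ";")
  tf <- tempfile()
  writeLines(canon, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

#' Measure every pin of one CT slice
#'
#' Runs the full pipeline on a single slice: body segmentation (-200 HU
#' threshold by default, taken from the template), exterior masking, per-
#' material pin segmentation, ROI placement, and TTF measurement.
#'
#' @param img an [hu_image] or a path to a CT DICOM file
#' @param phantom a phantom template name (see [get_template()]) or a
#'   `phantom_template`
#' @param config a [ttf_config()]
#' @return list with `rows` (data.frame: one row per measured pin with
#'   `material`, `cnr`, `f50_inv_mm`, `f10_inv_mm`, `fit_rmse_hu`, `flags`),
#'   `ttf` (list of `ttf_result`), `rois`, `body`, `failures` (named
#'   character vector)
#' @export
measure_slice <- function(img, phantom, config = ttf_config()) {
  if (is.character(img)) img <- load_slice(img)
  template <- if (inherits(phantom, "phantom_template")) phantom
              else get_template(phantom)
  body <- segment_body(img, template$body_threshold_hu)
  masked <- apply_body_mask(img, body)
  pins <- segment_pins(masked, body, template)
  rois <- place_rois(masked, body, pins,
                     annulus_inner = config$annulus_inner,
                     annulus_outer = config$annulus_outer)
  ttf <- measure_ttf(masked, rois, config)
  rows <- do.call(rbind, lapply(ttf, function(t) data.frame(
    material = t$material_name,
    cnr = t$cnr,
    f50_inv_mm = t$f50_inv_mm,
    f10_inv_mm = t$f10_inv_mm,
    fit_rmse_hu = if (!is.null(t$fit)) t$fit$rmse_hu else NA_real_,
    flags = paste(t$flags, collapse = "|"),
    stringsAsFactors = FALSE)))
  rownames(rows) <- NULL
  list(rows = rows, ttf = ttf, rois = rois, body = body,
       failures = attr(ttf, "errors"))
}

#' Run the batch TTF measurement
#'
#' Accepts a single DICOM file or a directory of slices (measured
#' independently, ordered by filename) and produces a run report.
#'
#' @param input path to a DICOM file or directory
#' @param phantom phantom template name
#' @param config a [ttf_config()]
#' @return object of class `run_report`: `rows` (one per measured pin, with
#'   a `slice` column), `failures`, `slices` (per-slice detail), and
#'   `provenance`
#' @export
run_measurement <- function(input, phantom, config = ttf_config()) {
  files <- if (dir.exists(input)) {
    sort(list.files(input, full.names = TRUE, pattern = "\\.dcm$",
                    ignore.case = TRUE))
  } else input
  if (!length(files) || !all(file.exists(files)))
    stop_ttfqa(paste0("no readable input at ", input), "ttfqa_io_error")
  slices <- list(); rows <- list(); failures <- list()
  for (f in files) {
    res <- measure_slice(f, phantom, config)
    key <- basename(f)
    slices[[key]] <- res
    if (nrow(res$rows %||% data.frame())) {
      r <- res$rows
      r <- cbind(slice = key, phantom = phantom, r,
                 schema_version = REPORT_SCHEMA_VERSION,
                 stringsAsFactors = FALSE)
      rows[[key]] <- r
    }
    if (length(res$failures))
      failures[[key]] <- res$failures
  }
  structure(list(
    rows = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    failures = failures,
    slices = slices,
    provenance = list(input = normalizePath(input),
                      phantom = phantom,
                      config = unclass(config),
                      config_hash = config_hash(config),
                      version = as.character(utils::packageVersion("ttfqa")))),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d measured pin(s), %d failure group(s)\n",
              nrow(x$rows %||% data.frame()), length(x$failures)))
  if (!is.null(x$rows)) print(x$rows, digits = 4)
  for (s in names(x$failures))
    cat(" failures in", s, ":",
        paste(names(x$failures[[s]]), collapse = ", "), "\n")
  invisible(x)
}

#' Write a run report to disk
#'
#' Writes `report.csv` (stable, versioned column schema; deterministic given
#' input, config and seed) and `report.json` (rows, failures, TTF curves and
#' provenance; the JSON also carries a wall-clock timestamp). Optional PNG
#' plots: the TTF curves per slice and an ROI overlay.
#'
#' @param report a [run_measurement()] result
#' @param out_dir output directory (created if needed)
#' @param plots also write PNG plots
#' @return `out_dir`, invisibly
#' @export
write_report <- function(report, out_dir, plots = FALSE) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$rows, file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  curves <- lapply(report$slices, function(s)
    lapply(s$ttf, function(t) list(
      frequencies_inv_mm = t$frequencies_inv_mm[t$frequencies_inv_mm <= 2],
      ttf = t$ttf[t$frequencies_inv_mm <= 2])))
  jsonlite::write_json(
    list(rows = report$rows, failures = report$failures,
         curves = curves,
         provenance = c(report$provenance,
                        list(timestamp = format(Sys.time(), tz = "UTC")))),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  if (plots) {
    for (key in names(report$slices)) {
      s <- report$slices[[key]]
      grDevices::png(file.path(out_dir, paste0(key, "_ttf.png")),
                     width = 800, height = 600)
      plot_ttf_curves(s$ttf)
      grDevices::dev.off()
    }
  }
  invisible(out_dir)
}

#' Plot TTF curves of one slice
#'
#' @param ttf list of `ttf_result`
#' @param fmax frequency axis limit (1/mm)
#' @export
plot_ttf_curves <- function(ttf, fmax = 1.5) {
  if (!length(ttf)) return(invisible(NULL))
  cols <- grDevices::hcl.colors(max(3, length(ttf)), "Dark 3")
  graphics::plot(NULL, xlim = c(0, fmax), ylim = c(0, 1.05),
                 xlab = "spatial frequency (1/mm)", ylab = "TTF",
                 main = "Task-transfer functions")
  graphics::abline(h = c(0.5, 0.1), lty = 3, col = "grey")
  for (i in seq_along(ttf)) {
    t <- ttf[[i]]
    keep <- t$frequencies_inv_mm <= fmax
    graphics::lines(t$frequencies_inv_mm[keep], t$ttf[keep], col = cols[i],
                    lwd = 2)
  }
  graphics::legend("topright",
                   legend = vapply(ttf, `[[`, "", "material_name"),
                   col = cols[seq_along(ttf)], lwd = 2, bty = "n")
  invisible(NULL)
}

#' Render a preset phantom and write it as DICOM with a ground-truth sidecar
#'
#' @param preset preset name (see [phantom_preset()])
#' @param seed noise seed
#' @param out_dir output directory
#' @param ... further overrides for [phantom_preset()]
#' @return path of the written DICOM file, invisibly
#' @export
simulate_to_dicom <- function(preset, seed, out_dir, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- phantom_preset(preset, seed = seed, ...)
  rendered <- render_phantom(spec)
  path <- file.path(out_dir, sprintf("%s_seed%d.dcm", preset, seed))
  save_slice(rendered$image, path)
  jsonlite::write_json(rendered$truth,
                       sub("\\.dcm$", "_truth.json", path),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
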