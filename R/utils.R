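`%||%` <- function(a, b) if (is.null(a)) b else a

#' Physical coordinates of pixel centers
#'
#' Returns matrices of the row/column coordinates (mm) of every pixel center
#' of an image, using the convention that pixel (1,1) is centered at
#' origin + spacing/2.
#'
#' @param img an [hu_image]
#' @return list with matrices `row_mm` and `col_mm`
#' @keywords internal
pixel_centers <- function(img) {
  d <- dim(img$pixels)
  r <- img$origin[1] + (seq_len(d[1]) - 0.5) * img$spacing_mm[1]
  c <- img$origin[2] + (seq_len(d[2]) - 0.5) * img$spacing_mm[2]
  list(row_mm = matrix(r, d[1], d[2]),
       col_mm = matrix(c, d[1], d[2], byrow = TRUE))
}

#' Squared distance (mm^2) of every pixel center to a point
#' @keywords internal
dist2_to <- function(img, center_mm) {
  pc <- pixel_centers(img)
  (pc$row_mm - center_mm[1])^2 + (pc$col_mm - center_mm[2])^2
}

stop_ttfqa <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ttfqa_error")))
}

warn_ttfqa <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "ttfqa_warning")))
}
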