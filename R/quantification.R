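#' Quantify array spots by median intensity
#'
#' For every spot in the layout, takes the median over all pixels of its
#' rectangular synthesis footprint (even pixel counts average the two
#' central order statistics, the standard sample median) and assigns it to
#' the spot's peptide. No segmentation is attempted inside the footprint:
#' the synthesis rectangle, not cell morphology, defines the spot area.
#' Background is reported, not subtracted: `background_estimate` is the
#' global median intensity over blank spots (NA when the layout has none).
#'
#' @param image a `pep_scan_image` (or a numeric matrix with attribute
#'   `um_per_pixel`).
#' @param layout a `pep_layout`; its footprint must fit inside the image
#'   and share the image scale.
#' @return a tibble with columns `spot_id`, `peptide_id`, `row`, `col`,
#'   `intensity` (the median), `pixel_count`, `background_estimate`.
#' @export
quantify_spots <- function(image, layout) {
  grid <- layout_grid(layout)
  um_per_pixel <- attr(image, "um_per_pixel", exact = TRUE)
  if (is.null(um_per_pixel)) {
    abort("image lacks a 'um_per_pixel' attribute")
  }
  edge_px <- spot_edge_um(grid) / um_per_pixel
  if (abs(edge_px - round(edge_px)) > 1e-9) {
    abort("layout spot edge is not an integer number of image pixels")
  }
  edge_px <- as.integer(round(edge_px))
  img <- unclass(image)
  out_of_bounds <- layout$row * edge_px > nrow(img) |
    layout$col * edge_px > ncol(img)
  if (any(out_of_bounds)) {
    abort(sprintf("spot '%s' footprint exceeds the image bounds",
                  layout$spot_id[out_of_bounds][1]))
  }
  medians <- vapply(seq_len(nrow(layout)), function(i) {
    rows <- ((layout$row[i] - 1L) * edge_px + 1L):(layout$row[i] * edge_px)
    cols <- ((layout$col[i] - 1L) * edge_px + 1L):(layout$col[i] * edge_px)
    stats::median(img[rows, cols])
  }, numeric(1))
  bg <- if (any(layout$peptide_id == "BLANK")) {
    stats::median(medians[layout$peptide_id == "BLANK"])
  } else {
    NA_real_
  }
  tibble(
    spot_id = layout$spot_id, peptide_id = layout$peptide_id,
    row = layout$row, col = layout$col,
    intensity = medians,
    pixel_count = edge_px^2L,
    background_estimate = bg
  )
}
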