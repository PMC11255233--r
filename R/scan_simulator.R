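#' Assign latent adhesion strengths to a peptide library
#'
#' Ground-truth generator for pipeline validation. Each peptide receives a
#' latent adhesion `adhesion` (arbitrary fluorescence-proportional units):
#' unplanted peptides draw from a log-normal baseline, which reproduces the
#' heavy-tailed, orders-of-magnitude intensity spread a ranked adhesion
#' curve shows on a log axis; planted repulsive peptides and blanks get
#' exactly 0; planted adhesive peptides are placed above every unplanted
#' draw (a configurable multiple of the unplanted maximum), creating the
#' steep gradient spikes at the curve edges that extreme detection relies
#' on.
#'
#' @param library a library tibble from [assemble_library()].
#' @param meanlog,sdlog baseline log-normal parameters for unplanted
#'   peptides (defaults `log(2500)` and `0.8`).
#' @param planted_repulsive,planted_adhesive character vectors of peptide
#'   ids to plant at the extremes (must exist in the library, disjoint).
#' @param adhesive_factor,adhesive_jitter planted adhesive values are
#'   `max(unplanted) * runif(adhesive_factor, adhesive_factor +
#'   adhesive_jitter)`.
#' @param seed integer seed.
#' @return a `pep_adhesion`: tibble with columns `peptide_id`, `adhesion`,
#'   `planted` (`"repulsive"`, `"adhesive"` or `NA`), with the model
#'   parameters attached as attribute `model`.
#' @export
assign_latent_adhesion <- function(library,
                                   meanlog = log(2500), sdlog = 0.8,
                                   planted_repulsive = character(0),
                                   planted_adhesive = character(0),
                                   adhesive_factor = 2.5,
                                   adhesive_jitter = 0.25,
                                   seed = 1) {
  ids <- library$peptide_id
  missing <- setdiff(c(planted_repulsive, planted_adhesive), ids)
  if (length(missing) > 0) {
    abort(sprintf("planted peptide id '%s' is not in the library",
                  missing[1]))
  }
  if (length(intersect(planted_repulsive, planted_adhesive)) > 0) {
    abort("planted repulsive and adhesive sets must be disjoint")
  }
  planted <- rep(NA_character_, length(ids))
  planted[ids %in% planted_repulsive] <- "repulsive"
  planted[ids %in% planted_adhesive] <- "adhesive"
  is_blank <- library$group == "blank"
  unplanted <- is.na(planted) & !is_blank
  a <- numeric(length(ids))
  with_seed(seed, {
    a[unplanted] <- stats::rlnorm(sum(unplanted), meanlog, sdlog)
    top <- if (any(unplanted)) max(a[unplanted]) else exp(meanlog)
    n_adh <- sum(planted == "adhesive", na.rm = TRUE)
    a[!is.na(planted) & planted == "adhesive"] <-
      top * stats::runif(n_adh, adhesive_factor,
                         adhesive_factor + adhesive_jitter)
  })
  structure(
    tibble(peptide_id = ids, adhesion = a, planted = planted),
    model = list(meanlog = meanlog, sdlog = sdlog,
                 adhesive_factor = adhesive_factor,
                 adhesive_jitter = adhesive_jitter, seed = seed),
    class = c("pep_adhesion", class(tibble()))
  )
}

#' Simulate a per-spot intensity table
#'
#' The readout model is multiplicative on the latent adhesion scale:
#' `I_s = b + a_p * eps_s` with `eps_s ~ lognormal(0, sigma_rep)` drawn
#' independently for every replicate spot. Blank and zero-adhesion spots
#' therefore read exactly the background `b`, matching the empty-spot
#' floor of a real scan.
#'
#' @param layout a `pep_layout`.
#' @param adhesion a `pep_adhesion` covering every layout peptide.
#' @param background background level `b` in scanner units.
#' @param sigma_rep multiplicative replicate noise (log-sd).
#' @param seed integer seed.
#' @return a tibble with columns `spot_id`, `row`, `col`, `peptide_id`,
#'   `intensity`.
#' @export
simulate_intensity_table <- function(layout, adhesion, background = 200,
                                     sigma_rep = 0.1, seed = 1) {
  a <- stats::setNames(adhesion$adhesion, adhesion$peptide_id)
  if (!"BLANK" %in% names(a)) a[["BLANK"]] <- 0
  missing <- setdiff(unique(layout$peptide_id), names(a))
  if (length(missing) > 0) {
    abort(sprintf("no latent adhesion for layout peptide '%s'",
                  missing[1]))
  }
  ap <- unname(a[layout$peptide_id])
  eps <- with_seed(seed, stats::rlnorm(nrow(layout), 0, sigma_rep))
  tibble(
    spot_id = layout$spot_id, row = layout$row, col = layout$col,
    peptide_id = layout$peptide_id,
    intensity = background + ap * eps
  )
}

#' Write / read a GPR-dialect spot intensity table
#'
#' @param spots a spot-intensity tibble.
#' @param path file path.
#' @param config_hash optional provenance hash comment.
#' @export
write_intensities <- function(spots, path, config_hash = NULL) {
  write_tsv_hashed(spots, path, config_hash)
}

#' @rdname write_intensities
#' @export
read_intensities <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    spot_id = "c", row = "i", col = "i",
                    peptide_id = "c", intensity = "d"
                  ))
}

#' Render a synthetic fluorescence scan image
#'
#' Emulates a confocal fluorescence scan of cells settled on the array.
#' Each spot receives a Poisson number of cells with rate proportional to
#' its latent adhesion (`cells_scale` cells per adhesion unit); cells are
#' rendered as solid disks of fixed radius at uniform positions inside the
#' spot footprint, their intensities accumulate where disks overlap, and
#' the image gains a constant background, optional off-spot "lawn" cells,
#' and Gaussian read noise. Values are clamped to the 16-bit range.
#'
#' @param layout a `pep_layout`.
#' @param adhesion a `pep_adhesion`.
#' @param um_per_pixel image scale; must divide the spot edge into an
#'   integer number of pixels and not exceed the s-pixel size.
#' @param cell_radius_um rendered cell disk radius (a simulation
#'   convenience, not a biological claim).
#' @param cells_scale expected cells per spot per adhesion unit.
#' @param cell_amplitude added intensity per overlapping cell disk.
#' @param background constant background level.
#' @param read_noise_sd Gaussian read noise (0 disables).
#' @param lawn_rate expected off-spot cells per spot-sized area, spread
#'   uniformly over the whole image (0 disables).
#' @param max_pixels memory guard: error if the image would exceed this
#'   many pixels.
#' @param seed integer seed.
#' @return a `pep_scan_image`: 16-bit integer-valued numeric matrix with
#'   attributes `um_per_pixel` and `grid_spec`.
#' @export
render_scan_image <- function(layout, adhesion, um_per_pixel = 5,
                              cell_radius_um = 7, cells_scale = 0.1,
                              cell_amplitude = 600, background = 200,
                              read_noise_sd = 30, lawn_rate = 0,
                              max_pixels = 2e8, seed = 1) {
  grid <- layout_grid(layout)
  if (um_per_pixel > grid$s_pixel_um) {
    abort("um_per_pixel must not exceed the s-pixel size")
  }
  edge_px <- spot_edge_um(grid) / um_per_pixel
  if (abs(edge_px - round(edge_px)) > 1e-9) {
    abort("spot edge must be an integer number of pixels at this scale")
  }
  edge_px <- as.integer(round(edge_px))
  nr <- grid$grid_rows * edge_px
  nc <- grid$grid_cols * edge_px
  if (as.numeric(nr) * nc > max_pixels) {
    abort(sprintf("image of %d x %d pixels exceeds max_pixels = %g",
                  nr, nc, max_pixels))
  }
  a <- stats::setNames(adhesion$adhesion, adhesion$peptide_id)
  if (!"BLANK" %in% names(a)) a[["BLANK"]] <- 0
  ap <- unname(a[layout$peptide_id])
  if (anyNA(ap)) {
    abort("no latent adhesion for a layout peptide")
  }
  r_px <- cell_radius_um / um_per_pixel
  # disk stencil: pixel-centre offsets within the cell radius
  half <- ceiling(r_px)
  offs <- expand.grid(dy = -half:half, dx = -half:half)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r_px^2, ]
  counts <- matrix(0L, nr, nc)
  with_seed(seed, {
    ncells <- stats::rpois(nrow(layout), ap * cells_scale)
    total <- sum(ncells)
    if (lawn_rate > 0) {
      n_lawn <- stats::rpois(1, lawn_rate * grid$grid_rows * grid$grid_cols)
    } else {
      n_lawn <- 0L
    }
    if (total + n_lawn > 0) {
      spot_idx <- rep.int(seq_len(nrow(layout)), ncells)
      # uniform continuous positions inside each spot footprint
      cy <- (layout$row[spot_idx] - 1) * edge_px +
        stats::runif(total, 0, edge_px)
      cx <- (layout$col[spot_idx] - 1) * edge_px +
        stats::runif(total, 0, edge_px)
      if (n_lawn > 0) {
        cy <- c(cy, stats::runif(n_lawn, 0, nr))
        cx <- c(cx, stats::runif(n_lawn, 0, nc))
      }
      py <- rep(ceiling(cy), each = nrow(offs)) +
        rep.int(offs$dy, length(cy))
      px <- rep(ceiling(cx), each = nrow(offs)) +
        rep.int(offs$dx, length(cx))
      keep <- py >= 1 & py <= nr & px >= 1 & px <= nc
      lin <- (px[keep] - 1L) * nr + py[keep]
      hits <- tabulate(lin, nbins = as.numeric(nr) * nc)
      counts[] <- counts + hits
    }
    img <- background + cell_amplitude * counts
    if (read_noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, read_noise_sd)
    }
    img <- round(pmin(pmax(img, 0), 65535))
    structure(img, um_per_pixel = um_per_pixel, grid_spec = grid,
              class = "pep_scan_image")
  })
}

#' @export
print.pep_scan_image <- function(x, ...) {
  cat(sprintf("<pep_scan_image> %d x %d pixels, %g um/pixel, range [%g, %g]\n",
              nrow(x), ncol(x), attr(x, "um_per_pixel"), min(x), max(x)))
  invisible(x)
}

#' Write / read a scan image as 16-bit grayscale TIFF
#'
#' Requires the optional `tiff` package. Scale metadata is not stored in
#' the TIFF; pass `um_per_pixel` and the grid when reading back.
#'
#' @param image a `pep_scan_image`.
#' @param path file path.
#' @param um_per_pixel,grid scale and grid to attach on read.
#' @export
write_scan_tiff <- function(image, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required to write TIFF scans")
  }
  tiff::writeTIFF(unclass(image) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_scan_tiff
#' @export
read_scan_tiff <- function(path, um_per_pixel, grid) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required to read TIFF scans")
  }
  m <- round(tiff::readTIFF(path) * 65535)
  structure(m, um_per_pixel = um_per_pixel, grid_spec = grid,
            class = "pep_scan_image")
}
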