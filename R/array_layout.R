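#' Specify the spot grid of a peptide chip
#'
#' Geometry of the synthesis grid: the minimum synthesis area (one
#' "s-pixel") is a square of `s_pixel_um` on a side, and each peptide spot
#' is a square block of `spot_side_spx` s-pixels. The default 4 s-pixels of
#' 30 µm gives 120 µm spots; the large-spot configuration uses 20 s-pixels
#' (600 µm). Spots abut (pitch = spot side).
#'
#' @param grid_rows,grid_cols spot capacity of the chip region.
#' @param s_pixel_um s-pixel edge length in µm.
#' @param spot_side_spx spot edge in s-pixels.
#' @param seed seed for randomized spot placement.
#' @return an object of class `grid_spec`.
#' @examples
#' g <- grid_spec(10, 10)
#' spot_edge_um(g) # 120
#' @export
grid_spec <- function(grid_rows, grid_cols, s_pixel_um = 30,
                      spot_side_spx = 4, seed = 1) {
  stopifnot(
    grid_rows >= 1, grid_cols >= 1, s_pixel_um > 0, spot_side_spx >= 1
  )
  structure(
    list(
      grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
      s_pixel_um = s_pixel_um, spot_side_spx = as.integer(spot_side_spx),
      seed = as.integer(seed)
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d spots, %g um s-pixels, %d x %d s-pixel spots (%g um edge), seed %d\n",
    x$grid_rows, x$grid_cols, x$s_pixel_um, x$spot_side_spx,
    x$spot_side_spx, spot_edge_um(x), x$seed
  ))
  invisible(x)
}

#' Physical spot edge length in µm
#' @param grid a `grid_spec`.
#' @export
spot_edge_um <- function(grid) {
  grid$spot_side_spx * grid$s_pixel_um
}

#' Spot packing density per square centimetre
#'
#' Abutting square spots of edge e µm pack to `(10^4 / e)^2` spots/cm²;
#' 120 µm spots give about 6,944, i.e. roughly 7,000 peptide candidates per
#' square centimetre.
#' @param grid a `grid_spec`.
#' @export
spot_density_per_cm2 <- function(grid) {
  (1e4 / spot_edge_um(grid))^2
}

#' Randomized replicate spot layout
#'
#' Expands every library entry to its replicate spots and places them at
#' uniformly random positions on the grid (a seeded random bijection onto
#' a subset of grid cells); replicates are scattered independently so that
#' local effects on cell adhesion cannot bias any one peptide. All
#' remaining cells become explicit blank spots (`peptide_id "BLANK"`), so
#' downstream quantification covers the full grid and blanks define the
#' background floor.
#'
#' @param library a library tibble from [assemble_library()].
#' @param grid a [grid_spec()]; capacity must be at least the total
#'   replicate count.
#' @return a `pep_layout`: a tibble with columns `spot_id`, `row`, `col`
#'   (1-based grid coordinates), `peptide_id`, carrying the grid as
#'   attribute `grid_spec`.
#' @export
build_layout <- function(library, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  needed <- sum(library$replicates)
  capacity <- grid$grid_rows * grid$grid_cols
  if (capacity < needed) {
    abort(sprintf(
      "grid capacity %d is smaller than the %d replicate spots required",
      capacity, needed
    ))
  }
  ids <- rep(library$peptide_id, library$replicates)
  cells <- with_seed(grid$seed, sample.int(capacity, capacity))
  assigned <- c(ids, rep("BLANK", capacity - needed))
  ord <- order(cells)
  layout <- tibble(
    spot_id = sprintf("S%06d", seq_len(capacity)),
    row = ((cells[ord] - 1L) %/% grid$grid_cols) + 1L,
    col = ((cells[ord] - 1L) %% grid$grid_cols) + 1L,
    peptide_id = assigned[ord]
  )
  layout <- layout[order(layout$row, layout$col), ]
  layout$spot_id <- sprintf("S%06d", seq_len(capacity))
  new_layout(layout, grid)
}

new_layout <- function(df, grid) {
  structure(as_tibble(df), grid_spec = grid,
            class = c("pep_layout", class(tibble())))
}

#' Grid specification of a layout
#' @param layout a `pep_layout`.
#' @export
layout_grid <- function(layout) {
  attr(layout, "grid_spec", exact = TRUE)
}

#' Physical spot coordinates in µm
#'
#' Top-left corner of each spot footprint, with the chip origin at (0, 0):
#' `x_um = (col - 1) * spot_edge`, `y_um = (row - 1) * spot_edge`.
#' @param layout a `pep_layout`.
#' @return the layout with `x_um` and `y_um` columns added.
#' @export
spot_coordinates_um <- function(layout) {
  edge <- spot_edge_um(layout_grid(layout))
  dplyr::mutate(as_tibble(layout),
                x_um = (.data$col - 1) * edge,
                y_um = (.data$row - 1) * edge)
}

#' Write / read a layout as a GAL-dialect TSV
#'
#' A minimal, lossless, diffable array-list dialect: one `#pepscreen-gal`
#' metadata line carrying the grid geometry and seed, a column-name line,
#' then one row per spot. `read_layout(write_layout(L))` reproduces `L`
#' field for field.
#'
#' @param layout a `pep_layout`.
#' @param path file path.
#' @param config_hash optional provenance hash comment.
#' @return the path (write) or a `pep_layout` (read).
#' @export
write_layout <- function(layout, path, config_hash = NULL) {
  g <- layout_grid(layout)
  meta <- sprintf(
    "#pepscreen-gal\tgrid_rows=%d\tgrid_cols=%d\ts_pixel_um=%g\tspot_side_spx=%d\tseed=%d",
    g$grid_rows, g$grid_cols, g$s_pixel_um, g$spot_side_spx, g$seed
  )
  lines <- meta
  if (!is.null(config_hash)) lines <- c(hash_header(config_hash), lines)
  writeLines(lines, path)
  readr::write_tsv(as_tibble(layout), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  lines <- readLines(path)
  meta_i <- grep("^#pepscreen-gal\t", lines)
  if (length(meta_i) != 1) {
    abort("not a pepscreen GAL file: missing '#pepscreen-gal' metadata line")
  }
  fields <- strsplit(lines[meta_i], "\t", fixed = TRUE)[[1]][-1]
  kv <- strsplit(fields, "=", fixed = TRUE)
  meta <- stats::setNames(
    as.numeric(vapply(kv, `[`, character(1), 2)),
    vapply(kv, `[`, character(1), 1)
  )
  grid <- grid_spec(meta[["grid_rows"]], meta[["grid_cols"]],
                    meta[["s_pixel_um"]], meta[["spot_side_spx"]],
                    meta[["seed"]])
  body <- lines[-seq_len(meta_i + 1L)]
  header <- strsplit(lines[meta_i + 1L], "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("spot_id", "row", "col", "peptide_id"))) {
    abort(sprintf("malformed layout header at line %d", meta_i + 1L))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad) > 0) {
    abort(sprintf("malformed layout row at line %d",
                  meta_i + 1L + bad[1]))
  }
  df <- tibble(
    spot_id = vapply(parts, `[`, character(1), 1),
    row = as.integer(vapply(parts, `[`, character(1), 2)),
    col = as.integer(vapply(parts, `[`, character(1), 3)),
    peptide_id = vapply(parts, `[`, character(1), 4)
  )
  if (anyNA(df$row) || anyNA(df$col)) {
    abort("malformed layout row: non-integer grid coordinate")
  }
  dup <- duplicated(df[, c("row", "col")])
  if (any(dup)) {
    abort(sprintf("duplicate spot position (row %d, col %d)",
                  df$row[dup][1], df$col[dup][1]))
  }
  if (any(df$row > grid$grid_rows | df$col > grid$grid_cols |
            df$row < 1 | df$col < 1)) {
    abort("spot position outside the declared grid")
  }
  new_layout(df, grid)
}
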