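#' Repulsion threshold from blank spots
#'
#' Blank spots define the fluorescence floor of the screen, so a peptide
#' reading close to the blank level is effectively cell-free. The default
#' rule is `median(blanks) + 2 * mad(blanks)`.
#'
#' @param spots spot-level tibble with `peptide_id` and `intensity`
#'   (blanks carry `peptide_id == blank_id`).
#' @param blank_id id of blank spots.
#' @param n_mad multiplier on the blank MAD.
#' @return a single threshold in scanner units.
#' @export
repulsion_threshold <- function(spots, blank_id = "BLANK", n_mad = 2) {
  blanks <- spots$intensity[spots$peptide_id == blank_id]
  if (length(blanks) == 0) {
    abort("no blank spots found; pass an explicit threshold instead")
  }
  stats::median(blanks) + n_mad * stats::mad(blanks)
}

#' Build a position-by-residue substitution matrix
#'
#' Arranges the per-peptide intensities of a parent's single-substitution
#' variants into the deep-mutational-scanning layout: rows are parent
#' positions, columns the 20 residues, each cell the measured *Int.* of
#' the variant carrying that substitution. Cells at the parent's own
#' residue hold the parent's *Int.*; variants absent from the
#' measurements are masked (`measured = FALSE`), never imputed.
#'
#' @param parent parent peptide sequence.
#' @param measurements per-peptide tibble with `peptide_id`, `intensity`.
#' @param library library tibble containing the parent's substitution
#'   entries (`group == "substitution"`, matching `parent`).
#' @return a `pep_submatrix`: a long tibble with columns `position`,
#'   `residue`, `intensity`, `is_parent`, `measured`, `peptide_id`; the
#'   parent sequence is attribute `parent`. Use [submatrix_wide()] for the
#'   `|parent| x 20` matrix form.
#' @export
build_substitution_matrix <- function(parent, measurements, library) {
  check_canonical(parent, "parent")
  entries <- library[library$group == "substitution" &
                       !is.na(library$parent) &
                       library$parent == parent, ]
  if (nrow(entries) == 0) {
    abort("library contains no substitution entries for this parent")
  }
  L <- nchar(parent)
  chars <- strsplit(parent, "", fixed = TRUE)[[1]]
  bad <- !is.na(entries$sub_pos) &
    (entries$sub_pos < 1 | entries$sub_pos > L)
  if (any(bad)) {
    abort(sprintf(
      "variant '%s' has substitution position %d outside the parent",
      entries$peptide_id[bad][1], entries$sub_pos[bad][1]
    ))
  }
  int <- stats::setNames(measurements$intensity, measurements$peptide_id)
  grid <- tidyr::expand_grid(position = seq_len(L), residue = AA_ALPHABET)
  variants <- entries[!is.na(entries$sub_pos), ]
  key <- paste(variants$sub_pos, variants$sub_to)
  vid <- stats::setNames(variants$peptide_id, key)
  parent_row <- entries[is.na(entries$sub_pos), ]
  parent_id <- if (nrow(parent_row) > 0) parent_row$peptide_id[1] else
    NA_character_
  cell_id <- vid[paste(grid$position, grid$residue)]
  is_parent <- chars[grid$position] == grid$residue
  cell_id[is_parent] <- parent_id
  out <- tibble(
    position = grid$position, residue = grid$residue,
    peptide_id = unname(cell_id),
    is_parent = is_parent,
    intensity = unname(int[cell_id]),
    measured = !is.na(unname(int[cell_id]))
  )
  structure(out, parent = parent,
            class = c("pep_submatrix", class(tibble())))
}

#' Wide matrix form of a substitution matrix
#' @param x a `pep_submatrix`.
#' @return a `|parent| x 20` numeric matrix (rows = positions, columns =
#'   residues); masked cells are `NA`.
#' @export
submatrix_wide <- function(x) {
  wide <- tidyr::pivot_wider(
    as_tibble(x)[, c("position", "residue", "intensity")],
    names_from = "residue", values_from = "intensity"
  )
  m <- as.matrix(wide[, AA_ALPHABET])
  rownames(m) <- wide$position
  m
}

#' Flag critical single substitutions
#'
#' Returns the substitutions whose variant intensity drops below the
#' repulsion threshold — single mutations that switch an otherwise
#' adhesive parent to cell-repellent. The `specific` flag applies the
#' position-specificity criterion: a call is position-specific when
#' introducing the same destination residue at every other position
#' leaves the intensity above the threshold, so the effect is tied to the
#' position, not to the residue per se.
#'
#' @param matrix a `pep_submatrix`.
#' @param threshold repulsion threshold in scanner units (e.g. from
#'   [repulsion_threshold()]); must lie within the observed intensity
#'   range.
#' @param position_specific compute the specificity flag.
#' @return a tibble with columns `position`, `residue`, `intensity`,
#'   `specific`, sorted by intensity; empty when nothing falls below the
#'   threshold. Parent cells are never called.
#' @export
find_critical_substitutions <- function(matrix, threshold,
                                        position_specific = TRUE) {
  obs <- matrix$intensity[matrix$measured]
  if (length(obs) == 0) abort("no measured cells in the matrix")
  if (threshold < min(obs) || threshold > max(obs)) {
    abort("threshold lies outside the observed intensity range")
  }
  hits <- matrix[matrix$measured & !matrix$is_parent &
                   matrix$intensity < threshold, ]
  if (nrow(hits) == 0) {
    return(tibble(position = integer(0), residue = character(0),
                  intensity = numeric(0), specific = logical(0)))
  }
  specific <- rep(NA, nrow(hits))
  if (position_specific) {
    specific <- vapply(seq_len(nrow(hits)), function(i) {
      others <- matrix[matrix$residue == hits$residue[i] &
                         matrix$position != hits$position[i] &
                         matrix$measured, ]
      nrow(others) > 0 && all(others$intensity >= threshold)
    }, logical(1))
  }
  out <- tibble(
    position = hits$position, residue = hits$residue,
    intensity = hits$intensity, specific = specific
  )
  out[order(out$intensity), ]
}
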