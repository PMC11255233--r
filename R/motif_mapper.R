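#' Per-protein track of overlapping-window intensities
#'
#' Lays the measured intensities of a protein's scan windows along the
#' protein: entry `start` holds the *Int.* of the k-mer window beginning
#' at that residue (1-based). A protein of length L at window length k
#' gives a track of `L - k + 1` starts; windows without a measurement are
#' masked.
#'
#' @param protein protein id.
#' @param measurements per-peptide tibble with `peptide_id`, `intensity`.
#' @param library library tibble containing the protein's scan windows.
#' @return a `pep_track`: tibble with columns `start`, `peptide_id`,
#'   `sequence`, `intensity`, `measured`; attributes `protein` and `k`.
#' @export
window_track <- function(protein, measurements, library) {
  wins <- library[library$group == "scan" &
                    !is.na(library$source_protein) &
                    library$source_protein == protein, ]
  if (nrow(wins) == 0) {
    abort(sprintf("library contains no scan windows for protein '%s'",
                  protein))
  }
  k <- unique(nchar(wins$sequence))
  if (length(k) != 1) {
    abort("scan windows for one protein must share a single length k")
  }
  int <- stats::setNames(measurements$intensity, measurements$peptide_id)
  starts <- seq.int(min(wins$start), max(wins$start))
  idx <- match(starts, wins$start)
  out <- tibble(
    start = starts,
    peptide_id = wins$peptide_id[idx],
    sequence = wins$sequence[idx],
    intensity = unname(int[wins$peptide_id[idx]]),
    measured = !is.na(unname(int[wins$peptide_id[idx]]))
  )
  structure(out, protein = protein, k = as.integer(k),
            class = c("pep_track", class(tibble())))
}

#' Flag extreme windows on a track
#'
#' Repulsive flags mark windows at or below a floor threshold (typically
#' the blank-based [repulsion_threshold()]); adhesive flags mark windows
#' at or above a ceiling (typically an upper intensity quantile of the
#' whole screen). Unmeasured windows are never flagged.
#'
#' @param track a `pep_track`.
#' @param threshold intensity threshold.
#' @param side `"repulsive"` (flag `<= threshold`) or `"adhesive"`
#'   (flag `>= threshold`).
#' @return the track with a logical `flagged` column added.
#' @export
flag_windows <- function(track, threshold,
                         side = c("repulsive", "adhesive")) {
  side <- match.arg(side)
  flagged <- track$measured & if (side == "repulsive") {
    track$intensity <= threshold
  } else {
    track$intensity >= threshold
  }
  track$flagged <- flagged
  track
}

#' Infer minimal motifs from runs of flagged overlapping windows
#'
#' Adjacent k-mer windows overlap in k - 1 residues, so when a maximal run
#' of r consecutive window starts `[i, i + r - 1]` is all flagged, the
#' residues common to every window in the run are
#' `[i + r - 1, i + k - 1]` — a shared subsequence of length
#' `k - r + 1`. That intersection is the minimal motif explaining the run:
#' the longer the run, the shorter (and more precisely localized) the
#' motif. Runs longer than k would have an empty core; these are reported
#' with `core_empty = TRUE`, the run's full span and no motif sequence.
#'
#' @param track a flagged `pep_track` (see [flag_windows()]), or a track
#'   plus an explicit logical `flags` vector.
#' @param protein the protein record (tibble row or named character) the
#'   track derives from; needed to extract motif sequences.
#' @param flags optional logical vector overriding `track$flagged`.
#' @return a tibble with columns `protein`, `motif`, `start`, `end`
#'   (1-based inclusive residues), `run_length`, `mean_intensity`,
#'   `core_empty`, sorted by `mean_intensity`.
#' @export
infer_minimal_motifs <- function(track, protein, flags = NULL) {
  k <- attr(track, "k", exact = TRUE)
  protein_id <- attr(track, "protein", exact = TRUE)
  proteins <- as_proteins(protein)
  seq <- proteins$sequence[match(protein_id, proteins$id)]
  if (is.na(seq)) {
    abort(sprintf("protein '%s' not found", protein_id))
  }
  flags <- flags %||% track$flagged
  if (is.null(flags)) {
    abort("track has no 'flagged' column; run flag_windows() first")
  }
  if (!any(flags)) {
    return(tibble(protein = character(0), motif = character(0),
                  start = integer(0), end = integer(0),
                  run_length = integer(0), mean_intensity = numeric(0),
                  core_empty = logical(0)))
  }
  runs <- rle(flags)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  keep <- which(runs$values)
  calls <- purrr::map_dfr(keep, function(j) {
    i <- track$start[run_start[j]]
    r <- runs$lengths[j]
    mean_int <- mean(track$intensity[run_start[j]:run_end[j]],
                     na.rm = TRUE)
    if (r > k) {
      # overlap-free core: the windows share no residue; report the span
      tibble(protein = protein_id, motif = NA_character_,
             start = i, end = i + r + k - 2L,
             run_length = r, mean_intensity = mean_int,
             core_empty = TRUE)
    } else {
      s <- i + r - 1L
      e <- i + k - 1L
      tibble(protein = protein_id,
             motif = substr(seq, s, e),
             start = as.integer(s), end = as.integer(e),
             run_length = as.integer(r), mean_intensity = mean_int,
             core_empty = FALSE)
    }
  })
  calls[order(calls$mean_intensity), ]
}

#' Reference list of reported cell-repellent peptides
#'
#' The published list of minimal repulsive peptides found on SFRP1, DKK1
#' and TNF-alpha in the original screen, shipped as a plain-text fixture
#' for parsing/mapping regression tests. Raw screen intensities are not
#' bundled, so this list documents sequence-level findings only.
#'
#' @return a tibble with columns `n`, `protein`, `peptide`.
#' @export
reference_repulsive_peptides <- function() {
  path <- system.file("extdata", "repulsive_peptides_reference.tsv",
                      package = "pepscreen")
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(n = "i", protein = "c",
                                          peptide = "c"))
}

#' Export motif calls as a BED track and per-residue table
#'
#' BED intervals are 0-based half-open (a motif at 1-based residues
#' `[start, end]` becomes `[start - 1, end)`), named by motif sequence and
#' scored 0–1000 by scaled mean intensity. The TSV lists one row per
#' protein residue with an in-motif flag, ready for structure coloring or
#' plotting.
#'
#' @param calls a motif-call tibble from [infer_minimal_motifs()].
#' @param protein the protein record the calls map to.
#' @param bed_path,tsv_path output paths (`NULL` skips that file).
#' @param config_hash optional provenance hash comment.
#' @return invisibly, a list with elements `bed` and `residues`.
#' @export
export_residue_track <- function(calls, protein, bed_path = NULL,
                                 tsv_path = NULL, config_hash = NULL) {
  proteins <- as_proteins(protein)
  calls <- calls[!calls$core_empty, , drop = FALSE]
  if (nrow(calls) > 0) {
    pidx <- match(calls$protein, proteins$id)
    if (anyNA(pidx)) abort("motif call references an unknown protein")
    plen <- proteins$length[pidx]
    if (any(calls$start < 1 | calls$end > plen)) {
      abort("motif outside protein bounds")
    }
    score <- if (max(calls$mean_intensity) > 0) {
      round(1000 * calls$mean_intensity / max(calls$mean_intensity))
    } else {
      rep(0L, nrow(calls))
    }
    bed <- tibble(
      chrom = calls$protein,
      chromStart = calls$start - 1L,
      chromEnd = calls$end,
      name = calls$motif,
      score = as.integer(score),
      strand = "."
    )
  } else {
    bed <- tibble(chrom = character(0), chromStart = integer(0),
                  chromEnd = integer(0), name = character(0),
                  score = integer(0), strand = character(0))
  }
  residues <- purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    n <- proteins$length[i]
    in_motif <- rep(FALSE, n)
    which_calls <- calls[calls$protein == proteins$id[i], , drop = FALSE]
    for (j in seq_len(nrow(which_calls))) {
      in_motif[which_calls$start[j]:which_calls$end[j]] <- TRUE
    }
    tibble(
      protein = proteins$id[i],
      position = seq_len(n),
      residue = strsplit(proteins$sequence[i], "", fixed = TRUE)[[1]],
      in_motif = in_motif
    )
  })
  if (!is.null(bed_path)) {
    header <- character(0)
    if (!is.null(config_hash)) header <- hash_header(config_hash)
    writeLines(c(header, sprintf(
      "%s\t%d\t%d\t%s\t%d\t%s", bed$chrom, bed$chromStart, bed$chromEnd,
      bed$name, bed$score, bed$strand
    )), bed_path)
  }
  if (!is.null(tsv_path)) {
    write_tsv_hashed(residues, tsv_path, config_hash)
  }
  invisible(list(bed = bed, residues = residues))
}
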