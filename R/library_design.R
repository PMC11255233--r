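#' Tile proteins into overlapping peptide windows
#'
#' Decomposes each protein into all k-mer windows at a fixed offset, the
#' classic overlapping-peptide ("scan") library: at `step = 1` adjacent
#' windows share `k - 1` residues, so a protein of length L yields
#' `L - k + 1` peptides.
#'
#' @param proteins a tibble with columns `id` and `sequence` (as returned
#'   by [read_proteins()] or [random_proteins()]), or a named character
#'   vector of sequences.
#' @param k window length in residues (default 15).
#' @param step window offset in residues (default 1).
#' @return a tibble of peptide entries with columns `peptide_id`,
#'   `sequence`, `group` (`"scan"`), `source_protein`, `start` (1-based
#'   residue position of the window).
#' @examples
#' tile_protein(c(demo = "ACDEFGH"), k = 5)
#' @export
tile_protein <- function(proteins, k = 15, step = 1) {
  stopifnot(k >= 1, step >= 1)
  proteins <- as_proteins(proteins)
  short <- proteins$length < k
  if (any(short)) {
    abort(sprintf(
      "protein '%s' (length %d) is shorter than the window length k = %d",
      proteins$id[short][1], proteins$length[short][1], k
    ))
  }
  purrr::map2_dfr(proteins$id, proteins$sequence, function(id, seq) {
    starts <- seq.int(1L, nchar(seq) - k + 1L, by = step)
    tibble(
      peptide_id = sprintf("%s_%04d", id, starts),
      sequence = substring(seq, starts, starts + k - 1L),
      group = "scan",
      source_protein = id,
      start = as.integer(starts)
    )
  })
}

#' Single-substitution scan of parent peptides
#'
#' For each parent peptide, generates every variant obtained by replacing
#' one position with each of the other 19 canonical amino acids — the
#' deep-mutational-scanning layout used to find position-critical residues.
#'
#' @param parents character vector of parent peptide sequences (optionally
#'   named; names become id prefixes).
#' @param include_parent also emit the unmodified parent as an entry
#'   (default `TRUE`).
#' @return a tibble of peptide entries with columns `peptide_id`,
#'   `sequence`, `group` (`"substitution"`), `parent`, `sub_pos`,
#'   `sub_from`, `sub_to` (all three `NA` for the parent entry itself).
#'   Exactly `19 * nchar(parent)` variants per parent, plus one parent row
#'   when `include_parent` is `TRUE`.
#' @examples
#' substitution_scan("NRWHE", include_parent = FALSE)
#' @export
substitution_scan <- function(parents, include_parent = TRUE) {
  check_canonical(parents, "parent")
  prefixes <- names(parents) %||% paste0("sub", seq_along(parents))
  purrr::map2_dfr(parents, prefixes, function(parent, prefix) {
    chars <- strsplit(parent, "", fixed = TRUE)[[1]]
    grid <- tidyr::expand_grid(pos = seq_along(chars), to = AA_ALPHABET)
    grid <- grid[grid$to != chars[grid$pos], ]
    variants <- purrr::map2_chr(grid$pos, grid$to, function(p, aa) {
      v <- chars
      v[p] <- aa
      paste(v, collapse = "")
    })
    out <- tibble(
      peptide_id = sprintf("%s_p%02d%s", prefix, grid$pos, grid$to),
      sequence = variants,
      group = "substitution",
      parent = parent,
      sub_pos = as.integer(grid$pos),
      sub_from = chars[grid$pos],
      sub_to = grid$to
    )
    if (include_parent) {
      out <- dplyr::bind_rows(
        tibble(
          peptide_id = paste0(prefix, "_parent"), sequence = parent,
          group = "substitution", parent = parent,
          sub_pos = NA_integer_, sub_from = NA_character_,
          sub_to = NA_character_
        ),
        out
      )
    }
    out
  })
}

#' Random recombination of scan-peptide fragments
#'
#' Builds the combinatorial third library group: each sequence is the
#' prefix of one randomly chosen pool peptide joined, at a random split
#' point, to the suffix of another, trimmed centrally to the target
#' length. Duplicates of other outputs or of pool members are rejected and
#' re-drawn, so the result is a set of unique sequences disjoint from the
#' pool. A pure function of `(pool, n, length, seed)`.
#'
#' @param pool a tibble of scan peptides (needs a `sequence` column) or a
#'   character vector of sequences.
#' @param n number of unique sequences to generate.
#' @param length target peptide length (default 15).
#' @param seed integer seed.
#' @param max_attempts attempt budget; if `n` unique sequences cannot be
#'   reached the function errors, reporting the achieved count.
#' @return a tibble of peptide entries with `group = "random"`.
#' @export
recombine_fragments <- function(pool, n, length = 15, seed,
                                max_attempts = 50 * n) {
  if (is.data.frame(pool)) pool <- pool$sequence
  stopifnot(length(pool) >= 1, n >= 1, length >= 2)
  check_canonical(pool, "pool peptide")
  pool_set <- unique(pool)
  out <- with_seed(seed, {
    seen <- character(0)
    attempts <- 0L
    while (length(seen) < n && attempts < max_attempts) {
      batch <- min(2L * (n - length(seen)), 10000L)
      attempts <- attempts + batch
      i <- sample.int(length(pool_set), batch, replace = TRUE)
      j <- sample.int(length(pool_set), batch, replace = TRUE)
      cand <- purrr::map2_chr(pool_set[i], pool_set[j], function(a, b) {
        s <- sample.int(min(nchar(a), nchar(b)) - 1L, 1L)
        recombined <- paste0(substr(a, 1L, s), substr(b, s + 1L, nchar(b)))
        # centre-crop (or reject) so every emitted sequence has the target
        # length even when pool members differ in length
        if (nchar(recombined) < length) return(NA_character_)
        off <- (nchar(recombined) - length) %/% 2L
        substr(recombined, off + 1L, off + length)
      })
      cand <- cand[!is.na(cand)]
      cand <- setdiff(unique(cand), c(pool_set, seen))
      seen <- c(seen, cand)
    }
    seen
  })
  if (length(out) < n) {
    abort(sprintf(
      "could only generate %d of %d unique recombined sequences within the attempt budget",
      length(out), n
    ))
  }
  out <- out[seq_len(n)]
  tibble(
    peptide_id = sprintf("rand_%05d", seq_len(n)),
    sequence = out,
    group = "random"
  )
}

#' The HA epitope control peptide
#'
#' Influenza haemagglutinin epitope used as an array quality control; in
#' adhesion screens it is also the strongest adhesive sequence.
#' @export
HA_EPITOPE <- "YPYDVPDYA"

#' Assemble the full peptide library
#'
#' Concatenates the three library groups — protein tilings, substitution
#' scans and random recombinations — plus control (HA epitope) and blank
#' entries, and assigns per-group replicate counts. Entries are kept even
#' when sequences collide across groups; cross-group duplicates are
#' reported by [library_duplicates()] rather than silently dropped.
#'
#' @param proteins proteins tibble or named character vector (may be
#'   `NULL` for no scan group).
#' @param parents character vector of substitution parents (may be `NULL`).
#' @param k,step tiling window length and offset.
#' @param n_random size of the random recombination group (0 disables).
#' @param replicates named vector of per-group replicate spot counts;
#'   defaults to the screen's 5/3/2 design with 5 for controls.
#' @param include_parent include parent peptides in the substitution group.
#' @param controls named character vector of control peptides.
#' @param n_blank_entries number of explicit blank (empty-sequence)
#'   entries; blank entries carry `replicates` each.
#' @param seed integer seed (drives the random group).
#' @return a tibble of peptide entries with columns `peptide_id`,
#'   `sequence`, `group`, `source_protein`, `start`, `parent`, `sub_pos`,
#'   `sub_from`, `sub_to`, `replicates`.
#' @export
assemble_library <- function(proteins = NULL, parents = NULL,
                             k = 15, step = 1, n_random = 0,
                             replicates = c(scan = 5, substitution = 3,
                                            random = 2, control = 5,
                                            blank = 5),
                             include_parent = TRUE,
                             controls = c(HA = HA_EPITOPE),
                             n_blank_entries = 1,
                             seed = 1) {
  stopifnot(all(replicates >= 1))
  groups <- list()
  if (!is.null(proteins)) {
    groups$scan <- tile_protein(proteins, k = k, step = step)
  }
  if (!is.null(parents)) {
    groups$substitution <- substitution_scan(parents, include_parent)
  }
  if (n_random > 0) {
    if (is.null(groups$scan)) {
      abort("the random group recombines scan peptides; supply proteins")
    }
    groups$random <- recombine_fragments(groups$scan, n = n_random,
                                         length = k, seed = seed)
  }
  if (length(controls) > 0) {
    check_canonical(controls, "control")
    groups$control <- tibble(
      peptide_id = paste0("ctrl_", names(controls) %||%
                            seq_along(controls)),
      sequence = unname(controls),
      group = "control"
    )
  }
  if (n_blank_entries > 0) {
    groups$blank <- tibble(
      peptide_id = if (n_blank_entries == 1) "BLANK" else
        sprintf("BLANK_%02d", seq_len(n_blank_entries)),
      sequence = "",
      group = "blank"
    )
  }
  lib <- dplyr::bind_rows(groups)
  template <- tibble(
    source_protein = NA_character_, start = NA_integer_,
    parent = NA_character_, sub_pos = NA_integer_,
    sub_from = NA_character_, sub_to = NA_character_
  )
  for (col in names(template)) {
    if (!col %in% names(lib)) lib[[col]] <- template[[col]]
  }
  lib$replicates <- as.integer(replicates[lib$group])
  if (anyNA(lib$replicates)) {
    abort("replicates must name every group present in the library")
  }
  if (anyDuplicated(lib$peptide_id)) {
    abort(sprintf("duplicate peptide id '%s'",
                  lib$peptide_id[duplicated(lib$peptide_id)][1]))
  }
  lib <- lib[, c("peptide_id", "sequence", "group", "source_protein",
                 "start", "parent", "sub_pos", "sub_from", "sub_to",
                 "replicates")]
  dups <- library_duplicates(lib)
  if (nrow(dups) > 0) {
    rlang::inform(sprintf(
      "%d sequence(s) occur in more than one library entry (%d unique sequences among %d non-blank entries); see library_duplicates()",
      nrow(dups), length(unique(lib$sequence[lib$group != "blank"])),
      sum(lib$group != "blank")
    ))
  }
  lib
}

#' Report sequences shared by multiple library entries
#'
#' The deduplication policy is report-only: colliding entries (within or
#' across groups) stay in the library, and this accessor lists them so the
#' unique-sequence count can be reconciled with per-group totals.
#'
#' @param library a library tibble from [assemble_library()].
#' @return a tibble with `sequence`, `n_entries`, `peptide_ids`, `groups`.
#' @export
library_duplicates <- function(library) {
  lib <- library[library$group != "blank", ]
  lib |>
    dplyr::summarise(
      n_entries = dplyr::n(),
      peptide_ids = paste(.data$peptide_id, collapse = ","),
      groups = paste(sort(unique(.data$group)), collapse = ","),
      .by = "sequence"
    ) |>
    dplyr::filter(.data$n_entries > 1)
}

#' Write / read a peptide library as TSV
#'
#' @param library a library tibble.
#' @param path file path.
#' @param config_hash optional provenance hash written as a `#` comment.
#' @return the path (write) or the library tibble (read).
#' @export
write_library <- function(library, path, config_hash = NULL) {
  write_tsv_hashed(library, path, config_hash)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  readr::read_tsv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      peptide_id = "c", sequence = "c", group = "c",
      source_protein = "c", start = "i", parent = "c",
      sub_pos = "i", sub_from = "c", sub_to = "c", replicates = "i"
    )
  ) |>
    dplyr::mutate(sequence = dplyr::coalesce(.data$sequence, ""))
}
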