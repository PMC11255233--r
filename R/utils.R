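#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# Canonical 20-letter amino-acid alphabet; anything else (X, U, B, Z, ...)
# is rejected at parse time.
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Check peptide/protein sequences for canonical residues
#'
#' @param x character vector of sequences.
#' @param what label used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error naming the first
#'   offending sequence and position.
#' @keywords internal
check_canonical <- function(x, what = "sequence") {
  for (i in seq_along(x)) {
    s <- x[[i]]
    if (is.na(s) || !nzchar(s)) {
      abort(sprintf("%s %d is empty", what, i))
    }
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% AA_ALPHABET)
    if (length(bad) > 0) {
      abort(sprintf(
        "%s %d contains non-canonical residue '%s' at position %d",
        what, i, chars[bad[1]], bad[1]
      ))
    }
  }
  invisible(x)
}

# Run `code` under a reproducible, isolated RNG stream. All stochastic
# operations in the package funnel through this so that a seed argument
# fully determines the output without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    abort("a seed is required for reproducible randomized operations")
  }
  withr::with_seed(as.integer(as.numeric(seed) %% .Machine$integer.max),
                   code)
}

# Derive a child seed from a master seed; keeps results < 2^31.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(offset)) %%
               .Machine$integer.max)
}

#' Generate random synthetic proteins
#'
#' Produces seeded random amino-acid sequences, typically used to stand in
#' for real screened proteins when exercising the pipeline with known
#' ground truth. Residues are drawn uniformly from the canonical alphabet.
#'
#' @param lengths named integer vector of protein lengths; names become
#'   protein ids (unnamed vectors get ids `protein_1`, ...).
#' @param seed integer seed.
#' @return a tibble with columns `id`, `sequence`, `length`.
#' @examples
#' random_proteins(c(SFRP1 = 314, DKK1 = 266, TNFA = 233), seed = 1)
#' @export
random_proteins <- function(lengths, seed) {
  stopifnot(length(lengths) >= 1, all(lengths >= 1))
  ids <- names(lengths)
  if (is.null(ids)) ids <- paste0("protein_", seq_along(lengths))
  seqs <- with_seed(seed, {
    vapply(lengths, function(n) {
      paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
    }, character(1))
  })
  tibble(id = ids, sequence = unname(seqs), length = nchar(unname(seqs)))
}

#' Read protein sequences from a FASTA file
#'
#' Multi-record, wrapped-line FASTA is supported. Sequences must use the
#' canonical 20-letter alphabet.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `id`, `sequence`, `length`.
#' @export
read_proteins <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  check_canonical(seqs, "protein")
  tibble(id = ids, sequence = unname(seqs), length = nchar(unname(seqs)))
}

# Coerce either a proteins tibble or a named character vector to the
# canonical proteins tibble.
as_proteins <- function(proteins) {
  if (is.character(proteins)) {
    ids <- names(proteins) %||% paste0("protein_", seq_along(proteins))
    proteins <- tibble(id = ids, sequence = unname(proteins))
  }
  proteins <- as_tibble(proteins)
  if (!all(c("id", "sequence") %in% names(proteins))) {
    abort("proteins must have columns 'id' and 'sequence'")
  }
  check_canonical(proteins$sequence, "protein")
  proteins$length <- nchar(proteins$sequence)
  proteins
}

# Header comment written at the top of every pipeline output file so any
# artifact can be traced back to the configuration that produced it.
hash_header <- function(config_hash) {
  sprintf("# pepscreen config_hash=%s", config_hash)
}

write_tsv_hashed <- function(df, path, config_hash = NULL) {
  if (!is.null(config_hash)) {
    writeLines(hash_header(config_hash), path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(df, path)
  }
  invisible(path)
}
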