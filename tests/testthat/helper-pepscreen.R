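# Shared builders for small synthetic screens. Everything is generated in
# code under fixed seeds; no stored fixtures beyond the plain-text scale
# tables shipped with the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A compact library: two proteins, one substitution parent, a small random
# group, HA control and one blank entry.
small_library <- function(seed = 11, n_random = 20,
                          lengths = c(protA = 40, protB = 30)) {
  assemble_library(
    proteins = random_proteins(lengths, seed = seed),
    parents = c("NRWHE"),
    n_random = n_random,
    seed = seed + 1
  )
}

# Library + layout + ground-truth adhesion + spot intensity table, with
# planted repulsive/adhesive sets.
small_screen <- function(seed = 11, n_random = 20, n_rep = 5, n_adh = 2,
                         sigma_rep = 0.1, grid_side = 24) {
  lib <- small_library(seed = seed, n_random = n_random)
  peptides <- lib$peptide_id[lib$group %in% c("scan", "random")]
  planted_rep <- peptides[seq_len(n_rep)]
  planted_adh <- rev(peptides)[seq_len(n_adh)]
  lay <- build_layout(lib, grid_spec(grid_side, grid_side, seed = seed + 2))
  adh <- assign_latent_adhesion(
    lib, planted_repulsive = planted_rep, planted_adhesive = planted_adh,
    seed = seed + 3
  )
  spots <- simulate_intensity_table(lay, adh, sigma_rep = sigma_rep,
                                    seed = seed + 4)
  list(
    library = lib, layout = lay, adhesion = adh, spots = spots,
    planted_repulsive = planted_rep, planted_adhesive = planted_adh
  )
}

# All-blank layout on a given grid (for hand-built images).
blank_layout <- function(grid) {
  lib <- assemble_library(
    n_random = 0, controls = character(0),
    replicates = c(scan = 5, substitution = 3, random = 2,
                   control = 5, blank = 1),
    seed = 1
  )
  build_layout(lib, grid)
}

# Brute-force per-spot median oracle: re-derives every footprint pixel set
# and takes a sort-based median, independently of quantify_spots().
oracle_spot_medians <- function(image, layout) {
  grid <- layout_grid(layout)
  edge_px <- as.integer(spot_edge_um(grid) / attr(image, "um_per_pixel"))
  img <- unclass(image)
  vapply(seq_len(nrow(layout)), function(i) {
    rows <- ((layout$row[i] - 1L) * edge_px + 1L):(layout$row[i] * edge_px)
    cols <- ((layout$col[i] - 1L) * edge_px + 1L):(layout$col[i] * edge_px)
    v <- sort(as.numeric(img[rows, cols]))
    n <- length(v)
    if (n %% 2L == 1L) v[(n + 1L) / 2L] else (v[n / 2L] + v[n / 2L + 1L]) / 2
  }, numeric(1))
}

# Tiny hand-made scan image: spot edge of `edge_px` pixels, with the
# matching um_per_pixel so quantify_spots() accepts it.
manual_image <- function(values, grid, edge_px = 2) {
  um_per_pixel <- spot_edge_um(grid) / edge_px
  structure(values, um_per_pixel = um_per_pixel, grid_spec = grid,
            class = "pep_scan_image")
}

# Independent motif oracle: intersect the residue-position sets of all
# flagged windows in a run, then extract the contiguous intersection.
oracle_run_motif <- function(protein_seq, starts, k) {
  sets <- lapply(starts, function(s) seq.int(s, s + k - 1L))
  shared <- Reduce(intersect, sets)
  if (length(shared) == 0) return(NULL)
  list(start = min(shared), end = max(shared),
       motif = substr(protein_seq, min(shared), max(shared)))
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
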