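#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Configure an end-to-end screen run
#'
#' Collects every stage's parameters into one serializable list. Module
#' seeds are derived deterministically from the master seed, so one
#' integer reproduces the whole run. `proteins = NULL` generates seeded
#' synthetic proteins of the given `protein_lengths`.
#'
#' @param proteins proteins tibble / named character vector, a FASTA path,
#'   or `NULL` for synthetic proteins.
#' @param protein_lengths lengths for synthetic proteins (named vector).
#' @param parents substitution-scan parent peptides.
#' @param k,step tiling parameters.
#' @param n_random random-group size.
#' @param replicates per-group replicate counts.
#' @param grid_rows,grid_cols,s_pixel_um,spot_side_spx grid geometry
#'   (`NULL` rows/cols auto-sizes a near-square grid).
#' @param n_planted_repulsive,n_planted_adhesive sizes of the planted
#'   ground-truth sets (sampled from non-control peptides).
#' @param meanlog,sdlog,background,sigma_rep adhesion / readout model.
#' @param simulate `"table"` (default) draws the per-spot intensity table
#'   directly; `"image"` renders a scan image and quantifies it.
#' @param um_per_pixel image scale for `simulate = "image"`.
#' @param q_low,q_high,gradient_factor extreme-detection parameters.
#' @param n_perm property-correlation permutations.
#' @param seed master seed.
#' @param out_dir output directory (`NULL`: no files written).
#' @return a `pepscreen_config` list.
#' @export
pepscreen_config <- function(proteins = NULL,
                             protein_lengths = c(SFRP1 = 314, DKK1 = 266,
                                                 TNFA = 233),
                             parents = c("NRWHE", "NGWQG",
                                         "KEQWFGNRWHEGYR",
                                         "QETWFQNGWQGKNP"),
                             k = 15, step = 1, n_random = 9818,
                             replicates = c(scan = 5, substitution = 3,
                                            random = 2, control = 5,
                                            blank = 5),
                             grid_rows = NULL, grid_cols = NULL,
                             s_pixel_um = 30, spot_side_spx = 4,
                             n_planted_repulsive = 0,
                             n_planted_adhesive = 0,
                             meanlog = log(2500), sdlog = 0.8,
                             background = 200, sigma_rep = 0.1,
                             simulate = c("table", "image"),
                             um_per_pixel = 5,
                             q_low = 0.05, q_high = 0.95,
                             gradient_factor = 3, n_perm = 200,
                             seed = 1, out_dir = NULL) {
  num <- function(x) {
    # stable double storage so a config hashes identically after a YAML
    # round trip (which may re-type whole numbers as integers)
    if (is.null(x)) NULL else stats::setNames(as.numeric(x), names(x))
  }
  config <- list(
    proteins = proteins, protein_lengths = num(protein_lengths),
    parents = parents, k = num(k), step = num(step),
    n_random = num(n_random),
    replicates = num(replicates), grid_rows = num(grid_rows),
    grid_cols = num(grid_cols), s_pixel_um = num(s_pixel_um),
    spot_side_spx = num(spot_side_spx),
    n_planted_repulsive = num(n_planted_repulsive),
    n_planted_adhesive = num(n_planted_adhesive),
    meanlog = num(meanlog), sdlog = num(sdlog),
    background = num(background),
    sigma_rep = num(sigma_rep), simulate = match.arg(simulate),
    um_per_pixel = num(um_per_pixel), q_low = num(q_low),
    q_high = num(q_high),
    gradient_factor = num(gradient_factor), n_perm = num(n_perm),
    seed = as.integer(seed), out_dir = out_dir
  )
  structure(config, class = "pepscreen_config")
}

#' Read / write a run configuration as YAML
#'
#' `read_config(write_config(cfg))` round-trips every field.
#' @param config a `pepscreen_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  # named vectors become YAML maps so names survive the round trip
  for (f in c("replicates", "protein_lengths")) {
    if (!is.null(x[[f]])) x[[f]] <- as.list(x[[f]])
  }
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$replicates <- unlist(raw$replicates)
  raw$protein_lengths <- unlist(raw$protein_lengths)
  raw$parents <- unlist(raw$parents)
  do.call(pepscreen_config, raw[!vapply(raw, is.null, logical(1))])
}

#' Hash of a run configuration
#'
#' Covers every scientific parameter; output locations are excluded so the
#' same run written to two directories shares one hash.
#' @param config a `pepscreen_config`.
#' @return a short stable hash string stamped into every output file.
#' @export
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  rlang::hash(x)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full screening pipeline
#'
#' Orchestrates design, layout, simulation, quantification, screen
#' analysis, substitution matrices and motif inference as one seeded run:
#' identical configurations produce byte-identical outputs. With
#' `out_dir` set, every stage writes its table (stamped with the config
#' hash) plus a JSON run report.
#'
#' @param config a [pepscreen_config()] or a path to its YAML form.
#' @return a `pepscreen_run` list with elements `config`, `config_hash`,
#'   `proteins`, `library`, `layout`, `adhesion`, `spots`, `measurements`,
#'   `ranked`, `extremes`, `property_cor`, `submatrices`, `motifs`,
#'   `report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pepscreen_config"))
  chash <- config_hash(config)
  seeds <- lapply(stats::setNames(1:6, c(
    "proteins", "library", "layout", "adhesion", "readout", "analysis"
  )), function(i) derive_seed(config$seed, i))

  proteins <- run_stage("design", {
    if (is.null(config$proteins)) {
      random_proteins(config$protein_lengths, seed = seeds$proteins)
    } else if (is.character(config$proteins) &&
                 length(config$proteins) == 1 &&
                 file.exists(config$proteins)) {
      read_proteins(config$proteins)
    } else {
      as_proteins(config$proteins)
    }
  })
  library <- run_stage("design", assemble_library(
    proteins = proteins, parents = config$parents, k = config$k,
    step = config$step, n_random = config$n_random,
    replicates = config$replicates, seed = seeds$library
  ))

  layout <- run_stage("layout", {
    needed <- sum(library$replicates)
    rows <- config$grid_rows
    cols <- config$grid_cols
    if (is.null(rows) || is.null(cols)) {
      # near-square grid with ~2% blank headroom
      side <- ceiling(sqrt(needed * 1.02))
      rows <- cols <- side
    }
    build_layout(library, grid_spec(
      rows, cols, s_pixel_um = config$s_pixel_um,
      spot_side_spx = config$spot_side_spx, seed = seeds$layout
    ))
  })

  adhesion <- run_stage("simulate", {
    eligible <- library$peptide_id[library$group %in%
                                     c("scan", "substitution", "random")]
    planted <- with_seed(seeds$adhesion, {
      n_rep <- min(config$n_planted_repulsive, length(eligible))
      rep_ids <- if (n_rep > 0) sample(eligible, n_rep) else character(0)
      left <- setdiff(eligible, rep_ids)
      n_adh <- min(config$n_planted_adhesive, length(left))
      adh_ids <- if (n_adh > 0) sample(left, n_adh) else character(0)
      list(repulsive = rep_ids, adhesive = adh_ids)
    })
    assign_latent_adhesion(
      library, meanlog = config$meanlog, sdlog = config$sdlog,
      planted_repulsive = planted$repulsive,
      planted_adhesive = planted$adhesive,
      seed = derive_seed(seeds$adhesion, 1)
    )
  })

  image <- NULL
  spots <- run_stage("simulate", {
    if (config$simulate == "image") {
      image <- render_scan_image(
        layout, adhesion, um_per_pixel = config$um_per_pixel,
        background = config$background, seed = seeds$readout
      )
      quantify_spots(image, layout)
    } else {
      simulate_intensity_table(
        layout, adhesion, background = config$background,
        sigma_rep = config$sigma_rep, seed = seeds$readout
      )
    }
  })

  measurements <- run_stage("analysis",
                            aggregate_replicates(spots, library))
  peptide_meas <- measurements[measurements$peptide_id != "BLANK", ]
  ranked <- run_stage("analysis", rank_curve(peptide_meas))
  extremes <- run_stage("analysis", detect_extremes(
    ranked, q_low = config$q_low, q_high = config$q_high,
    gradient_factor = config$gradient_factor
  ))
  profiles <- run_stage("analysis", {
    lib_seq <- library[library$group != "blank",
                       c("peptide_id", "sequence")]
    compute_property_profile(lib_seq)
  })
  property_cor <- run_stage("analysis", correlate_properties(
    peptide_meas, profiles, n_perm = config$n_perm,
    seed = seeds$analysis
  ))

  threshold <- run_stage("analysis", repulsion_threshold(spots))
  submatrices <- run_stage("substitution", {
    lapply(stats::setNames(config$parents, config$parents), function(p) {
      build_substitution_matrix(p, measurements, library)
    })
  })
  motifs <- run_stage("motifs", {
    purrr::map_dfr(proteins$id, function(pid) {
      track <- window_track(pid, measurements, library)
      track <- flag_windows(track, threshold, side = "repulsive")
      infer_minimal_motifs(track, proteins)
    })
  })

  report <- list(
    package_version = as.character(utils::packageVersion("pepscreen")),
    config_hash = chash,
    master_seed = config$seed,
    stage_seeds = seeds,
    parameters = unclass(config)[c(
      "k", "step", "n_random", "meanlog", "sdlog", "background",
      "sigma_rep", "simulate", "q_low", "q_high", "gradient_factor"
    )],
    group_sizes = as.list(table(library$group)),
    replicate_spots = sum(library$replicates),
    grid = unclass(layout_grid(layout))[c("grid_rows", "grid_cols",
                                          "s_pixel_um", "spot_side_spx")],
    repulsion_threshold = threshold,
    n_extreme = as.list(table(extremes$side)),
    planted_repulsive = adhesion$peptide_id[
      !is.na(adhesion$planted) & adhesion$planted == "repulsive"],
    planted_adhesive = adhesion$peptide_id[
      !is.na(adhesion$planted) & adhesion$planted == "adhesive"],
    called_repulsive = extremes$peptide_id[extremes$side == "repulsive"],
    called_adhesive = extremes$peptide_id[extremes$side == "adhesive"],
    motif_calls = nrow(motifs)
  )

  run <- structure(list(
    config = config, config_hash = chash, proteins = proteins,
    library = library, layout = layout, adhesion = adhesion,
    image = image, spots = spots, measurements = measurements,
    ranked = ranked, extremes = extremes, property_cor = property_cor,
    submatrices = submatrices, motifs = motifs, report = report
  ), class = "pepscreen_run")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    write_library(library, out("library.tsv"), chash)
    write_layout(layout, out("layout.gal.tsv"), chash)
    write_tsv_hashed(as_tibble(adhesion), out("adhesion.tsv"), chash)
    write_intensities(spots, out("intensities.tsv"), chash)
    write_tsv_hashed(as_tibble(measurements), out("measurements.tsv"),
                     chash)
    write_tsv_hashed(as_tibble(extremes), out("extremes.tsv"), chash)
    write_tsv_hashed(motifs, out("motifs.tsv"), chash)
    export_residue_track(motifs, proteins, out("motifs.bed"),
                         out("residue_track.tsv"), chash)
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  run
}

#' @export
print.pepscreen_run <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    paste0("<pepscreen_run> %d library entries (%s), %d replicate spots\n",
           "  grid %d x %d; %d repulsive / %d adhesive calls; %d motif calls\n",
           "  config hash %s\n"),
    nrow(x$library),
    paste(sprintf("%s=%d", names(r$group_sizes),
                  unlist(r$group_sizes)), collapse = ", "),
    r$replicate_spots, r$grid$grid_rows, r$grid$grid_cols,
    length(r$called_repulsive), length(r$called_adhesive),
    r$motif_calls, x$config_hash
  ))
  invisible(x)
}

#' @export
tidy.pepscreen_run <- function(x, ...) {
  as_tibble(x$extremes)
}

#' @export
glance.pepscreen_run <- function(x, ...) {
  r <- x$report
  tibble(
    n_entries = nrow(x$library),
    n_peptides = sum(x$library$group != "blank"),
    replicate_spots = r$replicate_spots,
    n_repulsive = length(r$called_repulsive),
    n_adhesive = length(r$called_adhesive),
    n_motifs = r$motif_calls,
    repulsion_threshold = r$repulsion_threshold,
    seed = x$config$seed,
    config_hash = x$config_hash
  )
}
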