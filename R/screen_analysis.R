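#' Aggregate replicate spots into per-peptide intensities
#'
#' Each peptide's intensity *Int.* is the median over its replicate spot
#' intensities, which is robust to single aberrant spots. Blank spots are
#' aggregated like any peptide under the id `"BLANK"`. Peptides present in
#' a library but with zero measured spots are excluded and reported via
#' attribute `missing_peptides`.
#'
#' @param spots a spot-level tibble with columns `peptide_id` and
#'   `intensity` (from [quantify_spots()] or
#'   [simulate_intensity_table()]).
#' @param library optional library tibble used to detect unmeasured
#'   peptides.
#' @return a tibble with columns `peptide_id`, `n_spots`, `intensity`.
#' @export
aggregate_replicates <- function(spots, library = NULL) {
  if (!all(c("peptide_id", "intensity") %in% names(spots))) {
    abort("spots must have 'peptide_id' and 'intensity' columns")
  }
  out <- spots |>
    dplyr::summarise(
      n_spots = dplyr::n(),
      intensity = stats::median(.data$intensity),
      .by = "peptide_id"
    )
  missing <- character(0)
  if (!is.null(library)) {
    missing <- setdiff(library$peptide_id, out$peptide_id)
    if (length(missing) > 0) {
      warn(sprintf("%d library peptide(s) have no measured spots (e.g. '%s')",
                   length(missing), missing[1]))
    }
  }
  structure(out, missing_peptides = missing)
}

#' Ranked intensity curve
#'
#' Sorts per-peptide intensities in ascending order of cell adhesion and
#' attaches the discrete gradient `g_i = Int._(i+1) - Int._(i)` (the last
#' rank gets `NA`). Ties are broken by `peptide_id` so the ranking is
#' deterministic. On a log axis this curve shows a flat background tail,
#' a gradually rising body, and spikes in the gradient at the edges where
#' specifically repellent or adhesive peptides sit.
#'
#' @param measurements a per-peptide tibble with `peptide_id` and
#'   `intensity` (from [aggregate_replicates()]).
#' @return a tibble with columns `rank`, `peptide_id`, `intensity`,
#'   `gradient`.
#' @export
rank_curve <- function(measurements) {
  if (nrow(measurements) < 2) {
    abort("at least 2 measurements are required to build a ranked curve")
  }
  ord <- order(measurements$intensity, measurements$peptide_id)
  out <- tibble(
    rank = seq_len(nrow(measurements)),
    peptide_id = measurements$peptide_id[ord],
    intensity = measurements$intensity[ord]
  )
  out$gradient <- c(diff(out$intensity), NA_real_)
  out
}

#' Detect extreme repulsive and adhesive peptides on the ranked curve
#'
#' Looks for the curve's maximum-gradient spikes at its edges. Within the
#' low-edge window (`rank <= q_low * n`) and the high-edge window
#' (`rank >= q_high * n`), gradients exceeding `gradient_factor` times the
#' median gradient of the whole curve count as spikes; the boundary on
#' each side is the rank of the largest spike, and peptides outside it
#' (below on the low side, above on the high side) are called repulsive
#' or adhesive. When a window holds no spike the side falls back to a
#' plain quantile cut if `fallback = TRUE`, otherwise makes no calls.
#' Blank measurements are excluded before ranking by default, since blanks
#' define the background floor rather than a peptide phenotype.
#'
#' @param ranked a ranked curve from [rank_curve()], or a per-peptide
#'   measurement tibble (then ranked internally).
#' @param q_low,q_high edge quantile windows (defaults 0.05 / 0.95).
#' @param gradient_factor spike threshold as a multiple of the median
#'   gradient (default 3).
#' @param fallback use the quantile cut when a window has no spike.
#' @param exclude peptide ids dropped before ranking (default `"BLANK"`).
#' @return a `pep_extremes` tibble with columns `peptide_id`, `side`
#'   (`"repulsive"` or `"adhesive"`), `rank`, `intensity`; detection
#'   parameters, per-side method (`"gradient"`, `"quantile"` or `"none"`)
#'   and boundaries are attached as attribute `detection` and shown by
#'   [glance()].
#' @export
detect_extremes <- function(ranked, q_low = 0.05, q_high = 0.95,
                            gradient_factor = 3, fallback = TRUE,
                            exclude = "BLANK") {
  stopifnot(q_low > 0, q_high < 1, q_low < q_high)
  if (!"rank" %in% names(ranked)) ranked <- rank_curve(ranked)
  ranked <- ranked[!ranked$peptide_id %in% exclude, ]
  n <- nrow(ranked)
  ranked$rank <- seq_len(n)
  ranked$gradient <- c(diff(ranked$intensity), NA_real_)
  lo_win <- seq_len(max(1L, floor(q_low * n)))
  hi_win <- seq.int(min(n - 1L, ceiling(q_high * n)), n - 1L)
  if (n < 3 || length(lo_win) < 1 || length(hi_win) < 1) {
    abort("too few peptides for the requested edge windows")
  }
  g <- ranked$gradient[-n]
  thr <- gradient_factor * stats::median(g)

  pick_boundary <- function(window) {
    spikes <- window[g[window] > thr]
    if (length(spikes) == 0) return(NA_integer_)
    spikes[which.max(g[spikes])]
  }
  b_lo <- pick_boundary(lo_win)
  b_hi <- pick_boundary(hi_win)
  method_lo <- method_hi <- "gradient"
  if (is.na(b_lo)) {
    if (fallback) {
      b_lo <- floor(q_low * n)
      method_lo <- "quantile"
    } else {
      method_lo <- "none"
    }
  }
  if (is.na(b_hi)) {
    if (fallback) {
      b_hi <- ceiling(q_high * n) - 1L
      method_hi <- "quantile"
    } else {
      method_hi <- "none"
    }
  }
  calls <- dplyr::bind_rows(
    if (!is.na(b_lo) && method_lo != "none") {
      dplyr::mutate(ranked[seq_len(b_lo), ], side = "repulsive")
    },
    if (!is.na(b_hi) && method_hi != "none") {
      dplyr::mutate(ranked[seq.int(b_hi + 1L, n), ], side = "adhesive")
    }
  )
  if (is.null(calls) || nrow(calls) == 0) {
    calls <- tibble(peptide_id = character(0), side = character(0),
                    rank = integer(0), intensity = numeric(0))
  }
  structure(
    as_tibble(calls[, c("peptide_id", "side", "rank", "intensity")]),
    detection = list(
      n = n, q_low = q_low, q_high = q_high,
      gradient_factor = gradient_factor, median_gradient = stats::median(g),
      boundary_low = b_lo, boundary_high = b_hi,
      method_low = method_lo, method_high = method_hi,
      fallback = fallback
    ),
    class = c("pep_extremes", class(tibble()))
  )
}

#' @export
glance.pep_extremes <- function(x, ...) {
  d <- attr(x, "detection", exact = TRUE)
  tibble(
    n = d$n, n_repulsive = sum(x$side == "repulsive"),
    n_adhesive = sum(x$side == "adhesive"),
    q_low = d$q_low, q_high = d$q_high,
    gradient_factor = d$gradient_factor,
    median_gradient = d$median_gradient,
    boundary_low = d$boundary_low, boundary_high = d$boundary_high,
    method_low = d$method_low, method_high = d$method_high
  )
}

#' Load a named per-residue property scale
#'
#' Scales ship as plain TSV data files (`residue`, `value`) and are
#' selectable by name; any 20-residue table in the same format can be
#' supplied as a file path instead.
#'
#' @param name one of `"hydrophobicity_kyte_doolittle"`,
#'   `"helix_propensity_pace_scholtz"`, `"charge_default"`,
#'   `"residue_mass_average"`, or a path to a scale TSV.
#' @return a named numeric vector over the 20 canonical residues.
#' @export
property_scale <- function(name) {
  path <- system.file("extdata", "scales", paste0(name, ".tsv"),
                      package = "pepscreen")
  if (!nzchar(path)) path <- name
  if (!file.exists(path)) {
    abort(sprintf("unknown property scale '%s'", name))
  }
  df <- utils::read.delim(path)
  v <- stats::setNames(df$value, df$residue)
  missing <- setdiff(AA_ALPHABET, names(v))
  if (length(missing) > 0) {
    abort(sprintf("scale '%s' lacks residue '%s'", name, missing[1]))
  }
  v
}

sum_scale <- function(sequences, scale) {
  vapply(sequences, function(s) {
    if (!nzchar(s)) return(0)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    sum(scale[chars])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Compute peptide property profiles
#'
#' Whole-peptide sums of per-residue tables: total charge (signed
#' elementary charges; His is neutral under the default table), total
#' molecular weight (sum of average residue masses plus one water per
#' non-empty peptide, i.e. the average mass of the intact chain), total
#' hydrophobicity *SH* (Kyte–Doolittle by default) and total helix
#' propensity *HP* (Pace–Scholtz by default). Empty sequences give all
#' zeros.
#'
#' @param peptides a tibble with `peptide_id` and `sequence` columns, or a
#'   character vector of sequences.
#' @param charge_scale,hydrophobicity_scale,helix_scale,mass_scale scale
#'   names or paths, see [property_scale()].
#' @return a tibble with columns `peptide_id`, `sequence`, `total_charge`,
#'   `total_mw`, `SH`, `HP`.
#' @examples
#' compute_property_profile("III")$SH # 13.5
#' @export
compute_property_profile <- function(peptides,
                                     charge_scale = "charge_default",
                                     hydrophobicity_scale =
                                       "hydrophobicity_kyte_doolittle",
                                     helix_scale =
                                       "helix_propensity_pace_scholtz",
                                     mass_scale = "residue_mass_average") {
  if (is.character(peptides)) {
    peptides <- tibble(
      peptide_id = names(peptides) %||% paste0("pep_", seq_along(peptides)),
      sequence = unname(peptides)
    )
  }
  seqs <- dplyr::coalesce(peptides$sequence, "")
  nonempty <- nzchar(seqs)
  if (any(nonempty)) check_canonical(seqs[nonempty], "peptide")
  water <- 18.01528
  tibble(
    peptide_id = peptides$peptide_id,
    sequence = seqs,
    total_charge = sum_scale(seqs, property_scale(charge_scale)),
    total_mw = sum_scale(seqs, property_scale(mass_scale)) +
      ifelse(nonempty, water, 0),
    SH = sum_scale(seqs, property_scale(hydrophobicity_scale)),
    HP = sum_scale(seqs, property_scale(helix_scale))
  )
}

#' Rank-correlate peptide intensities with property sums
#'
#' Spearman's rho between *Int.* and each property, with a two-sided
#' permutation p-value (the proportion of label permutations whose |rho|
#' reaches the observed one, with the +1 small-sample correction).
#' P-values are reported uncorrected: with four properties the
#' multiplicity burden is negligible and the screen's use of them is
#' descriptive.
#'
#' @param measurements per-peptide tibble with `peptide_id`, `intensity`.
#' @param profiles property tibble from [compute_property_profile()].
#' @param properties which property columns to test.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutations.
#' @return a `pep_property_cor` tibble with columns `property`, `rho`,
#'   `p_value`, `n`; the matched scatter table is attached as attribute
#'   `scatter` for export/plotting.
#' @export
correlate_properties <- function(measurements, profiles,
                                 properties = c("total_charge", "total_mw",
                                                "SH", "HP"),
                                 n_perm = 1000, seed = 1) {
  joined <- dplyr::inner_join(
    measurements[, c("peptide_id", "intensity")],
    profiles, by = "peptide_id"
  )
  if (nrow(joined) < 3) {
    abort("at least 3 matched peptide measurements are required")
  }
  res <- with_seed(seed, {
    purrr::map_dfr(properties, function(p) {
      x <- joined[[p]]
      y <- joined$intensity
      rho <- stats::cor(x, y, method = "spearman")
      null <- vapply(seq_len(n_perm), function(i) {
        stats::cor(x, sample(y), method = "spearman")
      }, numeric(1))
      tibble(
        property = p, rho = rho,
        p_value = (1 + sum(abs(null) >= abs(rho))) / (n_perm + 1),
        n = nrow(joined)
      )
    })
  })
  structure(res, scatter = joined, n_perm = n_perm,
            class = c("pep_property_cor", class(tibble())))
}

#' @export
glance.pep_property_cor <- function(x, ...) {
  tibble(
    n = x$n[1], n_properties = nrow(x), n_perm = attr(x, "n_perm"),
    min_p = min(x$p_value), max_abs_rho = max(abs(x$rho))
  )
}
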