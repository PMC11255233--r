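test_that("latent adhesion honours planted sets and degenerate spread", {
  lib <- small_library()
  planted <- lib$peptide_id[lib$group == "scan"][1:3]
  adh <- assign_latent_adhesion(lib, sdlog = 0, planted_repulsive = planted,
                                seed = 1)
  unplanted <- is.na(adh$planted) & lib$group != "blank"
  # sdlog = 0 collapses the baseline to its median
  expect_true(all(adh$adhesion[unplanted] == exp(log(2500))))
  expect_true(all(adh$adhesion[adh$peptide_id %in% planted] == 0))
  expect_true(all(adh$adhesion[lib$group == "blank"] == 0))

  expect_error(
    assign_latent_adhesion(lib, planted_repulsive = "nope", seed = 1),
    "not in the library"
  )
  expect_error(
    assign_latent_adhesion(lib, planted_repulsive = planted[1],
                           planted_adhesive = planted[1], seed = 1),
    "disjoint"
  )
})

test_that("baseline draws match the log-normal median closed form", {
  lib <- tibble::tibble(
    peptide_id = sprintf("p%05d", 1:10000),
    group = "random", replicates = 1L
  )
  adh <- assign_latent_adhesion(lib, meanlog = log(2500), sdlog = 0.8,
                                seed = 21)
  expect_lt(abs(median(adh$adhesion) / exp(log(2500)) - 1), 0.05)
  # planted adhesive dominates every unplanted draw
  adh2 <- assign_latent_adhesion(lib, planted_adhesive = lib$peptide_id[1:10],
                                 seed = 22)
  top_unplanted <- max(adh2$adhesion[is.na(adh2$planted)])
  expect_true(all(adh2$adhesion[!is.na(adh2$planted)] > top_unplanted))
})

test_that("intensity tables follow I = b + a * eps and are seed-deterministic", {
  scr <- small_screen()
  noiseless <- simulate_intensity_table(scr$layout, scr$adhesion,
                                        background = 0, sigma_rep = 0,
                                        seed = 1)
  a <- setNames(scr$adhesion$adhesion, scr$adhesion$peptide_id)
  a[["BLANK"]] <- 0
  expect_equal(noiseless$intensity, unname(a[noiseless$peptide_id]))

  # multiplicative noise leaves zero-adhesion spots exactly at background
  noisy <- simulate_intensity_table(scr$layout, scr$adhesion,
                                    background = 200, sigma_rep = 0.3,
                                    seed = 2)
  zero_spots <- noisy$peptide_id %in% c(scr$planted_repulsive, "BLANK")
  expect_true(all(noisy$intensity[zero_spots] == 200))
  expect_true(all(noisy$intensity[!zero_spots] > 200))

  again <- simulate_intensity_table(scr$layout, scr$adhesion,
                                    background = 200, sigma_rep = 0.3,
                                    seed = 2)
  expect_identical(noisy, again)
})

test_that("the ranked curve has the expected shape: flat floor, rising body, edge spikes", {
  # moderately sized screen with planted extreme tails
  lib <- assemble_library(random_proteins(c(A = 300, B = 300), seed = 1),
                          n_random = 400, seed = 2)
  peptides <- lib$peptide_id[lib$group %in% c("scan", "random")]
  planted_rep <- peptides[1:30]
  planted_adh <- rev(peptides)[1:10]
  lay <- build_layout(lib, grid_spec(61, 61, seed = 3))
  adh <- assign_latent_adhesion(lib, planted_repulsive = planted_rep,
                                planted_adhesive = planted_adh, seed = 4)
  spots <- simulate_intensity_table(lay, adh, seed = 5)
  meas <- aggregate_replicates(spots)
  ranked <- rank_curve(meas[meas$peptide_id != "BLANK", ])

  expect_true(all(diff(ranked$intensity) >= 0))
  n <- nrow(ranked)
  g <- ranked$gradient[-n]
  med_g <- median(g)
  # the jumps off the planted tails dwarf the body gradient
  expect_gt(g[length(planted_rep)], 3 * med_g)
  expect_gt(g[n - length(planted_adh)], 3 * med_g)
  # low tail is flat at the background level
  expect_true(all(ranked$intensity[seq_along(planted_rep)] == 200))
})

test_that("rendered scans are deterministic and geometrically faithful", {
  lib <- small_library()
  lay <- build_layout(lib, grid_spec(24, 24, seed = 2))

  # all-zero adhesion, no noise or lawn: constant background
  zero <- assign_latent_adhesion(lib, sdlog = 0, meanlog = log(0), seed = 1)
  expect_true(all(zero$adhesion == 0))
  img0 <- render_scan_image(lay, zero, read_noise_sd = 0, background = 150,
                            seed = 1)
  expect_true(all(unclass(img0) == 150))

  # a single adhesive peptide in a blank field: all signal within its
  # footprints +/- the cell radius
  one <- zero
  hot <- lay$peptide_id[lay$peptide_id != "BLANK"][1]
  one$adhesion[one$peptide_id == hot] <- 5000
  img1 <- render_scan_image(lay, one, read_noise_sd = 0, background = 0,
                            seed = 3)
  lit <- which(unclass(img1) > 0, arr.ind = TRUE)
  edge_px <- 120 / 5
  r_px <- ceiling(7 / 5)
  hot_spots <- lay[lay$peptide_id == hot, ]
  ok <- rep(FALSE, nrow(lit))
  for (i in seq_len(nrow(hot_spots))) {
    rows <- ((hot_spots$row[i] - 1) * edge_px + 1 - r_px):
      (hot_spots$row[i] * edge_px + r_px)
    cols <- ((hot_spots$col[i] - 1) * edge_px + 1 - r_px):
      (hot_spots$col[i] * edge_px + r_px)
    ok <- ok | (lit[, 1] %in% rows & lit[, 2] %in% cols)
  }
  expect_true(all(ok))

  # planted adhesive spots are brighter than planted repulsive ones
  scr <- small_screen()
  img <- render_scan_image(scr$layout, scr$adhesion, seed = 4)
  mean_in <- function(ids) {
    spots <- scr$layout[scr$layout$peptide_id %in% ids, ]
    vals <- c()
    for (i in seq_len(nrow(spots))) {
      rows <- ((spots$row[i] - 1) * 24 + 1):(spots$row[i] * 24)
      cols <- ((spots$col[i] - 1) * 24 + 1):(spots$col[i] * 24)
      vals <- c(vals, unclass(img)[rows, cols])
    }
    mean(vals)
  }
  expect_gt(mean_in(scr$planted_adhesive), mean_in(scr$planted_repulsive))

  expect_identical(
    unclass(render_scan_image(scr$layout, scr$adhesion, seed = 4)),
    unclass(img)
  )

  expect_error(
    render_scan_image(scr$layout, scr$adhesion, max_pixels = 100, seed = 1),
    "max_pixels"
  )
})

test_that("render -> quantify -> aggregate recovers the latent adhesion ordering", {
  # the pipeline's core parameter-recovery property, image route, n >= 500
  n_pep <- 500
  lib <- assemble_library(
    random_proteins(c(A = 264, B = 264), seed = 31),
    n_random = n_pep - 500, seed = 32
  )
  lib$replicates[lib$group %in% c("scan", "random")] <- 2L
  peptides <- lib$peptide_id[lib$group %in% c("scan", "random")]
  lay <- build_layout(lib, grid_spec(33, 33, seed = 33))
  adh <- assign_latent_adhesion(
    lib, planted_repulsive = peptides[1:10],
    planted_adhesive = rev(peptides)[1:5], seed = 34
  )
  img <- render_scan_image(lay, adh, seed = 35)
  meas <- aggregate_replicates(quantify_spots(img, lay))
  j <- dplyr::inner_join(meas, adh, by = "peptide_id")
  j <- j[j$peptide_id != "BLANK", ]
  expect_gte(nrow(j), 500)
  expect_gte(cor(j$adhesion, j$intensity, method = "spearman"), 0.9)
})
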