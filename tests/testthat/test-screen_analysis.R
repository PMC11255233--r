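test_that("replicate aggregation takes the per-peptide median", {
  spots <- tibble::tibble(
    peptide_id = c(rep("a", 3), rep("b", 2), rep("BLANK", 2)),
    intensity = c(5, 7, 100, 4, 6, 1, 3)
  )
  m <- aggregate_replicates(spots)
  expect_equal(m$intensity[m$peptide_id == "a"], 7) # robust to one outlier
  expect_equal(m$intensity[m$peptide_id == "b"], 5) # even-count rule
  expect_equal(m$intensity[m$peptide_id == "BLANK"], 2)

  lib <- tibble::tibble(peptide_id = c("a", "b", "c"))
  expect_warning(m2 <- aggregate_replicates(spots, lib), "'c'")
  expect_equal(attr(m2, "missing_peptides"), "c")
})

test_that("noise-free simulation aggregates to the exact latent adhesion", {
  scr <- small_screen(sigma_rep = 0)
  spots <- simulate_intensity_table(scr$layout, scr$adhesion,
                                    background = 200, sigma_rep = 0,
                                    seed = 1)
  m <- aggregate_replicates(spots)
  a <- setNames(scr$adhesion$adhesion, scr$adhesion$peptide_id)
  a[["BLANK"]] <- 0
  expect_equal(m$intensity, unname(a[m$peptide_id]) + 200)
})

test_that("rank_curve sorts ascending with deterministic ties and gradients", {
  m <- tibble::tibble(peptide_id = c("c", "a", "b", "d"),
                      intensity = c(3, 1, 3, 10))
  rc <- rank_curve(m)
  expect_true(all(diff(rc$intensity) >= 0))
  expect_equal(rc$peptide_id, c("a", "b", "c", "d")) # ties by id
  expect_equal(rc$gradient, c(2, 0, 7, NA))

  flat <- tibble::tibble(peptide_id = letters[1:5], intensity = rep(2, 5))
  expect_true(all(rank_curve(flat)$gradient[1:4] == 0))

  expect_error(rank_curve(m[1, ]), "at least 2")
})

test_that("detect_extremes recovers planted tails from the gradient spikes", {
  lib <- assemble_library(random_proteins(c(A = 300, B = 300), seed = 51),
                          n_random = 400, seed = 52)
  peptides <- lib$peptide_id[lib$group %in% c("scan", "random")]
  planted_rep <- peptides[1:25]
  planted_adh <- rev(peptides)[1:10]
  lay <- build_layout(lib, grid_spec(61, 61, seed = 53))
  adh <- assign_latent_adhesion(lib, planted_repulsive = planted_rep,
                                planted_adhesive = planted_adh, seed = 54)
  spots <- simulate_intensity_table(lay, adh, seed = 55)
  m <- aggregate_replicates(spots)
  ex <- detect_extremes(m[m$peptide_id != "BLANK", ])
  expect_setequal(ex$peptide_id[ex$side == "repulsive"], planted_rep)
  expect_setequal(ex$peptide_id[ex$side == "adhesive"], planted_adh)
  g <- glance(ex)
  expect_equal(g$method_low, "gradient")
  expect_equal(g$method_high, "gradient")
})

test_that("uniform intensities yield zero calls when the fallback is off", {
  m <- tibble::tibble(peptide_id = sprintf("p%03d", 1:200),
                      intensity = rep(5, 200))
  ex <- detect_extremes(m, fallback = FALSE)
  expect_equal(nrow(ex), 0)
  expect_equal(attr(ex, "detection")$method_low, "none")
})

test_that("the quantile fallback is invariant to monotone intensity transforms", {
  # a gentle ramp has no gradient spikes, so both sides fall back
  m <- tibble::tibble(peptide_id = sprintf("p%03d", 1:200),
                      intensity = seq(100, 300, length.out = 200))
  ex1 <- detect_extremes(m)
  expect_equal(attr(ex1, "detection")$method_low, "quantile")
  m2 <- dplyr::mutate(m, intensity = sqrt(intensity) + 3)
  ex2 <- detect_extremes(m2)
  expect_equal(attr(ex2, "detection")$method_low, "quantile")
  expect_equal(ex1$peptide_id, ex2$peptide_id)
  expect_equal(ex1$side, ex2$side)
})

test_that("property sums match per-residue table arithmetic", {
  p <- compute_property_profile(c(g = "GGG", cd44 = "KEQWFGNRWHEGYR",
                                  i = "III", empty = ""))
  expect_equal(p$total_charge, c(0, 1, 0, 0)) # K+R+R-E-E = +1
  expect_equal(p$SH[p$peptide_id == "i"], 3 * 4.5) # Kyte-Doolittle Ile
  expect_equal(unlist(p[p$peptide_id == "empty",
                        c("total_charge", "total_mw", "SH", "HP")]),
               c(total_charge = 0, total_mw = 0, SH = 0, HP = 0))
  # chain mass = residue masses + one water
  expect_equal(p$total_mw[p$peptide_id == "g"], 3 * 57.0519 + 18.01528)

  expect_error(compute_property_profile("GGXG"), "non-canonical")
})

test_that("property sums are additive under concatenation", {
  set.seed(13)
  props <- c("total_charge", "total_mw", "SH", "HP")
  for (i in 1:15) {
    s1 <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                       sample(1:20, 1), replace = TRUE), collapse = "")
    s2 <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                       sample(1:20, 1), replace = TRUE), collapse = "")
    p <- compute_property_profile(c(a = s1, b = s2, ab = paste0(s1, s2)))
    for (pr in props) {
      water <- if (pr == "total_mw") 18.01528 else 0
      expect_equal(p[[pr]][3], p[[pr]][1] + p[[pr]][2] - water)
    }
  }
})

test_that("property correlations behave under identity, null and planted trends", {
  set.seed(11)
  n <- 120
  meas <- tibble::tibble(peptide_id = sprintf("p%03d", 1:n),
                         intensity = exp(rnorm(n, 7, 1)))
  # profiles equal to the intensity itself: rho = 1
  prof <- tibble::tibble(peptide_id = meas$peptide_id, SH = meas$intensity)
  r <- correlate_properties(meas, prof, properties = "SH", seed = 1)
  expect_equal(r$rho, 1)
  expect_lt(r$p_value, 0.01)

  # independent profiles: small |rho|, non-significant permutation p
  set.seed(2)
  prof_null <- tibble::tibble(peptide_id = meas$peptide_id,
                              SH = sample(meas$intensity))
  r0 <- correlate_properties(meas, prof_null, properties = "SH",
                             n_perm = 500, seed = 3)
  expect_lt(abs(r0$rho), 0.3)
  expect_gt(r0$p_value, 0.05)

  # intensities built to rise with SH and fall with HP reproduce the signs
  prof2 <- compute_property_profile(
    tile_protein(random_proteins(c(x = 140), seed = 4), k = 15)
  )
  meas2 <- tibble::tibble(
    peptide_id = prof2$peptide_id,
    intensity = exp(0.3 * prof2$SH - 0.3 * prof2$HP + rnorm(nrow(prof2), 0, 0.2))
  )
  r2 <- correlate_properties(meas2, prof2, properties = c("SH", "HP"),
                             seed = 5)
  expect_gt(r2$rho[r2$property == "SH"], 0)
  expect_lt(r2$rho[r2$property == "HP"], 0)

  expect_error(correlate_properties(meas[1:2, ], prof, seed = 1),
               "at least 3")
})
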