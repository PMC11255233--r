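track_for <- function(protein, k = 15, intensities = NULL, seed = 2) {
  lib <- assemble_library(protein, k = k, n_random = 0, seed = seed)
  wins <- lib[lib$group == "scan", ]
  meas <- tibble::tibble(
    peptide_id = wins$peptide_id,
    intensity = intensities %||% rep(5000, nrow(wins))
  )
  window_track(as_proteins(protein)$id[1], meas, lib)
}

test_that("window tracks index measurements by window start", {
  prot <- random_proteins(c(x = 314), seed = 1)
  tr <- track_for(prot)
  expect_equal(nrow(tr), 314 - 15 + 1)
  expect_equal(tr$start, 1:300)
  expect_true(all(tr$measured))

  # values round-trip through the indexing
  lib <- assemble_library(prot, n_random = 0, seed = 2)
  wins <- lib[lib$group == "scan", ]
  meas <- tibble::tibble(peptide_id = wins$peptide_id,
                         intensity = seq_len(nrow(wins)) * 10)
  tr2 <- window_track("x", meas, lib)
  expect_equal(tr2$intensity[tr2$start], tr2$start * 10)

  # a protein exactly one window long gives a single-entry track
  p15 <- random_proteins(c(s = 15), seed = 3)
  expect_equal(nrow(track_for(p15)), 1)

  expect_error(window_track("absent", meas, lib), "no scan windows")
})

test_that("minimal motifs equal the k - r + 1 window intersection", {
  prot <- random_proteins(c(x = 80), seed = 4)
  k <- 15

  # single flagged window: the motif is the full k-mer
  tr <- track_for(prot, k = k)
  flags <- rep(FALSE, nrow(tr))
  flags[7] <- TRUE
  call <- infer_minimal_motifs(tr, prot, flags = flags)
  expect_equal(call$motif, substr(prot$sequence, 7, 7 + k - 1))
  expect_equal(call$run_length, 1L)

  # random flag patterns agree with the brute-force intersection oracle
  set.seed(9)
  for (i in 1:25) {
    flags <- runif(nrow(tr)) < 0.25
    calls <- infer_minimal_motifs(tr, prot, flags = flags)
    runs <- rle(flags)
    ends <- cumsum(runs$lengths)
    starts_idx <- ends - runs$lengths + 1
    true_runs <- which(runs$values)
    expect_equal(nrow(calls), length(true_runs))
    for (j in true_runs) {
      oracle <- oracle_run_motif(prot$sequence,
                                 tr$start[starts_idx[j]:ends[j]], k)
      row <- calls[calls$start == oracle$start, ]
      expect_equal(row$motif, oracle$motif)
      expect_equal(row$end, oracle$end)
      expect_equal(nchar(row$motif), k - row$run_length + 1)
    }
  }
})

test_that("runs longer than k report an empty core instead of a motif", {
  prot <- random_proteins(c(x = 60), seed = 5)
  tr <- track_for(prot, k = 15)
  flags <- rep(FALSE, nrow(tr))
  flags[1:17] <- TRUE # r = 17 > k: no residue shared by all windows
  call <- infer_minimal_motifs(tr, prot, flags = flags)
  expect_true(call$core_empty)
  expect_true(is.na(call$motif))
  expect_equal(c(call$start, call$end), c(1, 31))
})

test_that("extending a run never lengthens the reported motif", {
  prot <- random_proteins(c(x = 70), seed = 6)
  tr <- track_for(prot, k = 15)
  flags <- rep(FALSE, nrow(tr))
  flags[10:14] <- TRUE
  base <- infer_minimal_motifs(tr, prot, flags = flags)
  flags[15] <- TRUE # adjacent window joins the run
  longer <- infer_minimal_motifs(tr, prot, flags = flags)
  expect_lt(nchar(longer$motif), nchar(base$motif))
})

test_that("a planted 3-mer flagged across its 13 containing windows is recovered", {
  # EVK-style repellent core: plant the motif, flag exactly the windows
  # that fully contain it, and expect the intersection to name it
  base <- random_proteins(c(sfrp_like = 120), seed = 7)
  seq <- base$sequence
  pos <- 50
  substr(seq, pos, pos + 2) <- "EVK"
  prot <- tibble::tibble(id = "sfrp_like", sequence = seq)
  tr <- track_for(prot, k = 15)
  flags <- vapply(tr$start, function(w) {
    w <= pos && (w + 14) >= (pos + 2)
  }, logical(1))
  expect_equal(sum(flags), 13)
  call <- infer_minimal_motifs(tr, prot, flags = flags)
  expect_equal(call$motif, "EVK")
  expect_equal(call$start, pos)
  expect_equal(call$run_length, 13L)
})

test_that("flag_windows ties flags to the floor threshold and mask", {
  prot <- random_proteins(c(x = 40), seed = 8)
  ints <- c(rep(5000, 10), rep(100, 5), rep(5000, 11))
  tr <- track_for(prot, intensities = ints)
  fl <- flag_windows(tr, threshold = 150, side = "repulsive")
  expect_equal(which(fl$flagged), 11:15)
  fl2 <- flag_windows(tr, threshold = 4000, side = "adhesive")
  expect_equal(which(fl2$flagged), c(1:10, 16:26))
  # unmeasured windows are never flagged
  tr$intensity[2] <- NA
  tr$measured[2] <- FALSE
  expect_false(flag_windows(tr, 1e6, "repulsive")$flagged[2])
})

test_that("BED export converts coordinates and round-trips sequences", {
  prot <- random_proteins(c(x = 60), seed = 9)
  tr <- track_for(prot)
  flags <- rep(FALSE, nrow(tr))
  flags[c(3:15, 30)] <- TRUE # one 13-run (3-mer) and one single window
  calls <- infer_minimal_motifs(tr, prot, flags = flags)

  bed_path <- withr::local_tempfile(fileext = ".bed")
  tsv_path <- withr::local_tempfile(fileext = ".tsv")
  out <- export_residue_track(calls, prot, bed_path, tsv_path)

  expect_equal(out$bed$chromStart, calls$start - 1L)
  expect_equal(out$bed$chromEnd, calls$end)
  # re-extracting the BED intervals reproduces the motif sequences
  extracted <- substr(rep(prot$sequence, nrow(out$bed)),
                      out$bed$chromStart + 1, out$bed$chromEnd)
  expect_equal(extracted, out$bed$name)
  expect_true(all(out$bed$score >= 0 & out$bed$score <= 1000))

  residues <- readr::read_tsv(tsv_path, comment = "#",
                              show_col_types = FALSE)
  expect_equal(nrow(residues), 60)
  in_motif <- unlist(lapply(seq_len(nrow(calls)), function(i) {
    calls$start[i]:calls$end[i]
  }))
  expect_setequal(which(residues$in_motif), in_motif)

  # no calls: header-only outputs
  empty <- infer_minimal_motifs(tr, prot, flags = rep(FALSE, nrow(tr)))
  export_residue_track(empty, prot, bed_path, tsv_path)
  expect_length(readLines(bed_path), 0)

  # motifs outside the protein are refused
  bad <- calls
  bad$end[1] <- 100
  expect_error(export_residue_track(bad, prot, bed_path), "bounds")
})

test_that("the reference repulsive-peptide list parses and maps cleanly", {
  ref <- reference_repulsive_peptides()
  expect_equal(nrow(ref), 13)
  expect_setequal(unique(ref$protein), c("SFRP1", "DKK1", "TNF-alpha"))
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", ref$peptide)))
  expect_true(all(nchar(ref$peptide) >= 3))
  expect_true("EVK" %in% ref$peptide)
})
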