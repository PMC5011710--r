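test_that("the default motif catalog has 2 classical and 10 novel motifs", {
  cat <- default_motif_catalog()
  expect_identical(nrow(cat), 12L)
  expect_identical(anyDuplicated(cat$motif), 0L)
  expect_identical(cat$motif_class[cat$motif == "AAA-UAA"], "classical")
  expect_identical(cat$motif_class[cat$motif == "UUU-UAG"], "novel")
  expect_true(all(cat$stop_codon %in% c("UAA", "UAG")))
  expect_error(slippery_motif("AAA", "UGA"), "UAA or UAG")
})

test_that("slippery-site scanning finds in-frame shifty stops", {
  s <- scan_slippery_sites("AUGAAAUAAAUAA", transcript_id = "t")
  expect_identical(nrow(s), 1L)
  expect_identical(s$skip_pos, 6L)
  expect_identical(s$next_codon, "AAA")
  expect_identical(s$motif, "AAA-UAA")

  # AAA-UAAG context: codon after the skip is AAG (Lys)
  s2 <- scan_slippery_sites("AUGAAAUAAGGGUAA", transcript_id = "t")
  expect_identical(s2$skip_pos, 6L)
  expect_identical(s2$next_codon, "AAG")

  # no in-frame UAA/UAG in the tracked frame
  expect_identical(nrow(scan_slippery_sites("AUGGCUGGUGCU")), 0L)
  # shorter than 7 nt is an empty result, not an error
  expect_identical(nrow(scan_slippery_sites("AUGUAA")), 0L)
  # terminal stop with no downstream continuation is not a site
  expect_identical(nrow(scan_slippery_sites("AUGGCUAAAUAA")), 0L)
})

test_that("overlapping slippery windows are rejected with a warning", {
  # second in-frame stop 4 nt after the first: windows overlap
  expect_warning(
    s <- scan_slippery_sites("AUGAAAUAAAUAAAAAA", transcript_id = "t"),
    "overlap")
  expect_identical(nrow(s), 1L)
  expect_identical(s$skip_pos, 6L)
})

test_that("frameshift models join segments across +1 junctions", {
  eup <- euplotes_genetic_code()
  # derived with the independent loop translator: 0-frame MAK up to the
  # shifty stop, then +1 frame from the base after the skipped U
  seq <- "AUGGCUAAAUAAAGCUGAUAA"
  s <- scan_slippery_sites(seq, transcript_id = "t")
  expect_identical(s$skip_pos, 9L)
  m <- build_frameshift_model("t", seq, s)
  up <- oracle_translate(substr(seq, 1, 9), 0, eup$codon_to_aa)
  down <- oracle_translate(substr(seq, 11, nchar(seq)), 0,
                           eup$codon_to_aa, halt = TRUE)
  expect_identical(m$protein, paste0(up, down))
  expect_identical(m$junctions, nchar(up) - 1L)
  expect_identical(m$frame_of_residue,
                   c(rep(0L, nchar(up)), rep(1L, nchar(down))))

  # no sites: plain 0-frame halt translation, no junctions
  m0 <- build_frameshift_model("t", seq)
  expect_identical(m0$protein, translate_frame(seq, 0, eup, "halt"))
  expect_identical(m0$junctions, integer(0))
})

test_that("junction residue pairs follow the codon read after the skip", {
  # AAA-UAA-G -> (K, K); AAA-UAA-C -> (K, N)
  for (case in list(c("G", "K"), c("C", "N"), c("A", "K"))) {
    seq <- paste0("AUGGCUAAAUAA", case[1], "GGGCUUAA")
    s <- scan_slippery_sites(seq, transcript_id = "t")
    m <- build_frameshift_model("t", seq, s)
    j <- m$junctions[1]
    expect_identical(substr(m$protein, j + 1, j + 1), "K")
    expect_identical(substr(m$protein, j + 2, j + 2), case[2])
  }
})

test_that("two sites in one transcript give three frame segments 0 -> 1 -> 2", {
  seq <- paste0("AUGGCUGGUAAA", "UAA", "A", "GCUGGUAAA", "UAA", "G",
                "GUGGUGCU", "UAA")
  s <- scan_slippery_sites(seq, transcript_id = "t")
  expect_identical(nrow(s), 2L)
  m <- build_frameshift_model("t", seq, s)
  expect_length(m$junctions, 2L)
  expect_identical(m$segments$frame, c(0L, 1L, 2L))
  # frame increments by 1 (mod 3) across each junction
  jumps <- diff(m$frame_of_residue)
  expect_true(all(jumps[jumps != 0] == 1L))
})

test_that("re-translating each frame segment reproduces the protein slice", {
  cfg <- simulation_config(n_genes = 40, seed = 5)
  truth <- generate_transcriptome(cfg)
  eup <- euplotes_genetic_code()
  for (m in truth$models) {
    seg <- m$segments
    for (i in seq_len(nrow(seg))) {
      if (seg$nt_end[i] == seg$nt_start[i]) next
      piece <- translate_frame(
        substr(m$seq, seg$nt_start[i] + 1, seg$nt_end[i]), 0, eup,
        "readthrough")
      expect_identical(piece, substr(m$protein, seg$res_start[i] + 1,
                                     seg$res_end[i]))
    }
  }
})

test_that("the conceptual -2 product adds one residue of > 100 Da at classical sites", {
  s <- scan_slippery_sites("AUGGCUAAAUAAAGCUGAUAA", transcript_id = "t")
  m2 <- conceptual_minus2(s[1, ])
  expect_identical(m2$extra_codon, "AAU")
  expect_identical(m2$extra_residue, "N")
  expect_equal(m2$mass_delta, oracle_residue_mass("N"), tolerance = 1e-6)
  expect_gt(m2$mass_delta, 100)

  # mass_delta equals the mass excess of the product with the extra
  # residue (peptide-mass additivity)
  plus1 <- peptide_mass("MAKKAC")
  minus2 <- peptide_mass("MAKNKAC")
  expect_equal(minus2 - plus1, m2$mass_delta, tolerance = 1e-9)

  # AAA-UAG context re-reads the same AAU codon
  s2 <- scan_slippery_sites("AUGGCUAAAUAGAGCUGAUAA", transcript_id = "t")
  expect_identical(conceptual_minus2(s2[1, ])$extra_residue, "N")
})

test_that("naive any-position scanning reports out-of-frame motif hits too", {
  # motif shifted one base out of frame: invisible to the tracked scan
  seq <- "AUGGAAAUAAGGGGGUAA"
  expect_identical(nrow(scan_slippery_sites(seq)), 0L)
  naive <- scan_slippery_sites(seq, frame_tracking = FALSE)
  expect_identical(naive$skip_pos, 7L)
})
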