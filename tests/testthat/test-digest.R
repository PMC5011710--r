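test_that("trypsin digestion applies the cleavage rule with coordinates", {
  tryp <- enzyme_presets()$trypsin
  out <- digest("AKRC", tryp, min_len = 1, max_len = 50, max_missed = 0)
  expect_identical(out$sequence, c("AK", "R", "C"))
  expect_identical(out$start, c(0L, 2L, 3L))
  expect_identical(out$end, c(2L, 3L, 4L))
  expect_identical(out$missed_cleavages, c(0L, 0L, 0L))
  # proline blocks cleavage
  out2 <- digest("AKPR", tryp, min_len = 1, max_len = 50, max_missed = 0)
  expect_identical(out2$sequence, c("AKPR"))
  expect_error(digest("AKB", tryp), "invalid residue")
})

test_that("GluC and chymotrypsin recover the reported junction-spanning peptides", {
  enz <- enzyme_presets()
  p1 <- paste0("MAGE", "IVSMQATKKLLQLQAE", "GGKW")
  g <- digest(p1, enz$gluc)
  expect_true("IVSMQATKKLLQLQAE" %in% g$sequence)

  p2 <- paste0("MAGF", "VRSKKTGEVRLEKGKQTF", "AGK")
  c2 <- digest(p2, enz$chymotrypsin)
  hit <- c2[c2$sequence == "VRSKKTGEVRLEKGKQTF", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$missed_cleavages, 1L)  # one internal L
})

test_that("digestion matches a brute-force oracle on random proteins", {
  set.seed(202)
  enz <- enzyme_presets()
  for (i in 1:34) {
    prot <- random_protein(sample(20:120, 1))
    e <- enz[[sample(names(enz), 1)]]
    got <- digest(prot, e, min_len = 4, max_len = 30, protein_id = "p")
    want <- oracle_digest(prot, e$cleave_after, e$blocked_by_next,
                          e$max_missed, 4, 30)
    expect_identical(got$sequence, want$sequence)
    expect_identical(got$start, want$start)
    expect_identical(got$end, want$end)
    expect_identical(got$missed_cleavages, want$missed_cleavages)
  }
})

test_that("zero-missed peptides tile the protein and compose missed-cleavage peptides", {
  set.seed(203)
  enz <- enzyme_presets()
  for (i in 1:10) {
    prot <- random_protein(sample(30:100, 1))
    e <- enz[[sample(names(enz), 1)]]
    all_peps <- digest(prot, e, min_len = 1, max_len = 1000)
    zero <- all_peps[all_peps$missed_cleavages == 0, ]
    expect_identical(paste(zero$sequence, collapse = ""), prot)
    # each k-missed peptide concatenates k+1 adjacent zero-missed ones
    for (j in which(all_peps$missed_cleavages > 0)) {
      parts <- zero[zero$start >= all_peps$start[j] &
                      zero$end <= all_peps$end[j], ]
      expect_identical(nrow(parts), all_peps$missed_cleavages[j] + 1L)
      expect_identical(paste(parts$sequence, collapse = ""),
                       all_peps$sequence[j])
    }
  }
  # case-invariance
  e <- enz$trypsin
  expect_identical(digest("akrgcwk", e, min_len = 1),
                   digest("AKRGCWK", e, min_len = 1))
})

test_that("peptide masses agree with the elemental-composition oracle", {
  expect_equal(peptide_mass("G", carbamidomethyl = FALSE), 75.03203,
               tolerance = 1e-5)
  expect_equal(peptide_mass("YLMALCKKE"),
               oracle_peptide_mass("YLMALCKKE"), tolerance = 1e-6)
  set.seed(204)
  for (i in 1:1000) {
    p <- random_peptide(sample(2:30, 1))
    expect_equal(peptide_mass(p), oracle_peptide_mass(p),
                 tolerance = 1e-6)
  }
  # additivity: mass(AB) == mass(A) + mass(B) - water
  a <- random_peptide(8); b <- random_peptide(11)
  expect_equal(peptide_mass(paste0(a, b)),
               peptide_mass(a) + peptide_mass(b) - MASS_WATER,
               tolerance = 1e-9)
})

test_that("m/z follows the proton-adduct formula", {
  expect_equal(mz(1000, 1), 1001.007276, tolerance = 1e-8)
  expect_equal(mz(1000, 2), (1000 + 2 * MASS_PROTON) / 2,
               tolerance = 1e-12)
  expect_equal(mz(1500.5, 1) - 1500.5, MASS_PROTON, tolerance = 1e-12)
  expect_error(mz(1000, 0), "charge")
})

test_that("peptidoform enumeration bounds oxidation and gets modified masses right", {
  peps <- data.frame(sequence = c("ACKGM", "MAMGMK", "AGKR"),
                     protein_id = "p", start = 0L, end = 5L,
                     missed_cleavages = 0L, enzyme = "trypsin",
                     stringsAsFactors = FALSE)
  forms <- enumerate_peptidoforms(peps, max_ox = 2)
  # MAMGMK has 3 Ms: 1 + 3 + 3 = 7 forms with <= 2 oxidations
  expect_identical(sum(forms$sequence == "MAMGMK"), 7L)
  expect_identical(sum(forms$sequence == "AGKR"), 1L)
  for (i in seq_len(nrow(forms))) {
    ox <- if (nzchar(forms$ox_sites[i])) {
      as.integer(strsplit(forms$ox_sites[i], ",")[[1]])
    } else integer(0)
    expect_true(!length(ox) ||
                  all(substring(forms$sequence[i], ox, ox) == "M"))
    expect_equal(forms$mass[i],
                 oracle_peptide_mass(forms$sequence[i], ox),
                 tolerance = 1e-6)
  }
})
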