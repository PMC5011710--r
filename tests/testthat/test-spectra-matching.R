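test_that("b/y ladders follow the fragment definitions", {
  gg <- generate_by_ions("GG", carbamidomethyl = FALSE)
  expect_equal(gg$b, AA_MONO[["G"]] + MASS_PROTON, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(gg$y, AA_MONO[["G"]] + MASS_WATER + MASS_PROTON,
               tolerance = 1e-9, ignore_attr = TRUE)
  lad <- generate_by_ions("YLMALCKKE")
  expect_length(lad$b, 8L)
  expect_length(lad$y, 8L)
  expect_error(generate_by_ions("G"), "2 residues")
})

test_that("b/y complementarity holds to 1e-6 on 1000 random peptides", {
  set.seed(301)
  for (i in 1:1000) {
    p <- random_peptide(sample(2:25, 1))
    mpos <- which(strsplit(p, "")[[1]] == "M")
    ox <- mpos[sample.int(length(mpos),
                          min(length(mpos), sample(0:2, 1)))]
    lad <- generate_by_ions(p, ox)
    n <- nchar(p)
    expect_true(all(abs(lad$b + rev(lad$y) -
                          (lad$neutral_mass + 2 * MASS_PROTON)) < 1e-6))
    expect_equal(lad$neutral_mass, peptide_mass(p, ox), tolerance = 1e-9)
  }
})

test_that("MGF files round-trip and malformed blocks are reported", {
  specs <- list(
    observed_spectrum("S1 enzyme=trypsin", 512.34567, 2L,
                      c(300.1, 401.22, 155.5), c(10, 20, 5)),
    observed_spectrum("S2", 881.115, 3L, numeric(0), numeric(0))
  )
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(specs, path)
  back <- read_mgf(path)
  expect_length(back, 2L)
  expect_identical(back[[1]]$title, "S1 enzyme=trypsin")
  expect_identical(back[[1]]$charge, 2L)
  expect_equal(back[[1]]$pepmass, 512.34567, tolerance = 1e-6)
  expect_equal(back[[1]]$peaks[, "mz"], c(155.5, 300.1, 401.22),
               tolerance = 1e-6, ignore_attr = TRUE)
  # deterministic bytes
  path2 <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(specs, path2)
  expect_identical(readLines(path), readLines(path2))
  # corrupted block is named
  writeLines(c("BEGIN IONS", "TITLE=x", "PEPMASS=500.0", "bad peak line",
               "END IONS"), path2)
  expect_error(read_mgf(path2), "block 1")
  writeLines(c("BEGIN IONS", "TITLE=x"), path2)
  expect_error(read_mgf(path2), "unbalanced")
})

test_that("matching honors precursor ppm and fragment Da tolerances", {
  pep <- data.frame(sequence = "SAMPLEK", protein_id = "p1", start = 0L,
                    end = 7L, missed_cleavages = 0L, enzyme = "trypsin",
                    stringsAsFactors = FALSE)
  forms <- enumerate_peptidoforms(pep, max_ox = 0)
  forms$is_decoy <- FALSE
  idx <- build_candidate_index(forms)
  lad <- generate_by_ions("SAMPLEK")
  theo <- c(lad$b, lad$y)

  # noiseless self-match scores 1.0
  sp <- observed_spectrum("s", mz(forms$mass[1], 2), 2L, theo)
  hit <- match_spectrum(sp, idx)
  expect_identical(hit$sequence, "SAMPLEK")
  expect_equal(hit$score, 1.0)

  # precursor 25 ppm away is excluded at 20 ppm tolerance
  sp25 <- observed_spectrum("s", mz(forms$mass[1] * (1 + 25e-6), 2), 2L,
                            theo)
  expect_null(match_spectrum(sp25, idx))

  # a fragment displaced by 0.15 Da does not count as matched
  theo2 <- theo
  theo2[3] <- theo2[3] + 0.15
  sp2 <- observed_spectrum("s", mz(forms$mass[1], 2), 2L, theo2)
  hit2 <- match_spectrum(sp2, idx)
  expect_equal(hit2$score, (length(theo) - 1) / length(theo))

  # empty peak list matches nothing
  expect_null(match_spectrum(observed_spectrum("s", 500, 2L, numeric(0)),
                             idx))
})

test_that("decoy construction reverses sequences one for one", {
  prot <- c(a = "ABCDEF" , b = "KRKRG")
  dec <- build_decoys(prot)
  expect_identical(unname(dec), c("FEDCBA", "GRKRK"))
  expect_identical(names(dec), c("DECOY_a", "DECOY_b"))
  expect_length(dec, length(prot))
  expect_warning(build_decoys(c(p = "ABA")), "palindromic")
  # pseudo-reversal keeps the C-terminal residue in place
  ps <- build_decoys(c(a = "ABCDEK"), method = "pseudo_reverse")
  expect_identical(unname(ps), "EDCBAK")
})

test_that("FDR filtering keeps the decoy/target ratio at or below q", {
  mk <- function(score, decoy, seqs = NULL) {
    n <- length(score)
    data.frame(spectrum_id = sprintf("s%d", seq_len(n)),
               sequence = if (is.null(seqs)) sprintf("PEPTIDE%dK", seq_len(n)) else seqs,
               ox_sites = "", protein_id = sprintf("p%d", seq_len(n)),
               start = 0L, end = 8L, enzyme = "trypsin", score = score,
               precursor_error_ppm = 0, is_decoy = decoy,
               observed_neutral_mass = 900,
               stringsAsFactors = FALSE)
  }
  # all-target input: FDR 0, everything accepted
  all_t <- mk(runif(20, 0.5, 1), rep(FALSE, 20))
  acc <- fdr_filter(all_t, 0.01)
  expect_identical(nrow(acc), 20L)

  # one decoy above every target at small n: nothing survives
  one_d <- mk(c(0.99, 0.8, 0.7, 0.6, 0.5),
              c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(nrow(fdr_filter(one_d, 0.01)), 0L)

  # planted-decoy simulation: realized ratio <= q at the threshold
  set.seed(302)
  for (rep in 1:5) {
    n_t <- 400; n_d <- 200
    sc <- c(rbeta(n_t, 5, 2), rbeta(n_d, 1.2, 6))
    m <- mk(sc, c(rep(FALSE, n_t), rep(TRUE, n_d)))
    acc <- fdr_filter(m, 0.01)
    expect_true(all(!acc$is_decoy))
    expect_true(all(realized_decoy_fraction(acc) <= 0.01))
    thr <- attr(acc, "peptide_threshold")
    above <- m[m$score >= thr, ]
    expect_lte(sum(above$is_decoy) / sum(!above$is_decoy), 0.01)
  }
})
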