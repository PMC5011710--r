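# shared toy models for mapping/classification tests
toy_one_junction <- function() {
  seq <- "AUGGCUGGUAAAUAAAGCUGGUGGUGCUUAA"
  s <- scan_slippery_sites(seq, transcript_id = "t1")
  build_frameshift_model("t1", seq, s)
}

toy_two_junction <- function() {
  seq <- paste0("AUGGCUGGUAAA", "UAA", "A", "GCUGGUAAA", "UAA", "G",
                "GUGGUGCUGGUGGU", "UAA")
  s <- scan_slippery_sites(seq, transcript_id = "t2")
  build_frameshift_model("t2", seq, s)
}

pep_of <- function(model, start, end) {
  map_peptide(substr(model$protein, start + 1, end), start, end, model)
}

test_that("peptide mapping computes spanning/upstream/downstream per junction", {
  m <- toy_one_junction()
  j <- m$junctions[1]
  expect_identical(pep_of(m, j - 1L, j + 2L)$relations, "spanning")
  # a peptide ending exactly at the junction residue is upstream
  expect_identical(pep_of(m, 0L, j + 1L)$relations, "upstream")
  expect_identical(pep_of(m, j + 1L, j + 3L)$relations, "downstream")
  expect_identical(pep_of(m, 0L, j + 1L)$covered_frames, 0L)
  expect_identical(pep_of(m, j - 1L, j + 2L)$covered_frames, c(0L, 1L))
  expect_error(map_peptide("WRONG", 0L, 5L, m), "does not match")
  expect_error(map_peptide("A", -1L, 0L, m), "coordinates")

  # in a two-junction model one peptide can be downstream of junction 1
  # and upstream of junction 2 at once
  m2 <- toy_two_junction()
  j1 <- m2$junctions[1]; j2 <- m2$junctions[2]
  mid <- pep_of(m2, j1 + 1L, j2 + 1L)
  expect_identical(mid$relations, c("downstream", "upstream"))
})

test_that("evidence classes partition the taxonomy", {
  m <- toy_one_junction()
  j <- m$junctions[1]
  span <- pep_of(m, j - 1L, j + 2L)
  up <- pep_of(m, 0L, j)
  down <- pep_of(m, j + 2L, j + 5L)

  expect_identical(classify_protein(list(span), m)$evidence_class, "a")
  expect_identical(classify_protein(list(span, up), m)$evidence_class, "a")
  expect_identical(classify_protein(list(up, down), m)$evidence_class, "b")
  expect_identical(classify_protein(list(down), m)$evidence_class, "c")
  expect_identical(classify_protein(list(up), m)$evidence_class, "d")
  expect_identical(classify_protein(list(), m)$evidence_class, "none")

  # every combination of relations receives exactly one class
  set.seed(401)
  pool <- list(span, up, down)
  for (i in 1:20) {
    maps <- pool[sample(3, sample(1:3, 1), replace = TRUE)]
    cls <- classify_protein(maps, m)$evidence_class
    expect_true(cls %in% c("a", "b", "c", "d"))
  }
})

test_that("spanning peptides localize the planted site with +1 direction", {
  m <- toy_one_junction()
  j <- m$junctions[1]
  span <- pep_of(m, j - 1L, j + 2L)
  loc <- localize_site(span, m)
  expect_identical(loc$skip_pos, m$sites$skip_pos[1])
  expect_identical(loc$direction, "+1")
  expect_identical(loc$residue_before, "K")
  expect_error(localize_site(pep_of(m, 0L, j), m), "does not span")

  # both junctions of a two-junction model localize
  m2 <- toy_two_junction()
  spans <- lapply(1:2, function(k) {
    jk <- m2$junctions[k]
    pep_of(m2, jk - 1L, jk + 2L)
  })
  for (k in 1:2) {
    loc <- localize_site(spans[[k]], m2)
    expect_identical(loc$skip_pos, m2$sites$skip_pos[k])
    expect_identical(loc$direction, "+1")
  }
})

test_that("mass discrimination separates +1 from -2 without ambiguity", {
  m <- toy_one_junction()
  j <- m$junctions[1]
  pep_seq <- substr(m$protein, j, j + 3L)  # spans the junction
  site <- m$sites[1, ]
  plus1 <- peptide_mass(pep_seq)
  delta <- conceptual_minus2(site)$mass_delta

  expect_identical(discriminate_direction(plus1, site, pep_seq)$call, "+1")
  expect_identical(discriminate_direction(plus1 + delta, site,
                                          pep_seq)$call, "-2")
  expect_equal(delta, 114.04293, tolerance = 1e-5)

  # > 100 Da gap means never ambiguous at 20 ppm for classical contexts
  for (nextb in c("A", "G", "C", "U")) {
    seq <- paste0("AUGGCUAAAUAA", nextb, "GGGCUGGUUAA")
    s <- scan_slippery_sites(seq, transcript_id = "t")
    d <- conceptual_minus2(s[1, ])$mass_delta
    expect_gt(d, 100)
    call <- discriminate_direction(plus1 * (1 + 10e-6), site, pep_seq)
    expect_identical(call$call, "+1")
  }
})

test_that("the summary reproduces the class table, percentage and motif split", {
  ev <- data.frame(
    model_id = sprintf("m%d", 1:226),
    evidence_class = rep(c("a", "b", "c", "d"), c(6, 81, 74, 65)),
    n_peptides = 1L, n_spanning = 0L, stringsAsFactors = FALSE)
  s <- summarize_evidence(ev, 2842L)
  expect_identical(unname(s$class_counts), c(6L, 81L, 74L, 65L))
  expect_identical(s$prf_count, 226L)
  expect_equal(s$prf_percent, 8.0)
  expect_identical(s$prf_percent_int, 8L)

  # order invariance
  s2 <- summarize_evidence(ev[sample(nrow(ev)), ], 2842L)
  expect_identical(s2$class_counts, s$class_counts)

  # empty input gives a zero table; inconsistent totals error
  z <- summarize_evidence(ev[0, ], 0L)
  expect_identical(z$prf_count, 0L)
  expect_identical(unname(z$class_counts), rep(0L, 4))
  expect_error(summarize_evidence(ev, 100L), "smaller")

  # motif table splits classical and novel sites of evidenced models
  sites <- rbind(
    scan_slippery_sites("AUGGCUAAAUAAAGCUGAUAA", transcript_id = "m1"),
    scan_slippery_sites("AUGGCUUUUUAGAGCUGAUAA", transcript_id = "m2"))
  s3 <- summarize_evidence(ev[1:2, ], 10L, sites)
  expect_setequal(s3$motif_table$motif, c("AAA-UAA", "UUU-UAG"))
  expect_setequal(s3$motif_table$motif_class, c("classical", "novel"))
})
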