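# Ground-truthed synthetic transcriptomes, detections and spectra.
#
# The generator emulates a macronuclear transcriptome in which a
# configurable fraction of genes carries 1-3 +1 PRF junctions, most of
# them at the classical AAA-UAR shifty stop, with log-normal protein
# abundance and abundance-dependent peptide detectability (PRF proteins
# skewed low, so the detected PRF fraction falls below the planted one).
# Transcripts end exactly at their terminal stop codon, so chance motif
# contexts at the terminal stop have no downstream continuation and form
# the scanner's hard negative set.

#' Simulation configuration
#'
#' @param n_genes Number of genes.
#' @param prf_fraction Fraction of genes carrying +1 PRF junctions
#'   (default 0.114).
#' @param classical_motif_fraction Probability that a junction uses the
#'   classical AAA-UAR motif (default 0.942); otherwise a novel catalog
#'   motif is drawn uniformly.
#' @param junction_probs Probabilities of 1, 2 or 3 junctions for a PRF
#'   gene.
#' @param mean_gene_length,length_sd,min_gene_length Gene length in
#'   codons (normal draw, clamped below).
#' @param abundance_meanlog,abundance_sdlog Log-normal protein abundance.
#' @param prf_abundance_factor Multiplier on PRF-gene abundance (< 1
#'   reproduces their under-detection).
#' @param detection_pmax,detection_k Per-peptide detection probability
#'   `pmax * A / (A + k)` at protein abundance `A`.
#' @param mass_error_ppm Gaussian sigma of precursor and fragment m/z
#'   error, ppm.
#' @param noise_peaks Uniform noise peaks per spectrum in 300-1800 m/z.
#' @param charge_probs Probabilities of precursor charge 2 and 3.
#' @param classical_stop_probs Probabilities of UAA vs UAG for a
#'   classical junction.
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 1000L,
                              prf_fraction = 0.114,
                              classical_motif_fraction = 0.942,
                              junction_probs = c(0.90, 0.07, 0.03),
                              mean_gene_length = 200L,
                              length_sd = 40L,
                              min_gene_length = 60L,
                              abundance_meanlog = 0,
                              abundance_sdlog = 2,
                              prf_abundance_factor = 0.3,
                              detection_pmax = 0.5,
                              detection_k = 25,
                              mass_error_ppm = 5,
                              noise_peaks = 20L,
                              charge_probs = c(0.7, 0.3),
                              classical_stop_probs = c(0.9, 0.1),
                              seed = 1L) {
  stopifnot(n_genes >= 1L,
            prf_fraction >= 0, prf_fraction <= 1,
            classical_motif_fraction >= 0, classical_motif_fraction <= 1,
            length(junction_probs) == 3L,
            min_gene_length >= 20L)
  structure(as.list(environment()), class = "simulation_config")
}

.sense_codons <- function(code) {
  names(code$codon_to_aa)[code$codon_to_aa != "*"]
}

# one PRF gene: returns list(seq, skips, pres, stops)
.build_prf_gene <- function(n_codons, k, cfg, codons, catalog) {
  novel <- catalog[catalog$motif_class == "novel", , drop = FALSE]
  seg_min <- 5L
  extra <- max(0L, n_codons - seg_min * (k + 1L))
  seg_len <- seg_min + as.vector(stats::rmultinom(1L, extra,
                                                  rep(1, k + 1L)))
  pres <- character(k)
  stops <- character(k)
  for (i in seq_len(k)) {
    if (stats::runif(1) < cfg$classical_motif_fraction) {
      pres[i] <- "AAA"
      stops[i] <- sample(c("UAA", "UAG"), 1L,
                         prob = cfg$classical_stop_probs)
    } else {
      r <- novel[sample.int(nrow(novel), 1L), ]
      pres[i] <- r$pre_codon
      stops[i] <- r$stop_codon
    }
  }
  parts <- character(0)
  skips <- integer(0)
  len <- 0L
  for (i in seq_len(k)) {
    n_i <- seg_len[i]
    if (i == 1L) {
      body <- c("AUG", sample(codons, n_i - 2L, replace = TRUE), pres[i])
    } else {
      # first codon of this segment was already emitted at the previous
      # junction (stop bases 2-3 plus one chosen base)
      body <- c(sample(codons, n_i - 2L, replace = TRUE), pres[i])
    }
    parts <- c(parts, body)
    len <- len + 3L * length(body) + if (i == 1L) 0L else 1L
    skips <- c(skips, len)
    # emit the shifty stop; its first base is the skipped nucleotide
    parts <- c(parts, stops[i])
    len <- len + 3L
    # choose the third base of the first +1-frame codon (the codon read
    # after the skip starts at the stop's second base); any base keeps
    # it a sense codon because the stop starts with U
    x <- sample(c("A", "C", "G", "U"), 1L)
    parts <- c(parts, x)
  }
  term <- c(sample(codons, seg_len[k + 1L] - 2L, replace = TRUE),
            sample(c("UAA", "UAG"), 1L))
  parts <- c(parts, term)
  list(seq = paste(parts, collapse = ""), skips = skips,
       pres = pres, stops = stops)
}

#' Generate a ground-truthed synthetic transcriptome
#'
#' @param cfg A [simulation_config()].
#' @param code Genetic code (default Euplotes).
#' @param catalog Motif catalog.
#' @return List of class `synthetic_transcriptome`: `transcripts` (named
#'   character), `genes` (data frame: `gene_id`, `is_prf`, `n_sites`,
#'   `abundance`, `protein`), `sites` (planted-site table in
#'   [scan_slippery_sites()] layout) and `models` (truth models).
#' @export
generate_transcriptome <- function(cfg, code = euplotes_genetic_code(),
                                   catalog = default_motif_catalog()) {
  set.seed(cfg$seed)
  codons <- .sense_codons(code)
  n <- cfg$n_genes
  ids <- sprintf("G%05d", seq_len(n))
  lens <- pmax(cfg$min_gene_length,
               round(stats::rnorm(n, cfg$mean_gene_length, cfg$length_sd)))
  is_prf <- stats::runif(n) < cfg$prf_fraction
  ks <- integer(n)
  ks[is_prf] <- sample(1:3, sum(is_prf), replace = TRUE,
                       prob = cfg$junction_probs)

  transcripts <- character(n)
  site_rows <- vector("list", n)
  models <- vector("list", n)
  names(models) <- ids
  proteins <- character(n)
  for (g in seq_len(n)) {
    if (is_prf[g]) {
      built <- .build_prf_gene(lens[g], ks[g], cfg, codons, catalog)
      transcripts[g] <- built$seq
      sites <- .sites_frame(ids[g], built$seq, built$skips, catalog)
      site_rows[[g]] <- sites
    } else {
      transcripts[g] <- paste(c("AUG",
                                sample(codons, lens[g] - 2L,
                                       replace = TRUE),
                                sample(c("UAA", "UAG"), 1L)),
                              collapse = "")
      sites <- .empty_sites()
    }
    models[[g]] <- build_frameshift_model(ids[g], transcripts[g], sites,
                                          code)
    proteins[g] <- models[[g]]$protein
  }
  abundance <- stats::rlnorm(n, cfg$abundance_meanlog,
                             cfg$abundance_sdlog)
  abundance[is_prf] <- abundance[is_prf] * cfg$prf_abundance_factor

  structure(
    list(transcripts = stats::setNames(transcripts, ids),
         genes = data.frame(gene_id = ids, is_prf = is_prf,
                            n_sites = ks, abundance = abundance,
                            protein = proteins,
                            stringsAsFactors = FALSE),
         sites = do.call(rbind, site_rows),
         models = models),
    class = "synthetic_transcriptome"
  )
}

#' Simulate per-peptide detection
#'
#' Digests every truth protein with each enzyme and detects each
#' peptide independently with probability `pmax * A / (A + k)` at its
#' protein's abundance `A`; low-abundance proteins are thereby
#' under-detected.
#'
#' @param truth Result of [generate_transcriptome()].
#' @param cfg The [simulation_config()].
#' @param enzymes Named list of [enzyme_spec()] (default three-enzyme
#'   panel).
#' @param min_len,max_len Peptide length bounds.
#' @return Data frame of detected peptides (digestion columns plus
#'   `abundance`).
#' @export
simulate_detection <- function(truth, cfg,
                               enzymes = enzyme_presets(),
                               min_len = 6L, max_len = 50L) {
  set.seed(cfg$seed + 1000000L)
  proteins <- stats::setNames(truth$genes$protein, truth$genes$gene_id)
  proteins <- proteins[nchar(proteins) >= min_len]
  out <- vector("list", length(enzymes))
  for (e in seq_along(enzymes)) {
    peps <- digest_proteins(proteins, enzymes[[e]],
                            min_len = min_len, max_len = max_len)
    a <- truth$genes$abundance[match(peps$protein_id,
                                     truth$genes$gene_id)]
    p <- cfg$detection_pmax * a / (a + cfg$detection_k)
    keep <- stats::runif(nrow(peps)) < p
    peps <- peps[keep, , drop = FALSE]
    peps$abundance <- a[keep]
    out[[e]] <- peps
  }
  det <- do.call(rbind, out)
  rownames(det) <- NULL
  det
}

#' Simulate MS/MS spectra for detected peptides
#'
#' One spectrum per detected peptide: precursor charge 2 or 3, all
#' singly-charged b/y peaks with Gaussian ppm m/z error, and
#' `noise_peaks` uniform noise peaks in 300-1800 m/z. Intensities are
#' nuisance values. Spectrum titles carry the sample enzyme as
#' `enzyme=<name>` so a search can use the matching digest.
#'
#' @param detected Data frame from [simulate_detection()].
#' @param cfg The [simulation_config()].
#' @return List: `spectra` (list of [observed_spectrum()]) and `truth`
#'   (data frame: `spectrum_id`, `sequence`, `protein_id`, `enzyme`,
#'   `charge`, `true_mass`).
#' @export
simulate_spectra <- function(detected, cfg) {
  set.seed(cfg$seed + 2000000L)
  n <- nrow(detected)
  charge <- sample(2:3, n, replace = TRUE, prob = cfg$charge_probs)
  mass <- peptide_masses(detected$sequence)
  ids <- sprintf("S%06d enzyme=%s", seq_len(n), detected$enzyme)
  sigma <- cfg$mass_error_ppm * 1e-6
  pepmass <- mz(mass, charge) * (1 + stats::rnorm(n, 0, sigma))
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    ions <- generate_by_ions(detected$sequence[i])
    theo <- c(ions$b, ions$y)
    mzs <- theo * (1 + stats::rnorm(length(theo), 0, sigma))
    inten <- stats::runif(length(theo), 10, 100)
    if (cfg$noise_peaks > 0L) {
      mzs <- c(mzs, stats::runif(cfg$noise_peaks, 300, 1800))
      inten <- c(inten, stats::runif(cfg$noise_peaks, 1, 10))
    }
    spectra[[i]] <- observed_spectrum(ids[i], pepmass[i], charge[i],
                                      mzs, inten)
  }
  list(spectra = spectra,
       truth = data.frame(spectrum_id = ids,
                          sequence = detected$sequence,
                          protein_id = detected$protein_id,
                          enzyme = detected$enzyme,
                          charge = charge, true_mass = mass,
                          stringsAsFactors = FALSE))
}

#' Run the full simulation
#'
#' Convenience wrapper: transcriptome, detection and spectra in one
#' call, optionally written to disk (`transcripts.fasta`,
#' `proteins.fasta`, `sites.tsv`, `spectra.mgf`, `truth.tsv`).
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (`NULL` keeps everything in memory).
#' @param enzymes Enzyme panel.
#' @return List: `truth` (transcriptome), `detected`, `spectra`,
#'   `spectrum_truth`.
#' @export
simulate_dataset <- function(cfg, dir = NULL,
                             enzymes = enzyme_presets()) {
  truth <- generate_transcriptome(cfg)
  detected <- simulate_detection(truth, cfg, enzymes)
  sim <- simulate_spectra(detected, cfg)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fasta(truth$transcripts, file.path(dir, "transcripts.fasta"))
    prot <- stats::setNames(truth$genes$protein, truth$genes$gene_id)
    write_fasta(prot[nzchar(prot)], file.path(dir, "proteins.fasta"))
    write_site_table(truth$sites, file.path(dir, "sites.tsv"))
    write_mgf(sim$spectra, file.path(dir, "spectra.mgf"))
    utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(truth = truth, detected = detected, spectra = sim$spectra,
       spectrum_truth = sim$truth)
}

#' Planted detected-PRF fraction from simulation truth
#'
#' The ground-truth counterpart of the pipeline's PRF-fraction estimate:
#' among genes with at least one detected peptide (optionally restricted
#' to peptides unique to one protein, matching the pipeline's
#' accounting), the fraction that carries planted junctions.
#'
#' @param truth Result of [generate_transcriptome()].
#' @param detected Result of [simulate_detection()].
#' @param uniqueness Optional [peptide_uniqueness()] vector over the
#'   same peptide universe the pipeline searches.
#' @return List: `detected_genes`, `detected_prf`, `fraction`.
#' @export
planted_detected_fraction <- function(truth, detected,
                                      uniqueness = NULL) {
  det <- detected
  if (!is.null(uniqueness)) {
    det <- det[uniqueness[det$sequence] == 1L, , drop = FALSE]
  }
  ids <- unique(det$protein_id)
  prf <- truth$genes$is_prf[match(ids, truth$genes$gene_id)]
  list(detected_genes = length(ids), detected_prf = sum(prf),
       fraction = if (length(ids)) sum(prf) / length(ids) else NA_real_)
}
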