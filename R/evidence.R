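# Peptide-to-model mapping, the four-class evidence taxonomy,
# frameshift-site localization and +1 vs -2 discrimination.
#
# Classes over a frameshift gene model:
#   a - at least one junction is spanned by a peptide;
#   b - no spanning, but peptides cover both the 0-frame segment and at
#       least one downstream frame segment;
#   c - coverage only downstream of the first junction;
#   d - coverage only upstream of the first junction.

#' Map one peptide onto a frameshift gene model
#'
#' "Spanning" requires covering both the last residue of one frame
#' segment (junction index j) and the first residue of the next (j+1);
#' a peptide ending exactly at j is upstream.
#'
#' @param sequence Peptide sequence (checked against the model slice).
#' @param start,end 0-based half-open coordinates on the model protein.
#' @param model A [build_frameshift_model()] object.
#' @return List of class `peptide_mapping`: `model_id`, `sequence`,
#'   `start`, `end`, `relations` (per junction: `"spanning"`,
#'   `"upstream"` or `"downstream"`), `covered_frames` and
#'   `covered_segments`.
#' @export
map_peptide <- function(sequence, start, end, model) {
  if (start < 0L || end > nchar(model$protein) || end <= start) {
    stop("peptide coordinates outside the model protein")
  }
  if (substring(model$protein, start + 1L, end) != sequence) {
    stop("peptide sequence does not match the model slice")
  }
  j <- model$junctions
  relations <- if (length(j)) {
    ifelse(start <= j & end >= j + 2L, "spanning",
           ifelse(end <= j + 1L, "upstream", "downstream"))
  } else character(0)
  res <- seq.int(start, end - 1L)
  segs <- findInterval(res, model$segments$res_start)
  structure(list(model_id = model$transcript_id, sequence = sequence,
                 start = start, end = end, relations = relations,
                 covered_frames = sort(unique(model$frame_of_residue[res + 1L])),
                 covered_segments = sort(unique(segs))),
            class = "peptide_mapping")
}

#' Classify the peptide evidence for one model
#'
#' @param mappings List of [map_peptide()] results for this model.
#' @param model The frameshift gene model they refer to.
#' @return List of class `protein_evidence`: `model_id`,
#'   `evidence_class` (`"a"`, `"b"`, `"c"`, `"d"` or `"none"`),
#'   `n_peptides`, `spanning_count` (junctions spanned),
#'   `spanned_junctions` (ordinal indices) and `covered_segments`.
#' @export
classify_protein <- function(mappings, model) {
  nj <- length(model$junctions)
  if (!length(mappings)) {
    return(structure(list(model_id = model$transcript_id,
                          evidence_class = "none", n_peptides = 0L,
                          spanning_count = 0L,
                          spanned_junctions = integer(0),
                          covered_segments = integer(0)),
                     class = "protein_evidence"))
  }
  bad <- vapply(mappings, function(m) m$model_id != model$transcript_id,
                logical(1))
  if (any(bad)) stop("mapping refers to a different model")
  if (nj == 0L) stop("model has no junctions; nothing to classify")

  spanned <- sort(unique(unlist(lapply(mappings, function(m) {
    which(m$relations == "spanning")
  }))))
  covered <- sort(unique(unlist(lapply(mappings, `[[`,
                                       "covered_segments"))))
  cls <- if (length(spanned)) {
    "a"
  } else if (1L %in% covered && any(covered > 1L)) {
    "b"
  } else if (!1L %in% covered) {
    "c"
  } else {
    "d"
  }
  structure(list(model_id = model$transcript_id, evidence_class = cls,
                 n_peptides = length(unique(vapply(mappings, `[[`,
                                                   character(1),
                                                   "sequence"))),
                 spanning_count = length(spanned),
                 spanned_junctions = spanned,
                 covered_segments = covered),
            class = "protein_evidence")
}

#' Localize a frameshift site from a spanning peptide
#'
#' Returns the slippery site of each junction the mapping spans and
#' confirms the junction residue pair is consistent with skipping
#' exactly one nucleotide: residue j must be the translation of the
#' site's pre-codon and residue j+1 the translation of the codon read
#' after the skip. An inconsistent pair is flagged for the -2 check.
#'
#' @param mapping A spanning [map_peptide()] result.
#' @param model The model it refers to.
#' @param code Genetic code.
#' @return Data frame with one row per spanned junction: the site
#'   columns plus `junction_index`, `junction_pos` (0-based protein
#'   index), `residue_before`, `residue_after`, `direction` (`"+1"` or
#'   `"flagged_minus2"`).
#' @export
localize_site <- function(mapping, model, code = euplotes_genetic_code()) {
  k <- which(mapping$relations == "spanning")
  if (!length(k)) stop("mapping does not span any junction")
  out <- vector("list", length(k))
  for (i in seq_along(k)) {
    site <- model$sites[k[i], , drop = FALSE]
    j <- model$junctions[k[i]]
    before <- substring(model$protein, j + 1L, j + 1L)
    after <- substring(model$protein, j + 2L, j + 2L)
    exp_before <- unname(code$codon_to_aa[site$pre_codon])
    exp_after <- unname(code$codon_to_aa[site$next_codon])
    consistent <- identical(before, exp_before) &&
      identical(after, exp_after)
    out[[i]] <- cbind(site,
                      data.frame(junction_index = k[i], junction_pos = j,
                                 residue_before = before,
                                 residue_after = after,
                                 direction = if (consistent) "+1"
                                             else "flagged_minus2",
                                 stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Discriminate +1 from -2 at a spanned junction by mass
#'
#' Compares an observed neutral peptide mass with the theoretical +1
#' product mass and the -2 alternative (one extra residue, from
#' [conceptual_minus2()]) at `ppm_tol`. Because the -2 alternative
#' carries a full extra residue (> 100 Da at classical sites), the call
#' is unambiguous at usual instrument accuracy.
#'
#' @param observed_mass Observed neutral mass (Da) of the spanning
#'   peptide.
#' @param site The site row of the spanned junction.
#' @param sequence The spanning peptide (its +1 sequence).
#' @param ox_sites Oxidation positions of the identified peptidoform.
#' @param code Genetic code.
#' @param ppm_tol Mass tolerance in ppm (default 20).
#' @return List of class `shift_direction_call`: `observed_mass`,
#'   `plus1_mass`, `minus2_mass`, `mass_delta` and `call` (`"+1"`,
#'   `"-2"` or `"ambiguous"`).
#' @export
discriminate_direction <- function(observed_mass, site, sequence,
                                   ox_sites = integer(0),
                                   code = euplotes_genetic_code(),
                                   ppm_tol = 20) {
  plus1 <- peptide_mass(sequence, ox_sites)
  delta <- conceptual_minus2(site, code)$mass_delta
  minus2 <- plus1 + delta
  fits <- function(m) abs(observed_mass - m) / m * 1e6 <= ppm_tol
  call <- if (fits(plus1) && !fits(minus2)) "+1"
          else if (fits(minus2) && !fits(plus1)) "-2"
          else "ambiguous"
  structure(list(observed_mass = observed_mass, plus1_mass = plus1,
                 minus2_mass = minus2, mass_delta = delta, call = call),
            class = "shift_direction_call")
}

#' Peptide uniqueness over a target peptide universe
#'
#' @param target_peptides Data frame of digestion products of the target
#'   database (columns `sequence`, `protein_id`).
#' @return Named integer vector: distinct proteins per peptide sequence.
#' @export
peptide_uniqueness <- function(target_peptides) {
  tab <- unique(target_peptides[, c("sequence", "protein_id")])
  counts <- table(tab$sequence)
  stats::setNames(as.integer(counts), names(counts))
}

#' Map and classify accepted matches over a model set
#'
#' Peptides shared between proteins are excluded by default (the
#' "unique peptides" accounting). Models without junctions contribute to
#' the detected-protein total but receive no class.
#'
#' @param accepted Accepted target matches ([fdr_filter()] output).
#' @param models Named list of frameshift gene models.
#' @param uniqueness Result of [peptide_uniqueness()]; `NULL` disables
#'   the shared-peptide exclusion.
#' @param code Genetic code.
#' @param ppm_tol Tolerance for the direction calls.
#' @return List: `evidence` (data frame: `model_id`, `evidence_class`,
#'   `n_peptides`, `n_spanning`), `spanning_calls` (localized sites of
#'   spanned junctions with direction and mass calls), and
#'   `detected_proteins` (ids with >= 1 accepted unique peptide).
#' @export
classify_models <- function(accepted, models, uniqueness = NULL,
                            code = euplotes_genetic_code(),
                            ppm_tol = 20) {
  acc <- accepted[!accepted$is_decoy, , drop = FALSE]
  if (!is.null(uniqueness) && nrow(acc)) {
    acc <- acc[uniqueness[acc$sequence] == 1L, , drop = FALSE]
  }
  detected <- unique(acc$protein_id)

  evid <- list()
  calls <- list()
  for (id in detected) {
    model <- models[[id]]
    if (is.null(model) || !length(model$junctions)) next
    rows <- acc[acc$protein_id == id, , drop = FALSE]
    u <- unique(rows[, c("sequence", "start", "end")])
    maps <- lapply(seq_len(nrow(u)), function(i) {
      map_peptide(u$sequence[i], u$start[i], u$end[i], model)
    })
    ev <- classify_protein(maps, model)
    evid[[id]] <- data.frame(model_id = id,
                             evidence_class = ev$evidence_class,
                             n_peptides = ev$n_peptides,
                             n_spanning = ev$spanning_count,
                             stringsAsFactors = FALSE)
    # localization + direction for each spanning peptide
    for (i in seq_along(maps)) {
      if (!any(maps[[i]]$relations == "spanning")) next
      loc <- localize_site(maps[[i]], model, code)
      prow <- rows[rows$sequence == u$sequence[i] &
                     rows$start == u$start[i], , drop = FALSE][1L, ]
      loc$peptide <- u$sequence[i]
      loc$mass_call <- vapply(seq_len(nrow(loc)), function(r) {
        discriminate_direction(prow$observed_neutral_mass,
                               loc[r, , drop = FALSE], u$sequence[i],
                               .parse_ox(prow$ox_sites), code,
                               ppm_tol)$call
      }, character(1))
      calls[[length(calls) + 1L]] <- loc
    }
  }
  evidence <- if (length(evid)) do.call(rbind, evid) else
    data.frame(model_id = character(0), evidence_class = character(0),
               n_peptides = integer(0), n_spanning = integer(0),
               stringsAsFactors = FALSE)
  rownames(evidence) <- NULL
  spanning_calls <- if (length(calls)) do.call(rbind, calls) else NULL
  list(evidence = evidence, spanning_calls = spanning_calls,
       detected_proteins = detected)
}

.round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Summarize frameshift evidence
#'
#' Emits the class-count table, total PRF proteins, the PRF fraction of
#' the detected proteome (percent, rounded half away from zero to one
#' decimal, plus the integer headline figure) and the motif frequency
#' table split classical vs novel.
#'
#' @param evidence Evidence data frame from [classify_models()].
#' @param total_proteins Number of detected proteins (denominator).
#' @param sites Site table restricted to evidenced models (optional; the
#'   motif table is omitted when `NULL`).
#' @return List of class `prf_summary`.
#' @export
summarize_evidence <- function(evidence, total_proteins, sites = NULL) {
  classes <- c("a", "b", "c", "d")
  counts <- vapply(classes, function(k) {
    sum(evidence$evidence_class == k)
  }, integer(1))
  prf_count <- sum(counts)
  if (total_proteins < prf_count) {
    stop("total_proteins smaller than the PRF protein count")
  }
  pct <- if (total_proteins > 0) prf_count / total_proteins * 100 else 0
  motif_table <- NULL
  if (!is.null(sites) && nrow(sites)) {
    sub <- sites[sites$transcript_id %in% evidence$model_id, ,
                 drop = FALSE]
    if (nrow(sub)) {
      motif_table <- as.data.frame(table(motif = sub$motif,
                                         motif_class = sub$motif_class),
                                   stringsAsFactors = FALSE)
      motif_table <- motif_table[motif_table$Freq > 0, , drop = FALSE]
      names(motif_table)[3] <- "n_sites"
      rownames(motif_table) <- NULL
    }
  }
  structure(list(class_counts = counts, prf_count = prf_count,
                 total_proteins = total_proteins,
                 prf_percent = .round_half_up(pct, 1L),
                 prf_percent_int = as.integer(.round_half_up(pct, 0L)),
                 motif_table = motif_table),
            class = "prf_summary")
}

#' @export
print.prf_summary <- function(x, ...) {
  cat("PRF evidence summary\n")
  cat(sprintf("  classes: a=%d b=%d c=%d d=%d (total %d)\n",
              x$class_counts["a"], x$class_counts["b"],
              x$class_counts["c"], x$class_counts["d"], x$prf_count))
  cat(sprintf("  PRF proteins: %d of %d detected (%.1f%%, ~%d%%)\n",
              x$prf_count, x$total_proteins, x$prf_percent,
              x$prf_percent_int))
  if (!is.null(x$motif_table)) {
    cat("  motifs:\n")
    for (i in seq_len(nrow(x$motif_table))) {
      cat(sprintf("    %s (%s): %d\n", x$motif_table$motif[i],
                  x$motif_table$motif_class[i], x$motif_table$n_sites[i]))
    }
  }
  invisible(x)
}
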