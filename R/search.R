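# Spectrum-to-peptide matching and target-decoy FDR control.
#
# The score is deliberately simple and documented: the fraction of
# theoretical singly-charged b/y ions found in the peak list within the
# fragment tolerance. Peptide identity and accurate mass carry the
# biological conclusions; no probabilistic engine score is reproduced.

#' Build reversed-sequence decoy proteins
#'
#' Full-sequence reversal (`"pseudo_reverse"` keeps the C-terminal
#' residue in place, preserving tryptic termini). Ids are prefixed;
#' palindromic proteins (decoy identical to target) are kept with a
#' warning.
#'
#' @param proteins Named character vector of target proteins.
#' @param prefix Id prefix for decoys.
#' @param method `"reverse"` or `"pseudo_reverse"`.
#' @return Named character vector of decoys, same length as the input.
#' @export
build_decoys <- function(proteins, prefix = "DECOY_",
                         method = c("reverse", "pseudo_reverse")) {
  method <- match.arg(method)
  rev_one <- function(s) intToUtf8(rev(utf8ToInt(s)))
  dec <- vapply(proteins, function(s) {
    if (method == "reverse" || nchar(s) < 2L) return(rev_one(s))
    n <- nchar(s)
    paste0(rev_one(substring(s, 1L, n - 1L)), substring(s, n, n))
  }, character(1), USE.NAMES = FALSE)
  pal <- dec == unname(proteins)
  if (any(pal)) {
    warning(sum(pal), " palindromic protein(s); decoy identical to target")
  }
  stats::setNames(dec, paste0(prefix, names(proteins)))
}

#' Index peptidoform candidates by neutral mass
#'
#' @param peptidoforms Data frame from [enumerate_peptidoforms()] with a
#'   logical `is_decoy` column.
#' @return A `candidate_index`: the rows sorted by mass plus the sorted
#'   mass vector for interval lookup.
#' @export
build_candidate_index <- function(peptidoforms) {
  if (is.null(peptidoforms$is_decoy)) {
    stop("peptidoforms must carry an is_decoy column")
  }
  o <- order(peptidoforms$mass)
  pf <- peptidoforms[o, , drop = FALSE]
  rownames(pf) <- NULL
  structure(list(peptidoforms = pf, mass = pf$mass),
            class = "candidate_index")
}

# fraction of theoretical ions matched; each observed peak may support
# at most one theoretical ion (the closest wins)
.matched_fraction <- function(theo, obs_mz, tol) {
  if (!length(obs_mz)) return(0)
  lo <- findInterval(theo, obs_mz)
  hi <- pmin(lo + 1L, length(obs_mz))
  lo0 <- pmax(lo, 1L)
  d_lo <- abs(theo - obs_mz[lo0])
  d_lo[lo == 0L] <- Inf
  d_hi <- abs(obs_mz[hi] - theo)
  use_hi <- d_hi < d_lo
  peak <- ifelse(use_hi, hi, lo0)
  d <- pmin(d_lo, d_hi)
  ok <- d <= tol
  if (!any(ok)) return(0)
  length(unique(peak[ok])) / length(theo)
}

#' Match one observed spectrum against indexed candidates
#'
#' Candidates within `ppm_tol` of the observed neutral precursor mass
#' are scored as the fraction of their theoretical b/y ions present in
#' the peak list within `frag_tol_da`. The best score wins; ties are
#' broken by smaller absolute precursor error, then target before
#' decoy, then lexicographic peptide, then protein id.
#'
#' @param spectrum An [observed_spectrum()].
#' @param index A [build_candidate_index()].
#' @param ppm_tol Precursor tolerance in ppm (default 20).
#' @param frag_tol_da Fragment tolerance in Da (default 0.1).
#' @return One-row data frame (`spectrum_id`, `sequence`, `ox_sites`,
#'   `protein_id`, `start`, `end`, `enzyme`, `score`,
#'   `precursor_error_ppm`, `is_decoy`, `observed_neutral_mass`) or
#'   `NULL` when nothing matches.
#' @export
match_spectrum <- function(spectrum, index, ppm_tol = 20,
                           frag_tol_da = 0.1) {
  if (!nrow(spectrum$peaks)) return(NULL)
  z <- spectrum$charge
  neutral <- spectrum$pepmass * z - z * MASS_PROTON
  lo <- neutral * (1 - ppm_tol * 1e-6)
  hi <- neutral * (1 + ppm_tol * 1e-6)
  masses <- index$mass
  a <- findInterval(lo, masses) + 1L
  b <- findInterval(hi, masses)
  if (a > b) return(NULL)
  cand <- index$peptidoforms[a:b, , drop = FALSE]
  obs_mz <- spectrum$peaks[, 1L]
  score <- numeric(nrow(cand))
  for (j in seq_len(nrow(cand))) {
    ions <- generate_by_ions(cand$sequence[j], .parse_ox(cand$ox_sites[j]))
    score[j] <- .matched_fraction(sort(c(ions$b, ions$y)), obs_mz,
                                  frag_tol_da)
  }
  ppm_err <- (neutral - cand$mass) / cand$mass * 1e6
  pick <- order(-score, abs(ppm_err), cand$is_decoy, cand$sequence,
                cand$protein_id)[1L]
  data.frame(spectrum_id = spectrum$title,
             sequence = cand$sequence[pick],
             ox_sites = cand$ox_sites[pick],
             protein_id = cand$protein_id[pick],
             start = cand$start[pick], end = cand$end[pick],
             enzyme = cand$enzyme[pick],
             score = score[pick],
             precursor_error_ppm = ppm_err[pick],
             is_decoy = cand$is_decoy[pick],
             observed_neutral_mass = neutral,
             stringsAsFactors = FALSE)
}

#' Search a list of spectra
#'
#' @param spectra List of [observed_spectrum()] objects.
#' @param index A [build_candidate_index()].
#' @inheritParams match_spectrum
#' @return Data frame of peptide-spectrum matches (one best match per
#'   spectrum that produced any candidate).
#' @export
search_spectra <- function(spectra, index, ppm_tol = 20,
                           frag_tol_da = 0.1) {
  hits <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    hits[[i]] <- match_spectrum(spectra[[i]], index, ppm_tol, frag_tol_da)
  }
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) {
    return(data.frame(spectrum_id = character(0), sequence = character(0),
                      ox_sites = character(0), protein_id = character(0),
                      start = integer(0), end = integer(0),
                      enzyme = character(0), score = numeric(0),
                      precursor_error_ppm = numeric(0),
                      is_decoy = logical(0),
                      observed_neutral_mass = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

# loosest score threshold t such that among entries with score >= t the
# decoy/target ratio is <= q; Inf when no threshold qualifies
.td_threshold <- function(score, is_decoy, q) {
  if (!length(score) || !any(!is_decoy)) return(Inf)
  o <- order(score, decreasing = TRUE)
  s <- score[o]
  d <- is_decoy[o]
  cd <- cumsum(d)
  ct <- cumsum(!d)
  # evaluate only at the last index of each distinct score so tied
  # scores enter or leave together
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  ratio <- ifelse(ct[last] == 0L, Inf, cd[last] / ct[last])
  ok <- which(ratio <= q)
  if (!length(ok)) return(Inf)
  s[last[max(ok)]]
}

#' Target-decoy FDR filtering of matches
#'
#' Applies peptide-level then protein-level filtering, each at FDR `q`:
#' matches are collapsed to their best score per peptide, the loosest
#' score threshold with decoy/target ratio `<= q` is chosen, and the
#' surviving peptides are collapsed per protein for the second stage.
#' Accepted output contains target matches only.
#'
#' @param matches Data frame from [search_spectra()] (needs `sequence`,
#'   `protein_id`, `score`, `is_decoy`).
#' @param q FDR threshold (default 0.01).
#' @return Data frame of accepted target matches, with attributes
#'   `peptide_threshold`, `protein_threshold` and `fdr_summary` (counts
#'   of targets/decoys above each threshold).
#' @export
fdr_filter <- function(matches, q = 0.01) {
  empty <- matches[0, , drop = FALSE]
  if (!nrow(matches) || !any(!matches$is_decoy)) return(empty)

  pep_best <- stats::aggregate(
    score ~ sequence + is_decoy, data = matches, FUN = max)
  t_pep <- .td_threshold(pep_best$score, pep_best$is_decoy, q)
  pep_above <- pep_best[pep_best$score >= t_pep, , drop = FALSE]
  if (!nrow(pep_above) || !any(!pep_above$is_decoy)) return(empty)
  pep_keep <- pep_above$sequence[!pep_above$is_decoy]

  surv <- matches[matches$score >= t_pep &
                    (matches$sequence %in% pep_above$sequence), ,
                  drop = FALSE]
  prot_best <- stats::aggregate(
    score ~ protein_id + is_decoy, data = surv, FUN = max)
  t_prot <- .td_threshold(prot_best$score, prot_best$is_decoy, q)
  prot_above <- prot_best[prot_best$score >= t_prot, , drop = FALSE]
  prot_keep <- prot_above$protein_id[!prot_above$is_decoy]

  accepted <- matches[!matches$is_decoy &
                        matches$score >= t_pep &
                        matches$sequence %in% pep_keep &
                        matches$protein_id %in% prot_keep, , drop = FALSE]
  rownames(accepted) <- NULL
  attr(accepted, "peptide_threshold") <- t_pep
  attr(accepted, "protein_threshold") <- t_prot
  attr(accepted, "fdr_summary") <- c(
    peptides_target = sum(!pep_above$is_decoy),
    peptides_decoy = sum(pep_above$is_decoy),
    proteins_target = sum(!prot_above$is_decoy),
    proteins_decoy = sum(prot_above$is_decoy)
  )
  accepted
}

#' Realized decoy/target ratio of an FDR-filtered result
#'
#' @param accepted Result of [fdr_filter()].
#' @return Named numeric: decoy/target ratio at the peptide and protein
#'   levels among entries above the chosen thresholds (0 when no decoy
#'   survived).
#' @export
realized_decoy_fraction <- function(accepted) {
  s <- attr(accepted, "fdr_summary")
  if (is.null(s)) stop("not an fdr_filter() result")
  c(peptide = unname(if (s["peptides_target"] > 0)
        s["peptides_decoy"] / s["peptides_target"] else 0),
    protein = unname(if (s["proteins_target"] > 0)
        s["proteins_decoy"] / s["proteins_target"] else 0))
}
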