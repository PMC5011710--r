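# Multi-protease in-silico digestion.
#
# Fully-specific digestion with configurable missed cleavages. Enzyme
# dialects follow the common search-engine defaults: trypsin K/R not
# before P; GluC after E (D optional); chymotrypsin F/W/Y/L not before P
# (M optional).

#' Construct an enzyme specification
#'
#' @param name Enzyme name.
#' @param cleave_after Residues after which the peptide bond is cleaved.
#' @param blocked_by_next No cleavage when the next residue is in this
#'   set (classically proline).
#' @param max_missed Maximum missed cleavages retained (default 2).
#' @return An object of class `enzyme_spec`.
#' @export
enzyme_spec <- function(name, cleave_after, blocked_by_next = character(0),
                        max_missed = 2L) {
  if (!length(cleave_after)) stop("cleave_after must be non-empty")
  if (max_missed < 0L) stop("max_missed must be >= 0")
  structure(list(name = name,
                 cleave_after = toupper(cleave_after),
                 blocked_by_next = toupper(blocked_by_next),
                 max_missed = as.integer(max_missed)),
            class = "enzyme_spec")
}

#' Standard three-enzyme panel
#'
#' Trypsin (after K/R, blocked by P), GluC (after E; after D too when
#' `gluc_cleaves_d`) and chymotrypsin (after F/W/Y/L, blocked by P; M
#' added when `chymotrypsin_m`).
#'
#' @param max_missed Missed-cleavage allowance for all three.
#' @param gluc_cleaves_d Also cleave after aspartate for GluC.
#' @param chymotrypsin_m Also cleave after methionine for chymotrypsin.
#' @return Named list of [enzyme_spec()] objects.
#' @export
enzyme_presets <- function(max_missed = 2L, gluc_cleaves_d = FALSE,
                           chymotrypsin_m = FALSE) {
  gluc_after <- if (gluc_cleaves_d) c("E", "D") else "E"
  chym_after <- c("F", "W", "Y", "L", if (chymotrypsin_m) "M")
  list(
    trypsin = enzyme_spec("trypsin", c("K", "R"), "P", max_missed),
    gluc = enzyme_spec("gluc", gluc_after, character(0), max_missed),
    chymotrypsin = enzyme_spec("chymotrypsin", chym_after, "P", max_missed)
  )
}

.cleavage_points <- function(protein, enzyme) {
  n <- nchar(protein)
  if (n < 2L) return(integer(0))
  res <- substring(protein, 1:n, 1:n)
  pts <- which(res[-n] %in% enzyme$cleave_after)
  if (length(enzyme$blocked_by_next) && length(pts)) {
    pts <- pts[!res[pts + 1L] %in% enzyme$blocked_by_next]
  }
  pts
}

#' Digest one protein
#'
#' Returns every fully-specific peptide with 0..`max_missed` missed
#' cleavages and length within `[min_len, max_len]`. The protein termini
#' count as cleavage boundaries. Input case is normalized to upper case.
#'
#' @param protein Amino-acid string without `*`.
#' @param enzyme An [enzyme_spec()].
#' @param min_len,max_len Peptide length bounds (defaults 6 and 50).
#' @param protein_id Id recorded in the output.
#' @param max_missed Override of the enzyme's allowance.
#' @return Data frame ordered by (start, end): `sequence`, `protein_id`,
#'   `start`, `end` (0-based half-open protein coordinates),
#'   `missed_cleavages`, `enzyme`.
#' @export
digest <- function(protein, enzyme, min_len = 6L, max_len = 50L,
                   protein_id = NA_character_,
                   max_missed = enzyme$max_missed) {
  protein <- toupper(protein)
  if (!nzchar(protein)) stop("empty protein")
  codes <- utf8ToInt(protein)
  if (anyNA(.AA_LOOKUP[codes])) {
    stop("invalid residue letter in protein ", protein_id)
  }
  bounds <- c(0L, .cleavage_points(protein, enzyme), nchar(protein))
  nb <- length(bounds)
  starts <- integer(0); ends <- integer(0); missed <- integer(0)
  for (k in 0:min(max_missed, nb - 2L)) {
    i <- seq_len(nb - 1L - k)
    starts <- c(starts, bounds[i])
    ends <- c(ends, bounds[i + 1L + k])
    missed <- c(missed, rep.int(k, length(i)))
  }
  len <- ends - starts
  keep <- len >= min_len & len <= max_len
  starts <- starts[keep]; ends <- ends[keep]; missed <- missed[keep]
  if (!length(starts)) {
    return(data.frame(sequence = character(0), protein_id = character(0),
                      start = integer(0), end = integer(0),
                      missed_cleavages = integer(0), enzyme = character(0),
                      stringsAsFactors = FALSE))
  }
  o <- order(starts, ends)
  data.frame(sequence = substring(protein, starts[o] + 1L, ends[o]),
             protein_id = protein_id,
             start = starts[o], end = ends[o],
             missed_cleavages = missed[o],
             enzyme = enzyme$name,
             stringsAsFactors = FALSE)
}

#' Digest a set of proteins
#'
#' @param proteins Named character vector of protein sequences.
#' @param enzyme An [enzyme_spec()].
#' @param ... Passed to [digest()].
#' @return Row-bound data frame of peptides (see [digest()]).
#' @export
digest_proteins <- function(proteins, enzyme, ...) {
  ids <- names(proteins)
  if (is.null(ids)) stop("proteins must be named")
  out <- vector("list", length(proteins))
  for (i in seq_along(proteins)) {
    out[[i]] <- digest(proteins[[i]], enzyme, protein_id = ids[i], ...)
  }
  do.call(rbind, out)
}

#' Enumerate peptidoforms with modifications
#'
#' Applies the fixed carbamidomethyl to every cysteine and enumerates
#' variable methionine oxidation over 0..`max_ox` sites per peptide
#' (combinatorics bounded at two sites by default). Adds the neutral
#' monoisotopic `mass` of each form.
#'
#' @param peptides Data frame from [digest()]/[digest_proteins()].
#' @param max_ox Maximum simultaneous oxidations per peptide.
#' @param carbamidomethyl Apply the fixed C modification.
#' @return The input rows replicated per peptidoform, with columns
#'   `ox_sites` (comma-joined 1-based positions, `""` for none) and
#'   `mass`.
#' @export
enumerate_peptidoforms <- function(peptides, max_ox = 2L,
                                   carbamidomethyl = TRUE) {
  base_mass <- peptide_masses(peptides$sequence, carbamidomethyl)
  n <- nrow(peptides)
  rows <- vector("list", n)
  ox <- vector("list", n)
  add <- vector("list", n)
  mpos <- gregexpr("M", peptides$sequence, fixed = TRUE)
  for (i in seq_len(n)) {
    p <- mpos[[i]]
    if (p[1L] == -1L || max_ox < 1L) {
      rows[[i]] <- i; ox[[i]] <- ""; add[[i]] <- 0
      next
    }
    p <- as.integer(p)
    combos <- list(integer(0))
    for (k in seq_len(min(max_ox, length(p)))) {
      # combn over indices: combn(x, k) on a scalar x would expand 1:x
      cmb <- utils::combn(seq_along(p), k, function(j) p[j],
                          simplify = FALSE)
      combos <- c(combos, cmb)
    }
    rows[[i]] <- rep.int(i, length(combos))
    ox[[i]] <- vapply(combos, paste, character(1), collapse = ",")
    add[[i]] <- MOD_OXIDATION * lengths(combos)
  }
  idx <- unlist(rows, use.names = FALSE)
  out <- peptides[idx, , drop = FALSE]
  out$ox_sites <- unlist(ox, use.names = FALSE)
  out$mass <- base_mass[idx] + unlist(add, use.names = FALSE)
  rownames(out) <- NULL
  out
}

.parse_ox <- function(ox_sites) {
  if (is.na(ox_sites) || !nzchar(ox_sites)) return(integer(0))
  as.integer(strsplit(ox_sites, ",", fixed = TRUE)[[1L]])
}

#' Write a peptide table as TSV
#'
#' @param peptides Peptide data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  utils::write.table(peptides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
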