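# Monoisotopic mass arithmetic for peptides.
#
# Residue masses are the standard monoisotopic values used by search
# engines; I and L are distinct letters with identical mass.

#' Monoisotopic residue masses (Da)
#'
#' Named numeric vector of the 20 standard amino-acid residue masses
#' (peptide-bond residues, i.e. amino acid minus water). I and L share a
#' mass but remain distinct letters.
#'
#' @format Named numeric vector of length 20.
#' @export
AA_MONO <- c(
  G =  57.021463723, A =  71.037113787, S =  87.032028409,
  P =  97.052763851, V =  99.068413914, T = 101.047678473,
  C = 103.009184477, L = 113.084063978, I = 113.084063978,
  N = 114.042927446, D = 115.026943031, Q = 128.058577510,
  K = 128.094963015, E = 129.042593095, M = 131.040484604,
  H = 137.058911861, F = 147.068413914, R = 156.101111026,
  Y = 163.063328536, W = 186.079312952
)

#' Mass constants (Da, monoisotopic)
#'
#' Water (added to a residue-mass sum to obtain a neutral peptide mass),
#' the proton (for m/z), and the deltas of the two modifications the
#' pipeline uses: carbamidomethylation of cysteine (fixed, from
#' iodoacetamide alkylation) and oxidation of methionine (variable).
#'
#' @name mass-constants
#' @export
MASS_WATER <- 18.010564686

#' @rdname mass-constants
#' @export
MASS_PROTON <- 1.007276467

#' @rdname mass-constants
#' @export
MOD_CARBAMIDOMETHYL <- 57.021463723

#' @rdname mass-constants
#' @export
MOD_OXIDATION <- 15.994914622

# fast byte-indexed lookup for residue masses
.AA_LOOKUP <- local({
  v <- rep(NA_real_, 128L)
  v[vapply(names(AA_MONO), utf8ToInt, integer(1))] <- unname(AA_MONO)
  v
})

.C_CODE <- utf8ToInt("C")
.M_CODE <- utf8ToInt("M")

#' Per-residue monoisotopic masses of a peptide
#'
#' Returns the mass of each residue of `sequence`, including the fixed
#' carbamidomethyl delta on every cysteine (when `carbamidomethyl` is
#' `TRUE`) and the oxidation delta at the 1-based methionine positions
#' given in `ox_sites`.
#'
#' @param sequence Peptide string (uppercase one-letter amino acids).
#' @param ox_sites Integer vector of 1-based positions carrying an
#'   oxidation; each must be an M.
#' @param carbamidomethyl Apply the fixed +57.021464 Da to every C.
#' @return Numeric vector, one mass per residue.
#' @export
residue_masses <- function(sequence, ox_sites = integer(0),
                           carbamidomethyl = TRUE) {
  codes <- utf8ToInt(sequence)
  m <- .AA_LOOKUP[codes]
  if (anyNA(m)) {
    bad <- unique(intToUtf8(codes[is.na(m)], multiple = TRUE))
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  }
  if (carbamidomethyl) {
    idx <- which(codes == .C_CODE)
    m[idx] <- m[idx] + MOD_CARBAMIDOMETHYL
  }
  if (length(ox_sites)) {
    ox_sites <- as.integer(ox_sites)
    if (any(ox_sites < 1L | ox_sites > length(m))) {
      stop("oxidation site outside peptide")
    }
    if (any(codes[ox_sites] != .M_CODE)) {
      stop("oxidation site is not a methionine")
    }
    m[ox_sites] <- m[ox_sites] + MOD_OXIDATION
  }
  m
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus one water, with the same modification
#' handling as [residue_masses()].
#'
#' @inheritParams residue_masses
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(sequence, ox_sites = integer(0),
                         carbamidomethyl = TRUE) {
  if (!nzchar(sequence)) stop("empty peptide")
  sum(residue_masses(sequence, ox_sites, carbamidomethyl)) + MASS_WATER
}

#' Neutral masses for many peptides
#'
#' Vectorised unmodified-backbone mass (fixed carbamidomethyl included
#' when requested); oxidation is handled per peptidoform by
#' [enumerate_peptidoforms()].
#'
#' @param sequences Character vector of peptides.
#' @param carbamidomethyl Apply the fixed C modification.
#' @return Numeric vector of neutral masses (Da).
#' @export
peptide_masses <- function(sequences, carbamidomethyl = TRUE) {
  vapply(sequences, function(s) {
    codes <- utf8ToInt(s)
    m <- .AA_LOOKUP[codes]
    if (anyNA(m)) stop("unknown residue letter in ", s)
    tot <- sum(m)
    if (carbamidomethyl) tot <- tot + MOD_CARBAMIDOMETHYL * sum(codes == .C_CODE)
    tot + MASS_WATER
  }, numeric(1), USE.NAMES = FALSE)
}

#' Mass-to-charge ratio
#'
#' `(mass + charge * proton) / charge` with the proton at 1.007276 Da.
#'
#' @param mass Neutral mass (Da).
#' @param charge Positive integer charge state.
#' @return m/z value(s).
#' @export
mz <- function(mass, charge) {
  if (any(charge < 1)) stop("charge must be >= 1")
  (mass + charge * MASS_PROTON) / charge
}
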