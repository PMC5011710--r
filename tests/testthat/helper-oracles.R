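# Independent oracles, deliberately written on different routes from the
# implementation: masses are derived from elemental compositions and
# atomic monoisotopic masses (the package uses a literal residue table),
# digestion is brute-force enumeration over all substrings, and
# translation is a character-by-character loop.

.atomic <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
             O = 15.9949146221, S = 31.97207069)

# residue elemental compositions (C, H, N, O, S)
.residue_formula <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0)
)

oracle_residue_mass <- function(aa) {
  f <- .residue_formula[[aa]]
  unname(f[1] * .atomic["C"] + f[2] * .atomic["H"] + f[3] * .atomic["N"] +
           f[4] * .atomic["O"] + f[5] * .atomic["S"])
}

# carbamidomethyl = +C2H3NO on C; oxidation = +O on M
oracle_peptide_mass <- function(seq, ox_sites = integer(0),
                                carbamidomethyl = TRUE) {
  letters <- strsplit(seq, "")[[1]]
  total <- 0
  for (i in seq_along(letters)) {
    total <- total + oracle_residue_mass(letters[i])
    if (carbamidomethyl && letters[i] == "C") {
      total <- total + 2 * .atomic["C"] + 3 * .atomic["H"] +
        .atomic["N"] + .atomic["O"]
    }
    if (i %in% ox_sites) total <- total + .atomic["O"]
  }
  unname(total + 2 * .atomic["H"] + .atomic["O"])
}

# brute-force digestion: enumerate every substring and keep those whose
# ends are cleavage boundaries with few enough internal boundaries
oracle_digest <- function(protein, cleave_after, blocked_by_next,
                          max_missed, min_len, max_len) {
  letters <- strsplit(protein, "")[[1]]
  n <- length(letters)
  boundary <- c(TRUE, vapply(seq_len(n - 1), function(i) {
    letters[i] %in% cleave_after && !(letters[i + 1] %in% blocked_by_next)
  }, logical(1)), TRUE)  # boundary[i+1] == cut after residue i
  res <- list()
  for (s in 0:(n - 1)) {
    if (!boundary[s + 1]) next
    for (e in (s + 1):n) {
      if (!boundary[e + 1]) next
      len <- e - s
      if (len < min_len || len > max_len) next
      internal <- if (e - s >= 2) sum(boundary[(s + 2):e]) else 0
      if (internal > max_missed) next
      res[[length(res) + 1]] <- data.frame(
        sequence = paste(letters[(s + 1):e], collapse = ""),
        start = s, end = e, missed_cleavages = internal,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), missed_cleavages = integer(0)))
  }
  out <- do.call(rbind, res)
  out[order(out$start, out$end), , drop = FALSE]
}

# plain loop translation, independent of translate_frame
oracle_translate <- function(seq, frame, map, halt = TRUE) {
  out <- character(0)
  i <- frame + 1
  while (i + 2 <= nchar(seq)) {
    aa <- unname(map[substr(seq, i, i + 2)])
    if (halt && aa == "*") break
    out <- c(out, aa)
    i <- i + 3
  }
  paste(out, collapse = "")
}

random_peptide <- function(len) {
  paste(sample(names(prfscan::AA_MONO), len, replace = TRUE),
        collapse = "")
}

random_protein <- function(len) random_peptide(len)
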