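# Variant genetic codes and frame-aware conceptual translation.
#
# Euplotes reads UGA as cysteine, leaving UAA/UAG as the only stop
# codons; that property is what makes the "shifty stop" slippery sites
# scannable at 0-frame stop codons.

#' Construct a genetic code
#'
#' A genetic code is a total map from the 64 RNA codons to one-letter
#' amino acids, with `"*"` marking stops. The stop-codon set is derived
#' from the map.
#'
#' @param name Label for the code.
#' @param codon_to_aa Named character vector: 64 RNA codons (A/C/G/U) to
#'   single amino-acid letters or `"*"`.
#' @return An object of class `genetic_code` with elements `name`,
#'   `codon_to_aa` and `stop_codons`.
#' @export
genetic_code <- function(name, codon_to_aa) {
  if (length(codon_to_aa) != 64L || is.null(names(codon_to_aa))) {
    stop("codon_to_aa must map exactly the 64 codons")
  }
  codons <- names(codon_to_aa)
  if (anyDuplicated(codons) || any(grepl("[^ACGU]", codons)) ||
      any(nchar(codons) != 3L)) {
    stop("codon names must be the 64 distinct RNA triplets")
  }
  structure(
    list(name = name,
         codon_to_aa = codon_to_aa,
         stop_codons = codons[codon_to_aa == "*"]),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code:", x$name, "\n")
  cat("  stop codons:", paste(x$stop_codons, collapse = ", "), "\n")
  special <- x$codon_to_aa["UGA"]
  cat("  UGA ->", special, "\n")
  invisible(x)
}

#' The standard genetic code (RNA codons)
#'
#' Derived from the canonical translation table, with codons written in
#' the RNA alphabet.
#'
#' @return A `genetic_code`.
#' @export
standard_genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  map <- as.character(gc)
  names(map) <- chartr("T", "U", names(gc))
  genetic_code("standard", map)
}

#' The Euplotes variant genetic code
#'
#' The standard code with UGA reassigned to cysteine; UAA and UAG remain
#' the only stop codons.
#'
#' @return A `genetic_code`.
#' @export
euplotes_genetic_code <- function() {
  map <- standard_genetic_code()$codon_to_aa
  map["UGA"] <- "C"
  genetic_code("euplotes", map)
}

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. Any character outside A/C/G/U after
#' normalization (including IUPAC ambiguity codes such as N) is an
#' error: downstream mass arithmetic cannot tolerate ambiguous residues.
#'
#' @param seq Character vector of nucleotide sequences (DNA or RNA).
#' @return Character vector in the A/C/G/U alphabet.
#' @export
normalize_rna <- function(seq) {
  out <- chartr("Tt", "UU", toupper(seq))
  bad <- grepl("[^ACGU]", out)
  if (any(bad)) {
    stop("non-ACGU character after normalization in sequence ",
         which(bad)[1])
  }
  if (any(!nzchar(out))) stop("empty nucleotide sequence")
  out
}

#' Frame-aware conceptual translation
#'
#' Reads codons from offset `frame` (0, 1 or 2) in steps of three; a
#' trailing partial codon is ignored. Under `stop_policy = "halt"` the
#' translation ends before the first stop codon; under `"readthrough"`
#' stops are rendered as `"*"`.
#'
#' @param seq Nucleotide sequence (DNA input is normalized to RNA).
#' @param frame Integer in 0..2.
#' @param code A [genetic_code()]; defaults to the Euplotes code.
#' @param stop_policy `"halt"` or `"readthrough"`.
#' @return Amino-acid string (possibly empty).
#' @export
translate_frame <- function(seq, frame = 0L,
                            code = euplotes_genetic_code(),
                            stop_policy = c("halt", "readthrough")) {
  stop_policy <- match.arg(stop_policy)
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  if (length(frame) != 1L || frame < 0L || frame > 2L || frame >= n) {
    stop("frame must be 0, 1 or 2 and smaller than the sequence length")
  }
  ncod <- (n - frame) %/% 3L
  if (ncod == 0L) return("")
  starts <- frame + 1L + 3L * (seq_len(ncod) - 1L)
  aas <- unname(code$codon_to_aa[substring(seq, starts, starts + 2L)])
  if (stop_policy == "halt") {
    st <- which(aas == "*")
    if (length(st)) aas <- aas[seq_len(st[1L] - 1L)]
  }
  paste(aas, collapse = "")
}

#' Read transcripts from a FASTA file
#'
#' Sequences are normalized to the RNA alphabet; ids are the first
#' whitespace-delimited token of each header.
#'
#' @param path FASTA file.
#' @return Named character vector of RNA sequences.
#' @export
read_fasta_transcripts <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  stats::setNames(normalize_rna(as.character(x)), ids)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta_proteins <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  stats::setNames(toupper(as.character(x)), ids)
}

#' Write sequences as multi-FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file; lines wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named")
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path,
                              width = 60L)
  invisible(path)
}
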