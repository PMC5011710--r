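# Theoretical fragment-ion ladders and MGF peak-list I/O.

#' Theoretical b/y fragment-ion ladder
#'
#' Singly-charged b and y ions of a peptide:
#' `b_i = sum(residue masses 1..i) + proton`,
#' `y_j = sum(residue masses n-j+1..n) + water + proton`.
#' Modifications are included via [residue_masses()].
#'
#' @inheritParams residue_masses
#' @return List of class `theoretical_spectrum`: `sequence`, `b`
#'   (b_1..b_{n-1}), `y` (y_1..y_{n-1}) and `neutral_mass`.
#' @export
generate_by_ions <- function(sequence, ox_sites = integer(0),
                             carbamidomethyl = TRUE) {
  m <- residue_masses(sequence, ox_sites, carbamidomethyl)
  n <- length(m)
  if (n < 2L) stop("peptide must have at least 2 residues")
  fwd <- cumsum(m)
  rev_cum <- cumsum(rev(m))
  structure(
    list(sequence = sequence,
         b = fwd[-n] + MASS_PROTON,
         y = rev_cum[-n] + MASS_WATER + MASS_PROTON,
         neutral_mass = fwd[n] + MASS_WATER),
    class = "theoretical_spectrum"
  )
}

#' Construct an observed spectrum
#'
#' @param title Spectrum identifier.
#' @param pepmass Precursor m/z.
#' @param charge Precursor charge state.
#' @param mz Fragment m/z values.
#' @param intensity Fragment intensities (non-negative).
#' @return List of class `observed_spectrum`; peaks sorted by m/z.
#' @export
observed_spectrum <- function(title, pepmass, charge, mz,
                              intensity = rep(1, length(mz))) {
  if (length(mz) != length(intensity)) stop("mz/intensity length mismatch")
  if (any(intensity < 0)) stop("negative intensity")
  o <- order(mz)
  structure(list(title = title, pepmass = pepmass,
                 charge = as.integer(charge),
                 peaks = cbind(mz = mz[o], intensity = intensity[o])),
            class = "observed_spectrum")
}

#' Write spectra in Mascot generic format (MGF)
#'
#' Emits BEGIN IONS/END IONS blocks with TITLE, PEPMASS and CHARGE
#' headers followed by "m/z intensity" peak lines.
#'
#' @param spectra List of [observed_spectrum()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- lapply(spectra, function(s) {
    c("BEGIN IONS",
      paste0("TITLE=", s$title),
      sprintf("PEPMASS=%.6f", s$pepmass),
      sprintf("CHARGE=%d+", s$charge),
      if (nrow(s$peaks)) sprintf("%.6f %.4f", s$peaks[, 1L], s$peaks[, 2L]),
      "END IONS", "")
  })
  writeLines(unlist(blocks), path)
  invisible(path)
}

#' Read spectra from an MGF file
#'
#' Honors TITLE, PEPMASS and CHARGE inside BEGIN IONS/END IONS blocks;
#' other headers are ignored. A malformed block (unterminated, or a
#' non-numeric peak line) is reported with its position.
#'
#' @param path MGF file.
#' @return List of [observed_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  }
  lapply(seq_along(begins), function(k) {
    body <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    is_hdr <- grepl("^[A-Z]+=", body)
    hdr <- body[is_hdr]
    get <- function(key) {
      v <- hdr[startsWith(hdr, paste0(key, "="))]
      if (!length(v)) return(NA_character_)
      sub(paste0("^", key, "="), "", v[1L])
    }
    title <- get("TITLE")
    pepmass <- suppressWarnings(
      as.numeric(strsplit(get("PEPMASS"), "\\s+")[[1L]][1L]))
    charge <- suppressWarnings(
      as.integer(sub("\\+$", "", get("CHARGE"))))
    if (is.na(pepmass)) {
      stop("malformed MGF block ", k, " (near line ", begins[k],
           "): missing or invalid PEPMASS")
    }
    peak_lines <- body[!is_hdr & nzchar(trimws(body))]
    if (length(peak_lines)) {
      fields <- strsplit(trimws(peak_lines), "\\s+")
      mzv <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
      inten <- suppressWarnings(as.numeric(vapply(fields, function(f) {
        if (length(f) >= 2L) f[2L] else "1"
      }, "")))
      if (anyNA(mzv) || anyNA(inten)) {
        stop("malformed MGF block ", k, " (near line ", begins[k],
             "): non-numeric peak line")
      }
    } else {
      mzv <- numeric(0); inten <- numeric(0)
    }
    observed_spectrum(title, pepmass,
                      if (is.na(charge)) 2L else charge, mzv, inten)
  })
}
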