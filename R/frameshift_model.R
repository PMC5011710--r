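# Slippery-site scanning and frameshift-joined gene models.
#
# A +1 PRF site in Euplotes is a "shifty stop": a sense codon (the
# pre-codon, typically AAA/Lys) immediately 5' of a UAA/UAG stop whose
# first base is skipped, after which translation continues in the +1
# frame. Coordinates are 0-based; `skip_pos` is the index of the skipped
# nucleotide, i.e. the first base of the stop codon.

#' Construct a slippery motif
#'
#' @param pre_codon Codon translated immediately before the shift.
#' @param stop_codon `"UAA"` or `"UAG"` (the shifty stop).
#' @param motif_class `"classical"` or `"novel"`.
#' @return One-row data frame with `pre_codon`, `stop_codon`, `motif`
#'   (label such as `"AAA-UAA"`) and `motif_class`.
#' @export
slippery_motif <- function(pre_codon, stop_codon,
                           motif_class = c("classical", "novel")) {
  motif_class <- match.arg(motif_class)
  pre_codon <- normalize_rna(pre_codon)
  stop_codon <- normalize_rna(stop_codon)
  if (nchar(pre_codon) != 3L) stop("pre_codon must be a triplet")
  if (!stop_codon %in% c("UAA", "UAG")) {
    stop("stop_codon must be UAA or UAG (the shifty stop)")
  }
  data.frame(pre_codon = pre_codon, stop_codon = stop_codon,
             motif = paste(pre_codon, stop_codon, sep = "-"),
             motif_class = motif_class, stringsAsFactors = FALSE)
}

#' Default slippery-motif catalog
#'
#' The two classical Euplotes motifs (AAA-UAA, AAA-UAG) plus the ten
#' distinct novel pre-codon/stop combinations reported for
#' E. octocarinatus proteins with putative novel slippery sequences.
#'
#' @return Data frame of 12 motifs (see [slippery_motif()]).
#' @export
default_motif_catalog <- function() {
  classical <- rbind(
    slippery_motif("AAA", "UAA", "classical"),
    slippery_motif("AAA", "UAG", "classical")
  )
  novel <- list(
    c("UUU", "UAG"), c("UUU", "UAA"), c("AUU", "UAA"), c("AUU", "UAG"),
    c("AAG", "UAA"), c("ACC", "UAA"), c("AGA", "UAG"), c("UAU", "UAG"),
    c("CUU", "UAA"), c("AAU", "UAA")
  )
  rbind(classical,
        do.call(rbind, lapply(novel, function(m) {
          slippery_motif(m[1], m[2], "novel")
        })))
}

.empty_sites <- function() {
  data.frame(transcript_id = character(0), skip_pos = integer(0),
             pre_codon = character(0), stop_codon = character(0),
             motif = character(0), motif_class = character(0),
             next_codon = character(0), stringsAsFactors = FALSE)
}

.sites_frame <- function(transcript_id, seq, skip, motifs) {
  if (!length(skip)) return(.empty_sites())
  pre <- substring(seq, skip - 2L, skip)
  stopc <- substring(seq, skip + 1L, skip + 3L)
  lab <- paste(pre, stopc, sep = "-")
  cls <- motifs$motif_class[match(lab, motifs$motif)]
  data.frame(transcript_id = transcript_id, skip_pos = skip,
             pre_codon = pre, stop_codon = stopc, motif = lab,
             motif_class = cls,
             next_codon = substring(seq, skip + 2L, skip + 4L),
             stringsAsFactors = FALSE)
}

#' Scan a transcript for slippery +1 PRF sites
#'
#' With `frame_tracking = TRUE` (the default) the transcript is walked
#' codon-wise from frame 0. At each in-frame stop codon the site is
#' accepted when (i) the preceding in-frame codon plus the stop match a
#' catalog motif, (ii) at least `min_downstream_codons` complete codons
#' remain after the skipped base, and (iii) fewer than `max_sites` sites
#' have been accepted. After an accepted site the walk resumes one base
#' downstream (the +1 frame), mimicking serial frameshifts; an
#' unaccepted stop terminates the ORF and the scan. Sites whose 7-mer
#' windows overlap a previous site are rejected with a warning.
#'
#' With `frame_tracking = FALSE` every position whose 6-mer matches a
#' motif is reported regardless of reading frame (exploratory mode).
#'
#' @param seq Transcript nucleotide sequence.
#' @param motifs Motif catalog, as from [default_motif_catalog()].
#' @param code Genetic code used to recognise stop codons.
#' @param frame_tracking Scan in the tracked reading frame (see above).
#' @param min_downstream_codons Complete codons required after the skip.
#' @param max_sites Maximum accepted sites per transcript.
#' @param transcript_id Id recorded in the output.
#' @return Data frame of sites ordered by position: `transcript_id`,
#'   `skip_pos` (0-based index of the skipped base, the first base of
#'   the stop codon), `pre_codon`, `stop_codon`, `motif`, `motif_class`,
#'   `next_codon` (the codon read after the skip).
#' @export
scan_slippery_sites <- function(seq, motifs = default_motif_catalog(),
                                code = euplotes_genetic_code(),
                                frame_tracking = TRUE,
                                min_downstream_codons = 1L,
                                max_sites = 3L,
                                transcript_id = NA_character_) {
  if (!nrow(motifs)) stop("motif set is empty")
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  if (n < 7L) return(.empty_sites())
  keys <- motifs$motif
  need <- 3L * min_downstream_codons

  if (frame_tracking) {
    skips <- integer(0)
    pos <- 0L  # 0-based start of the codon under the ribosome
    while (pos + 3L <= n) {
      codon <- substring(seq, pos + 1L, pos + 3L)
      if (codon %in% code$stop_codons) {
        accept <- FALSE
        if (pos >= 3L && length(skips) < max_sites &&
            codon %in% c("UAA", "UAG")) {
          lab <- paste(substring(seq, pos - 2L, pos), codon, sep = "-")
          if (lab %in% keys && (n - pos - 1L) >= need) {
            if (length(skips) && (pos - 3L) <= (skips[length(skips)] + 3L)) {
              warning("overlapping slippery windows at ", pos,
                      "; site rejected")
            } else {
              skips <- c(skips, pos)
              accept <- TRUE
            }
          }
        }
        if (!accept) break  # this stop terminates the ORF
        pos <- pos + 1L     # skip one base, continue in the +1 frame
      } else {
        pos <- pos + 3L
      }
    }
    return(.sites_frame(transcript_id, seq, skips, motifs))
  }

  # naive any-position scan
  sixmers <- paste0(motifs$pre_codon, motifs$stop_codon)
  skips <- integer(0)
  for (i in 0:(n - 7L)) {
    if (substring(seq, i + 1L, i + 6L) %in% sixmers &&
        (n - i - 4L) >= need) {
      skips <- c(skips, i + 3L)
    }
  }
  .sites_frame(transcript_id, seq, skips, motifs)
}

#' Build a frameshift-joined gene model
#'
#' Translates the transcript in frame 0 up to the codon before the first
#' slippery stop, skips one nucleotide at each site, and continues in
#' the next frame; the terminal segment ends at the first stop codon in
#' its frame (or at the sequence end). With no sites the model is the
#' plain 0-frame halt translation.
#'
#' @param transcript_id Id of the transcript.
#' @param seq Transcript nucleotide sequence.
#' @param sites Data frame of sites as from [scan_slippery_sites()],
#'   ordered and non-overlapping; 0 to `max_junctions` rows.
#' @param code Genetic code.
#' @param max_junctions Maximum allowed junctions (default 3).
#' @return An object of class `frameshift_model`: a list with
#'   `transcript_id`, `seq`, `sites`, `protein`, `junctions` (0-based
#'   protein indices of the last residue of each frame segment),
#'   `frame_of_residue` (transcript frame of each residue's codon) and
#'   `segments` (per-segment residue and nucleotide spans).
#' @export
build_frameshift_model <- function(transcript_id, seq, sites = NULL,
                                   code = euplotes_genetic_code(),
                                   max_junctions = 3L) {
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  if (is.null(sites)) sites <- .empty_sites()
  if (nrow(sites) > 1L && is.unsorted(sites$skip_pos)) {
    sites <- sites[order(sites$skip_pos), , drop = FALSE]
  }
  if (nrow(sites) > max_junctions) {
    stop("more than ", max_junctions, " junctions in one gene")
  }

  pieces <- character(0)
  seg_frame <- integer(0)
  seg_nt_start <- integer(0)
  seg_nt_end <- integer(0)
  cur <- 0L  # 0-based nt position where the current segment starts

  if (nrow(sites)) {
    for (k in seq_len(nrow(sites))) {
      skip <- sites$skip_pos[k]
      stopc <- substring(seq, skip + 1L, skip + 3L)
      if (stopc != sites$stop_codon[k] ||
          !stopc %in% code$stop_codons) {
        stop("site ", k, ": transcript does not carry stop codon ",
             sites$stop_codon[k], " at position ", skip)
      }
      if (skip >= 3L &&
          substring(seq, skip - 2L, skip) != sites$pre_codon[k]) {
        stop("site ", k, ": pre-codon mismatch at position ", skip)
      }
      if ((skip - cur) %% 3L != 0L) {
        stop("site ", k, ": stop codon not in the tracked frame")
      }
      ncod <- (skip - cur) %/% 3L
      if (ncod < 1L) stop("segment of zero residues before site ", k)
      piece <- translate_frame(substring(seq, cur + 1L, skip), 0L, code,
                               "readthrough")
      if (grepl("*", piece, fixed = TRUE)) {
        stop("premature stop codon inside segment ", k)
      }
      pieces <- c(pieces, piece)
      seg_frame <- c(seg_frame, cur %% 3L)
      seg_nt_start <- c(seg_nt_start, cur)
      seg_nt_end <- c(seg_nt_end, skip)
      cur <- skip + 1L
    }
  }

  # terminal segment: halt at the first in-frame stop (or sequence end)
  term <- if (cur + 3L <= n) {
    translate_frame(substring(seq, cur + 1L, n), 0L, code, "halt")
  } else ""
  if (nrow(sites) && !nzchar(term)) {
    stop("terminal segment of zero residues after the last site")
  }
  pieces <- c(pieces, term)
  seg_frame <- c(seg_frame, cur %% 3L)
  seg_nt_start <- c(seg_nt_start, cur)
  seg_nt_end <- c(seg_nt_end, cur + 3L * nchar(term))

  seg_len <- nchar(pieces)
  protein <- paste(pieces, collapse = "")
  junctions <- if (nrow(sites)) {
    as.integer(cumsum(seg_len[seq_len(nrow(sites))]) - 1L)
  } else integer(0)

  structure(
    list(transcript_id = transcript_id,
         seq = seq,
         sites = sites,
         protein = protein,
         junctions = junctions,
         frame_of_residue = rep(seg_frame, seg_len),
         segments = data.frame(
           segment = seq_along(pieces),
           frame = seg_frame,
           res_start = c(0L, cumsum(seg_len)[-length(seg_len)]),
           res_end = cumsum(seg_len),
           nt_start = seg_nt_start,
           nt_end = seg_nt_end
         )),
    class = "frameshift_model"
  )
}

#' @export
print.frameshift_model <- function(x, ...) {
  cat("Frameshift gene model", x$transcript_id, "\n")
  cat("  junctions:", length(x$junctions),
      if (length(x$junctions)) paste0("(after residues ",
                                      paste(x$junctions, collapse = ", "),
                                      ")") else "", "\n")
  cat("  protein length:", nchar(x$protein), "residues\n")
  invisible(x)
}

#' Conceptual -2 frameshift alternative at a slippery site
#'
#' A -2 shift at the same junction would re-read one extra codon
#' starting two bases before the skipped nucleotide, inserting one extra
#' residue into the product while leaving the downstream sequence
#' identical. The resulting mass excess discriminates the two
#' directions.
#'
#' @param site One site row (as from [scan_slippery_sites()]).
#' @param code Genetic code used to translate the extra codon.
#' @return List with `extra_codon`, `extra_residue` and `mass_delta`
#'   (monoisotopic residue mass of the extra residue, Da).
#' @export
conceptual_minus2 <- function(site, code = euplotes_genetic_code()) {
  if (site$skip_pos < 2L) stop("skip position too close to the 5' end")
  extra_codon <- paste0(substring(site$pre_codon, 2L, 3L),
                        substring(site$stop_codon, 1L, 1L))
  aa <- unname(code$codon_to_aa[extra_codon])
  if (is.na(aa) || aa == "*") {
    stop("-2 alternative re-reads a stop codon")
  }
  list(extra_codon = extra_codon, extra_residue = aa,
       mass_delta = unname(AA_MONO[aa]))
}

#' Scan and model every transcript of a set
#'
#' @param transcripts Named character vector of transcript sequences.
#' @param motifs Motif catalog.
#' @param code Genetic code.
#' @param ... Passed to [scan_slippery_sites()].
#' @return List with `models` (named list of [build_frameshift_model()]
#'   results) and `sites` (row-bound site table).
#' @export
predict_models <- function(transcripts, motifs = default_motif_catalog(),
                           code = euplotes_genetic_code(), ...) {
  ids <- names(transcripts)
  if (is.null(ids)) stop("transcripts must be named")
  models <- vector("list", length(transcripts))
  names(models) <- ids
  all_sites <- vector("list", length(transcripts))
  for (i in seq_along(transcripts)) {
    s <- scan_slippery_sites(transcripts[[i]], motifs, code,
                             transcript_id = ids[i], ...)
    models[[i]] <- build_frameshift_model(ids[i], transcripts[[i]], s, code)
    all_sites[[i]] <- s
  }
  list(models = models, sites = do.call(rbind, all_sites))
}

#' Write a site table as TSV
#'
#' @param sites Site data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write frame segments as GFF3-style features
#'
#' One `frame_segment` feature per model segment, with 1-based inclusive
#' nucleotide coordinates and the reading frame in the attributes.
#'
#' @param models Named list of frameshift models.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_segments_gff <- function(models, path) {
  lines <- c("##gff-version 3")
  for (m in models) {
    seg <- m$segments
    keep <- seg$nt_end > seg$nt_start
    seg <- seg[keep, , drop = FALSE]
    if (!nrow(seg)) next
    lines <- c(lines, sprintf(
      "%s\tprfscan\tframe_segment\t%d\t%d\t.\t+\t.\tID=%s.seg%d;frame=%d",
      m$transcript_id, seg$nt_start + 1L, seg$nt_end, m$transcript_id,
      seg$segment, seg$frame))
  }
  writeLines(lines, path)
  invisible(path)
}
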