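---
title: "Methods: proteogenomic verification of +1 ribosomal frameshifting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteogenomic verification of +1 ribosomal frameshifting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prfscan)
```

## The biological problem

In *Euplotes* ciliates a remarkable share of macronuclear genes is
interrupted by a stop codon in the zero reading frame and can only
produce a full-length protein if the ribosome executes a +1 programmed
ribosomal frameshift (PRF) at that stop. The licensing element — the
"shifty stop" — is minimal: a sense codon (in the classical motif the
lysine codon AAA) immediately 5' of a UAA or UAG whose first base the
ribosome skips before resuming translation one nucleotide downstream.
Because *Euplotes* reads UGA as cysteine, UAA and UAG are the only
stops, and an internal in-frame stop is exactly where a candidate
frameshift lives.

Nucleic-acid evidence for such genes is strong (two ORFs that would
align to a single homologous protein if joined), but protein-level
evidence requires peptides — ideally peptides that physically span the
junction, whose sequence pins down both the location and the direction
of the shift. `prfscan` implements that verification pipeline end to
end, together with a ground-truthed simulator so every stage can be
validated without any external data.

## The model

A transcript with junctions at skipped positions $s_1 < s_2 < \dots$
(each $s_k$ the 0-based index of the first base of a shifty stop) is
translated as the concatenation of frame segments: frame 0 up to the
codon before $s_1$, then from $s_1 + 1$ in the +1 frame, and so on;
the terminal segment ends at the first in-frame stop. Up to three
junctions per gene are supported (multi-shift genes are documented in
euplotid telomerase and major-vault-protein genes). The per-residue
frame annotation drives the evidence classes:

* **a** — some junction is spanned by a peptide covering both the last
  residue of one segment and the first residue of the next;
* **b** — no spanning, but coverage on both sides of the first
  junction;
* **c** — coverage only downstream of the first junction;
* **d** — coverage only upstream.

The published taxonomy defines b as "every segment adjacent to a
junction covered", which for a 3-segment gene with coverage in segments
1 and 2 only assigns no class at all, while the classes must partition
the evidenced genes. We therefore key b/c/d off the first junction
(coverage in segment 1 and beyond → b; none in segment 1 → c; only in
segment 1 → d), which coincides with the published wording for
single-junction genes — the overwhelmingly common case — and keeps the
partition total. Per-junction relations remain available from
`map_peptide()` for the stricter reading.

### +1 versus −2 discrimination

A −2 shift at the same junction would produce the identical C-terminal
sequence but re-read one extra codon starting two bases before the
skipped nucleotide, inserting one extra residue. At a classical
AAA-UAR site that codon is AAU (Asn), so the −2 product is heavier by
the asparagine residue mass, 114.0429 Da — far beyond any instrument
tolerance. `discriminate_direction()` compares an observed spanning
peptide mass against both theoretical masses at 20 ppm; with a gap two
orders of magnitude above the tolerance the call is never ambiguous.

## Scanning rules and their rationale

`scan_slippery_sites()` walks the transcript codon-wise (frame
tracked), because a genuine +1 PRF site must terminate the currently
translated ORF: only an in-frame UAA/UAG whose preceding in-frame codon
matches a catalog motif is a candidate. Three further rules:

* at least one complete codon must follow the skipped base (default 1,
  configurable) — a terminal stop is never a site;
* after an accepted site the walk resumes one base downstream,
  mimicking serial shifts, so 2- and 3-junction genes are scanned in
  one pass;
* sites whose 7-mer windows overlap are rejected with a warning as
  biologically incoherent.

Stops in the *next* frame upstream of a junction are irrelevant by
construction (segments are only translated downstream of their start),
which handles genes whose +1-frame ORF begins upstream of the 0-frame
stop. A naive any-position scan (`frame_tracking = FALSE`) exists for
exploration only.

The default catalog holds the two classical motifs (AAA-UAA, AAA-UAG)
plus the ten distinct novel pre-codon/stop combinations reported for
*E. octocarinatus*; the catalog is an ordinary data frame and can be
extended freely.

## Digestion, masses, and matching

Digestion is fully specific with up to two missed cleavages (the
reference search setting): trypsin after K/R not before P, GluC after E
(D optional), chymotrypsin after F/W/Y/L not before P (M optional).
Peptide length defaults to 6–50 residues — the engine defaults are not
published for the original search, so these are declared, not inferred.
The three-enzyme panel matters scientifically: ~94% of classical
junctions put a lysine immediately before the stop, so trypsin cleaves
right at the junction and rarely yields spanning peptides; GluC and
chymotrypsin recover them.

Masses are monoisotopic, from a 9-decimal standard residue table with
carbamidomethyl-C fixed (+57.021464 Da) and up to two variable
oxidations per peptide (+15.994915 Da each); the test suite checks the
table against an independently coded elemental-composition oracle to
1e-6 Da. Fragment matching uses singly charged b/y ladders
($b_i + y_{n-i}$ must reconstruct the precursor, asserted to 1e-6) with
a deliberately transparent score: the fraction of theoretical ions
found within 0.1 Da, each observed peak supporting at most one ion. The
probabilistic scores of commercial engines are out of scope — the
biological conclusions rest on peptide identity and accurate mass, not
on a score scale. Precursor matching is at 20 ppm; precursor charges 2
and 3 are considered and fragments are charge 1 only. Ties are broken
by smaller precursor error, then target before decoy, then
lexicographically — all deterministic.

FDR control is target–decoy with full-sequence reversed decoys
(pseudo-reversal available), filtered at q = 0.01 first at peptide
level (best score per peptide) and then at protein level, choosing in
each stage the loosest score threshold whose decoy/target ratio stays
at or below q. Peptides shared between proteins are excluded from
classification, mirroring unique-peptide accounting.

## The simulator: what it emulates, and what it does not

`generate_transcriptome()` draws genes with uniform codon usage over
the 62 *Euplotes* sense codons (an AT-rich bias preset was considered
and rejected as a default to keep chance-motif rates predictable),
plants junctions in 11.4% of genes (94.2% classical, the remainder
uniform over the novel catalog; 1/2/3 junctions with probabilities
0.90/0.07/0.03), and ends every transcript exactly at its terminal
stop. Chance motif contexts upstream of a terminal stop therefore have
no downstream continuation and form a built-in hard-negative set for
the scanner. Gene length is normal with mean 200 codons (sd 40,
minimum 60) — a desk-scale choice; protein abundance is log-normal
(meanlog 0, sdlog 2) with PRF genes scaled by 0.3, reflecting the
observation that frameshifted genes are expressed at low abundance.
Peptides are detected independently with probability
$p = 0.5\,A/(A+25)$ at protein abundance $A$; one spectrum per detected
peptide, charge 2 with probability 0.7 (else 3), Gaussian 5 ppm m/z
error on precursor and fragments, and 20 uniform noise peaks per
spectrum. All of these are declared modeling choices fixed before any
validation was run; none is a published measurement.

Under these conditions the detected PRF fraction lands around 8–10%
versus the planted 11.4%, reproducing the qualitative gap between
protein-level and nucleic-acid-level frequency estimates. What passing
tests on this simulator do **not** show: robustness to real
chromatography, isotope envelopes, co-eluting precursors, non-uniform
codon usage, semi-tryptic peptides, or abundance-correlated noise —
none of which are modeled.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout; `skip_pos` is the
  skipped nucleotide itself.
* DNA input (T) is silently normalized to RNA (U); lowercase is
  uppercased; ambiguity codes are rejected rather than translated to X,
  because X has no mass.
* I/L are distinct letters with identical mass; sequence comparisons
  keep the letters. Spectra can therefore in principle be assigned to
  an I/L (or, on heavy peptides, K/Q) isobaric twin in a different
  protein; with ≥6-residue peptides this is vanishingly rare but it is
  the one stochastic caveat on exact end-to-end closure.
* Transcripts shorter than 7 nt scan to an empty result, not an error;
  a zero-residue segment between junctions is an error.
* An FDR stage with no qualifying threshold returns an empty accepted
  set; an all-target input is accepted wholesale (FDR 0).
* With fixed seeds every artifact — FASTA, MGF, TSV, JSON — is
  byte-identical across runs.

## Validation protocol

The test suite validates each module against an independent route
(loop translator, brute-force digestion enumeration,
elemental-composition masses) and then closes the loop end to end: on
a noiseless 1,000-gene simulation every spanned planted junction is
localized exactly with +1 calls on both the sequence and the mass
route, and the pipeline's PRF-fraction estimate equals the planted
detected fraction; with default noise across ten seeds the estimate
stays inside the binomial 95% band of the planted detected fraction
and the realized decoy fraction never exceeds 0.01. Problem sizes
(1,000 genes for closure, 500 genes per seed for parameter recovery)
were chosen as the package's desk-scale validation conditions.

## Known limitations

* The scorer is intentionally simple; it is not calibrated against any
  engine and its absolute values are not comparable across datasets.
* Stimulatory-element context (Shine–Dalgarno-like sequences,
  pseudoknots) is not searched — no association with euplotid
  frameshifting has been observed — and tRNA anticodon-loop mechanics
  are out of scope.
* Homology-based nomination of candidate genes is not implemented; the
  scanner is motif-driven.
* Selenocysteine insertion at UGA is not modeled; UGA is always Cys
  under the *Euplotes* code.
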