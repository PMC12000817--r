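---
title: "Comparative mitogenome characterization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenome characterization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitovult)
library(dplyr)
```

mitovult implements the standard comparative characterization of an annotated
avian mitochondrial genome, built around the mitogenome of the Asian king
vulture (*Sarcogyps calvus*) and its comparison with the other Old World
vultures (tribe Gypini) and the New World vultures (family Cathartidae). This
vignette explains what each stage computes, the assumptions and parameter
choices behind it, and what the packaged synthetic-data generators do and do
not emulate.

## The gene table and its arithmetic

The primary input is a ten-column tab-separated gene table (start, end,
declared length, direction, type, gene name, product, anticodon, start codon,
stop codon), the way mitogenome annotations are published. Coordinates are
1-based and inclusive everywhere in the package; there are no half-open
intervals on the public surface. Minus-strand rows may list coordinates
high-to-low and are normalized to `start <= end` plus a strand symbol, and any
dash glyph (hyphen, en dash, minus sign) in the direction column is read as
minus — published tables are typeset inconsistently, and silently dropping a
row over a glyph would corrupt every downstream count.

Validation is report-only: `validate_feature_table()` flags disagreements
between the declared length and `end - start + 1`, CDS lengths not divisible
by 3 (incomplete stop codons, completed by polyadenylation in vivo, are normal
in vertebrate mitogenomes — the vulture's COX3 at 784 bp is one), overlapping
features (mitochondrial gene tables legitimately overlap; the packaged table
has ATP8/ATP6 and ND4L/ND4 style overlaps), and out-of-bounds features. The
pipeline never "repairs" an annotation: observed start/stop codons extracted
from sequence are reported alongside the declared ones, and the reader decides.

Two arithmetic conventions matter downstream:

* The **protein-coding span** is the plain sum of CDS lengths, without
  deduplicating overlapping bases. On the packaged table this gives
  11,407 bp of 17,750 bp (64.26%); deduplicating the small CDS overlaps
  would not reproduce the published span, so plain summation is clearly the
  convention in use in this literature.
* **Composition** is reported over non-N positions only (the table's genome
  has none, but resequenced mitogenomes often do), rounded half-away-from-zero
  to one decimal; fractions elsewhere use two decimals. Half-up rounding is
  chosen over R's banker's rounding to match how printed percentages are
  conventionally rounded.

Origin-spanning (wrap-around) features are rejected with an error rather than
supported: the packaged table contains none, and silently unwrapping
coordinates would make every downstream position ambiguous.

## Codon usage and RSCU

Codons are counted as in-frame, non-overlapping triplets from position 1 of
each strand-oriented CDS; trailing partial codons are dropped and codons
containing N are skipped but tallied. Relative synonymous codon usage is the
codon's count divided by the mean count of its synonymous family, so family
values sum to the family size whenever the family is used at all — a property
the test suite checks on random usage tables for all 21 families of the
vertebrate mitochondrial code.

The genetic code is a parameter, defaulting to the vertebrate mitochondrial
code (from `Biostrings::getGeneticCode`): AGA/AGG join TAA/TAG in a four-codon
stop family, ATA is Met, TGA is Trp, and GTG is an admissible initiation codon
(the vulture's COX1 initiates with GTG). The standard nuclear code is exposed
as an option because general-purpose codon-usage software sometimes applies it
to mitochondrial genes, which moves AGA/AGG into the arginine family and
visibly changes the stop-family RSCUs; having both codes makes such outputs
reproducible. RSCU is computed over the pooled protein-coding genes by
default, with per-gene tables available by calling `count_codons()` on single
sequences. Ranking ties are broken lexicographically so reported "top codons"
are deterministic.

## Microsatellite scanning

`find_ssrs()` reports maximal, non-extendable perfect tandem repeats of
primitive motifs of length 1–6. "Primitive" means the motif is not itself a
repetition of a shorter motif, so an (AC)₄ run is never additionally reported
as (ACAC)₂; "non-extendable" means no further full motif copy exists on either
side, and the reported span is exactly `motif length × repeats` even when a
partial further copy follows. Runs containing N are never part of a hit.
Scanning is linear even for circular genomes — this matches standard
microsatellite tools, and origin-spanning repeats are out of scope.

The default minima are 4 repeats for mononucleotide motifs and 3 for motif
lengths 2–6. Published SSR totals are extremely sensitive to these settings
(and published censuses are not always internally consistent), so the
thresholds are fully configurable and the package makes no attempt to match
any particular published total. The scanner is verified against an exhaustive
positional oracle that tests every (start, motif-length) pair independently.

The census (`ssr_census()`) groups hits by the feature containing their start
position — first feature in table order wins when annotations overlap, and
hits outside every feature fall into "(unidentified region)" — and tabulates
mono/di/tri/tetra columns plus a pooled penta+hexa column, the layout this
literature prints.

## Group-conserved substitution sites

The core comparative analysis scans per-gene amino-acid alignment columns for
sites where two taxon groups are each monomorphic yet differ: all Gypini rows
share one residue, all Cathartidae rows share a different one. Any gap or
non-standard residue in a qualifying row disqualifies the column; the
alignments consumed here are of conserved mitochondrial proteins, where a gap
under a candidate diagnostic substitution is more plausibly an alignment
artifact than a character, and strictness keeps the detector deterministic.
Positions are reported per gene in ungapped numbering on the first group-A
taxon, alongside the raw alignment column. `focal_vs_group_sites()` applies
the same logic within a group: columns where a focal taxon differs from a
residue shared by all other members.

Residues are classified by side-chain chemistry: Hydrophobic
(A, V, L, I, M, F, W, Y), Polar uncharged (S, T, N, Q), Positive (K, R, H),
Negative (D, E) and Special case (C, G, P). When deciding whether a
substitution crosses chemical classes, the three special-case residues each
count as their own singleton class: cysteine (disulfide bonds), glycine
(conformational freedom) and proline (backbone rigidity) are special for
unrelated reasons, and a C→G exchange is chemically a change — pooling them
into one class would call it conservative. This singleton rule is also the
only reading under which the published 67-site table is internally consistent,
since it lists a C→G site among substitutions "with different side chain
property".

The packaged transcriptions of the two published site tables serve as
fixtures. The classifier reproduces all 134 printed class labels of the
67-site Gypini-versus-Cathartidae table. In the 43-site table of
*S. calvus*-private substitutions it reproduces 85 of 86 labels; the single
exception is the source table's ND3 position-108 row, which prints threonine
as Hydrophobic where every scheme in use places it in Polar uncharged. That
row is preserved verbatim in the fixture and documented rather than edited.
One further transcription note: the published gene table's ND3 row spans
351 bp against a declared length of 354 bp, and only 354 reproduces the
published protein-coding total; the packaged table uses the 354-bp span.

## Distances

`p_distance()` is the uncorrected proportion of differing sites as a
percentage, with pairwise deletion: per pair, only columns where either row
has a gap or a non-standard residue are excluded. This is the default because
it is the least parameterized choice and the one most distance tables in this
literature appear to use; a Poisson correction (`-ln(1 - p)`) and complete
deletion are exposed because publications rarely state their settings, and
re-running under both modes brackets the plausible published values.
Distances are reported to two decimals as percentages. Concatenated distances
equal the used-site-weighted mean of per-gene distances, which the tests
assert, and the implementation is cross-checked against ape's raw
pairwise-deletion distance on a small alignment.

## What the synthetic data emulates

The generators exist so every stage has inputs with known truth:

* `generate_mitogenome()` realizes a feature layout (by default the packaged
  17,750-bp vulture layout) with declared start/stop codons in place, CDS
  bodies drawn from a configurable codon-weight map with stop codons excluded
  (so planted genes translate cleanly), and non-coding sequence drawn i.i.d.
  at a target AT fraction, 54.1% by default to mirror the real genome's
  composition. With a 17-kb genome the realized AT fraction is binomially
  concentrated within a couple of points of the target. Where same-strand CDS
  overlap, the later feature wins and the truth tallies are re-read from the
  final sequence; opposite-strand CDS overlaps are rejected as infeasible.
* `plant_ssrs()` overwrites chosen spans with exact repeats and fixes one
  flanking base on each side so a plant cannot extend past its declared
  repeat count; the scanner then recovers each plant as exactly one hit.
* `generate_clade_alignments()` builds two gapless clades of protein
  sequences (default 5 and 6 taxa, the two vulture group sizes; default gene
  lengths are the 13 vulture protein lengths) with planted group-conserved
  sites, optional focal-private sites, optional between-group divergence, and
  within-group noise drawn uniformly over the 19 alternative residues. In
  constraint mode (the default for recovery tests) noise is post-processed so
  it can never create a spurious qualifying column, making recovery exact;
  unconstrained mode exists for power exploration. Planting a between-group
  divergence fraction with no noise makes every cross-group p-distance
  exactly that fraction, which anchors the distance tests.

What the generators deliberately do **not** emulate: realistic substitution
processes (no mtREV/JTT-style exchangeabilities, no rate heterogeneity, no
transition/transversion structure), indels (alignments are gapless, while
real alignments of these proteins contain gaps), phylogenetic correlation
within groups (rows are exchangeable, real clades are nested), and base
composition structure beyond a single AT fraction (no strand asymmetry, no
codon-position effects). Passing the recovery tests therefore shows the
detectors compute their definitions exactly; it does not show robustness to
alignment error or to borderline conservation, which real data exhibit and
which the report-only validation surfaces are designed to expose rather than
absorb.

Problem sizes in the test suite follow the study's own scales where they are
desk-scale (the 39-row gene table, the 67- and 43-site tables, 11-taxon
clades) and use a few hundred bases or columns for the brute-force oracle
comparisons, which is ample to exercise every code path of scanners whose
state is local.

## Numerical and degenerate-input choices

* Rounding: half away from zero; composition 1 decimal, fractions and
  distances 2 decimals.
* FASTA normalization: sequences uppercased, U→T, IUPAC ambiguity codes
  collapsed to N; anything else is a format error naming record and position.
  N is permitted throughout, and each module defines its own N handling
  (excluded from composition denominators, breaks SSR runs, skipped codons).
* Empty inputs error early: empty FASTA, empty group file, all-N sequence,
  alignment with fewer than two rows, table with no CDS for span statistics.
* Ties: codon ranking breaks ties lexicographically; genes tied for most
  substitution sites are reported as a set.
* All randomness flows through a single integer seed per generator call;
  identical seeds give byte-identical outputs.

## Command-line interface

Every stage is also reachable through `mito_cli()` (wrapped by the installed
`exec/mitovult` script) with subcommands `profile`, `codon-usage`, `ssr`,
`subst`, `dist` and `simulate`. Each run writes plain-TSV reports plus a
`manifest.json` recording the subcommand, every parameter and the package
version, so a run is reproducible from its manifest alone. Format errors
name the offending file and exit non-zero.

## Known limitations

* GenBank flat files and GFF3 are not parsed; the feature-table dialect and
  FASTA are the interchange formats.
* The SSR scanner reports perfect repeats only — no compound or interrupted
  microsatellites — and does not scan across the circular origin.
* Distances are alignment-based and uncorrected (or Poisson-corrected);
  model-based distances and tree building are out of scope.
* Site detection requires strict within-group monomorphism; it has no notion
  of "nearly conserved" columns.
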