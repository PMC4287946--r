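---
title: "Parsing, validating and mapping HGVS sequence variants"
author: "hgvsr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsing, validating and mapping HGVS sequence variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgvsr)
```

## The problem

Sequence variants in clinical reports, databases and the literature are
written in the Human Genome Variation Society (HGVS) nomenclature:
`NM_182763.2:c.688+403C>T` names a reference sequence, a coordinate system
(`c.`, CDS-relative) and a positioned edit.  Working with such strings
programmatically requires four capabilities that this package provides as a
library: parsing strings into typed objects, formatting objects back to
canonical text, validating variants both internally and against reference
sequence, and projecting variants between genomic (`g.`), transcript
(`n.`/`c.`/`r.`) and protein (`p.`) coordinates through genome–transcript
alignments — including alignments that contain insertion/deletion
discrepancies, which defeat tools that assume a gapless exon model.

## The object model

A `sequence_variant` is an accession, a sequence-type letter and a
*posedit* (interval + edit).  Three position kinds cover the coordinate
systems:

* `simple_position` — plain 1-based genomic coordinates (`g.`/`m.`);
* `base_offset_position` — transcript coordinates with an intronic offset
  and a datum.  `c.688+403` is base 688, offset +403, datum `cds_start`;
  `c.-14` is a 5' UTR base (there is no position 0); `c.*3` counts from the
  first base after the stop codon (datum `cds_end`);
* `aa_position` — a residue number carrying its reference amino acid.

Edits are an explicitly tagged union: substitution, deletion, insertion,
deletion–insertion, duplication, repeat and identity at the nucleotide
level; substitution, deletion–insertion, frameshift and identity at the
protein level.  All coordinates in the model are 1-based and inclusive, as
in HGVS itself; this removes any conversion layer between text and model.
The only 0-based half-open arithmetic in the package is inside alignment
maps, where interbase coordinates make gap and intron arithmetic
off-by-one-proof; the conversion happens at that module's boundary only.

Positions are totally ordered (`position_order()`): 5' UTR before CDS,
`*`-positions after, and within a base smaller offsets first, so
`c.88 < c.88+2 < c.89-2 < c.89`.  Interval constructors enforce
`start <= end`; the parser defers that check so that a string such as
`g.7_5del` still parses and is *reported* by the validator rather than
rejected mid-parse.

Deliberately out of scope, matching the package's intended subset of the
recommendations: compound alleles (`[...;...]`), mosaic and chimeric
variants, inversions, conversions, uncertain positions (`?`, parenthesised
ranges), and canonicalization such as 3'-shifting.

## The grammar

`parse_hgvs()` is a PEG-style recursive-descent parser: a registry of named
productions with ordered choice and full-input consumption.  Every
production can be invoked on its own through `parse_rule()` — e.g.
`parse_rule("c_posedit", "688+403C>T")` or
`parse_rule("base_offset_position", "88-2")` — which is what makes the
grammar usable for fragments, not just complete variants.  Design choices
worth stating:

* One canonical spelling in, one out: type letters and nucleotides are
  case-sensitive (upper-case DNA, lower-case RNA), whitespace is never
  legal, and a point interval never prints as `x_x`.  This makes
  `format(parse(s)) == s` exact on canonical strings and
  `parse(format(v)) == v` structural on model objects — both properties are
  enforced in the test suite over 10^4 generated cases.
* Deleted/duplicated sequences are accepted in sequence form (`delGTA`) and
  not in length form (`del3`): the sequence form is checkable against a
  reference, the length form adds ambiguity for no information.
* Gene-symbol annotations (`NM_x(GENE):c...`) are accepted and discarded
  with a warning, since they are common in the wild.
* Amino acids parse in 3-letter or 1-letter form and render 3-letter by
  default (`format(v, aa_format = "one")` switches).
* Errors are structured conditions (`hgvs_parse_error`) carrying the
  failing character position and the deepest rule attempted; the parser
  never fails unstructuredly on arbitrary bytes (fuzzed in the suite).

## Reference data: providers and synthetic loci

Mapping and extrinsic validation need sequences and transcript structures.
Seven generics (`get_seq`, `get_transcript`, `find_transcripts`,
`get_transcripts_for_gene`, `get_alignment_methods`,
`get_protein_accession`, `get_data_version`) define everything the rest of
the package consumes; `fixture_provider()` implements them over a
`locus_fixture`.  No network access exists anywhere.

A fixture is a contig, transcript sequences and transcript records: exon
spans stored in genomic ascending order with a strand flag (transcript-order
traversal is computed, never stored — one source of truth), per-exon
run-length alignment segments (`M` aligned, `D` genome-only, `I`
transcript-only), CDS bounds in `n.` coordinates, gene and alignment-method
labels.  Fixtures serialize to FASTA plus a JSON document whose coordinates
are 1-based inclusive, stated in its header.

`generate_locus()` builds such loci deterministically from a seed.  Its
defaults describe a compact but realistic coding locus: 2 transcripts of
three 80–150 bp exons separated by 60–200 bp introns — large enough for
intronic offsets, small enough that property tests over hundreds of seeds
run in seconds.  The generator emulates the transcript features that
historically break mappers: minus-strand transcripts, CDS start outside
exon 1, genome–transcript indels, and a second alignment method whose exon
boundary is shifted (the flanking intron bases are made equal to the moved
exonic bases, exactly the sequence ambiguity that makes real aligners
disagree).  Coding transcripts receive a clean open reading frame (no
internal stop, terminal stop codon) so protein inference is well defined.
What the generator does *not* emulate — and what passing tests therefore do
not show — includes sequencing error, polymorphism between reference
releases, overlapping genes on opposite strands, selenoproteins and other
non-standard translation, and the scale of a real transcript archive.

`toy_locus()` is a fixed demonstration locus with all of those features at
hand-chosen coordinates, including two plus-strand transcripts that share
exons but carry different ORF annotations in different reading frames.
Overlapping clean ORFs in two frames are possible because the shared exon
sequence is generated without `TA`/`TG` dinucleotides (hence no stop codon
in any frame) and each transcript's stop codon is patched in where the
other frame reads no stop.

## The indel-aware mapper

`build_alignment_map()` expands a record into blocks (`M`, `D`, `I`,
intron) over the transcript's genomic span.  Projection rules:

* exonic aligned bases map exactly, offset 0, in both directions;
* intronic bases anchor on the nearest exon boundary with a signed offset;
  at the exact midpoint of an even-length intron the tie goes to the
  boundary that is 5' in *transcript* orientation — a fixed rule chosen to
  keep round trips deterministic;
* a genomic base inside a `D` (genome-only) block has no transcript image:
  it is clamped to the transcript base immediately 5' of the gap and
  flagged (`gap = TRUE`), mirrored for transcript bases inside `I` blocks.
  Clamping rather than erroring is the design choice that keeps variants in
  discrepant regions mappable at all; the flag is surfaced as a warning on
  variant-level operations so the loss of exactness is never silent.

`c_to_g()`/`g_to_c()` compose this table with the CDS arithmetic
(`n_to_c()`/`c_to_n()`: piecewise linear, skipping position 0, `*` past the
CDS end).  On minus-strand transcripts interval endpoints swap and edit
sequences are reverse-complemented.  Edits spanning a splice boundary are
mapped endpoint-wise with a warning rather than rejected — genomic
deletions crossing exon boundaries are real and must round-trip to `g.`.
`liftover()` is the composition `c_to_g` then `g_to_c` under a second
transcript or a second alignment method of the same transcript.
`r.` variants are the formatter-level transliteration of `c.`/`n.`
(`to_rna_variant()`); their coordinates are identical, so no separate
mapping path exists.

`c_to_p()` infers protein consequences for exonic CDS variants: apply the
edit, translate reference and edited sequence with the standard nuclear
code, and classify the difference — identity (`p.(=)`), substitution
(including nonsense when the first affected residue is a new stop),
in-frame deletion/insertion/delins via common prefix/suffix trimming, or
frameshift at the first changed residue with the new-frame stop position
scanned through the 3' UTR (`Ter` omitted when no stop is reached before
the transcript ends).  A diff that reduces to a pure insertion before the
first or after the last residue is widened to a delins of the boundary
residue, since flanking-residue insertion syntax does not exist there.
Intronic and UTR positions raise a typed error directing users to describe
such variants at the `g.`/`n.` level; inferred protein variants always
format in parentheses.

## Validation

Intrinsic validation is provider-free and pure: interval order; the
insertion rule (the location range of an insertion must have length one,
i.e. two adjacent flanking positions — `688` and `688+1` count as
adjacent); agreement between a stated ref sequence and the interval span
where that span is decidable without reference data; and edit alphabet
versus sequence type.  Extrinsic validation consults a provider: known
accession, positions within bounds, stated ref bases against the reference
(intronic `c.`/`n.` positions are checked after projection to the genome
through the named alignment), and for protein variants the stated reference
residue against the translated CDS.  All findings are collected in a
report, never raised; `validate_variant()` short-circuits extrinsic checks
when intrinsic validation already failed, so reports never mix object-level
nonsense with reference-level noise.

## Numerical and testing choices

Test problem sizes are chosen to exercise every code path while keeping the
default suite fast on one CPU: 10^4 round-trip cases, 6 × 10^4 fuzz strings,
100 random fixtures for the mapper-versus-oracle comparison, 10^3
provider-derived variants for validator soundness and 10^3 random CDS edits
for protein inference.  The oracles are genuinely independent code paths: a
per-base walker that expands alignments base by base (against the block
arithmetic of the mapper), a second fixture reader built on seqinr (against
the Biostrings-based provider), and a translate-and-diff oracle for protein
calls.  `scripts/acceptance.R` recomputes the headline quantities from
scratch against the installed package.

Known limitations, beyond the scoped-out syntax above: no variant
canonicalization or 3'-shifting (two spellings of one variant are not
recognised as equal); repeat edits are not projected to protein
consequences; protein-level extrinsic validation checks only the reference
residue at the stated position; and the fixture provider holds whole loci
in memory, which is appropriate for synthetic loci, not for a genome-scale
archive.
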