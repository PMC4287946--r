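# hgvsr

Parsing, formatting, validation and coordinate mapping of sequence variants
written in the Human Genome Variation Society (HGVS) nomenclature, for R.

Variants like `NM_182763.2:c.688+403C>T` are how sequence changes travel
between sequencing pipelines, clinical reports and databases.  Using them
programmatically requires more than string handling: a typed object model
(`accession : type . position edit`), a grammar whose rules can parse whole
variants or fragments, canonical re-formatting, validation against a
reference sequence, and — the hard part — projection between genomic
(`g.`), transcript (`n.`/`c.`/`r.`) and protein (`p.`) coordinates through
genome–transcript alignments.  `hgvsr` implements all of this, including an
**indel-aware mapper**: alignments between a transcript and its genomic
reference may contain insertion/deletion discrepancies (`I`/`D` segments in
addition to matches), and positions falling inside such discrepancies are
clamped to the nearest aligned transcript/genomic base and flagged, instead
of being silently mis-mapped by a gapless exon model.

Coordinates follow HGVS conventions throughout: 1-based inclusive
intervals; CDS-relative positions with no position 0 (`c.-14` is 5' UTR,
`c.*3` counts past the stop codon); intronic positions as `base±offset`
(`688+403` = 403 bases into the intron after CDS base 688).  For a CDS
position, `c = n − cds_start + 1` inside the CDS, negative values 5' of it
and `*`(n − cds_end) past it; protein consequences are inferred by applying
the edit to the CDS and translating, with frameshifts reported as
`p.(XxxNYyyfsTer*k*)` where *k* is the stop position in the new reading
frame.

Reference data come through a seven-method provider interface backed by
plain-text locus fixtures; a deterministic synthetic-locus generator
(`generate_locus()`) builds test loci with minus-strand transcripts, CDS
starts outside exon 1, alignment indels and alternative alignment methods.
No network access is used anywhere.

## Worked example

A variant on transcript `TX1` of the bundled demonstration locus, projected
to the genome, onto a second transcript sharing the same exons but a
different ORF annotation, and to both inferred proteins:

```r
library(hgvsr)
p <- fixture_provider(toy_locus())

v <- parse_hgvs("TX1:c.30G>T")
v$posedit$pos$start$base          # 30
format(c_to_g(v, p, aln_method = "splign"))
#> [1] "CTG1:g.150G>T"
format(g_to_c(c_to_g(v, p, aln_method = "splign"), "TX2", p))
#> [1] "TX2:c.41G>T"
format(c_to_p(v, p))
#> [1] "PRO_TX1:p.(=)"
format(c_to_p(liftover(v, "TX2", p), p))
#> [1] "PRO_TX2:p.(Arg14Leu)"
```

Five representations of one event: the source `c.` variant, its genomic
projection, the lifted-over `c.` variant (the `c.` coordinate changes
because TX2's CDS starts earlier), and the two inferred protein variants —
synonymous on TX1's reading frame, a missense `Arg14Leu` on TX2's.

Validation distinguishes intrinsic checks (object-only: interval order, the
insertion location range must have length one, stated ref length vs span)
from extrinsic checks against the provider:

```r
format(validate_variant(parse_hgvs("TX1:c.30A>T"), p))
#> [1] "ERROR ref_mismatch stated reference 'A' differs from the reference sequence 'G'"
format(validate_variant(v, p))
#> [1] "OK"
```

Any grammar rule is invocable on fragments:

```r
parse_rule("c_posedit", "688+403C>T")     # a PosEdit
parse_rule("base_offset_position", "88-2")  # base 88, offset -2
```

A command-line wrapper is installed at `exec/hgvstools` (subcommands
`parse`, `validate`, `map`, `liftover`, `fixture`; one variant per line,
results on stdout, logs on stderr).

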