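# The data-provider interface: seven generics supplying the sequences and
# transcript/alignment metadata that mapping and validation need.  Any object
# implementing these generics can back the mapper and the extrinsic
# validator; the package ships a fixture-backed implementation.

#' Data provider interface
#'
#' Seven generics declare everything the mapper and validator require from a
#' reference-data source:
#' * `get_seq(provider, ac, start, end)` — substring (1-based inclusive) of a
#'   stored sequence, upper-case for DNA; `end = NULL` means the full length.
#' * `get_transcript(provider, tx_ac, ref_ac, aln_method)` — the
#'   [transcript_record()] for a (transcript, reference, alignment-method)
#'   triple; `NULL` selects the only (or lexicographically first) choice.
#' * `find_transcripts(provider, ref_ac, g_start, g_end)` — records whose
#'   exon span overlaps a genomic range, ordered by accession.
#' * `get_transcripts_for_gene(provider, gene)` — records for a gene symbol.
#' * `get_alignment_methods(provider, tx_ac, ref_ac)` — available alignment
#'   method labels for a transcript/reference pair.
#' * `get_protein_accession(provider, tx_ac)` — the protein accession of a
#'   coding transcript.
#' * `get_data_version(provider)` — an identifying string for the data.
#'
#' All lookup failures raise classed conditions
#' (`hgvs_unknown_accession_error`, `hgvs_unknown_transcript_error`,
#' `hgvs_unknown_aln_method_error`, `hgvs_range_error`).
#'
#' @param provider A provider object.
#' @param ac,tx_ac,ref_ac Accession strings.
#' @param start,end 1-based inclusive bounds.
#' @param aln_method Alignment method label or `NULL`.
#' @param g_start,g_end Genomic range (1-based inclusive).
#' @param gene Gene symbol.
#' @name data_provider
NULL

#' @rdname data_provider
#' @export
get_seq <- function(provider, ac, start = 1L, end = NULL) UseMethod("get_seq")

#' @rdname data_provider
#' @export
get_transcript <- function(provider, tx_ac, ref_ac = NULL, aln_method = NULL)
  UseMethod("get_transcript")

#' @rdname data_provider
#' @export
find_transcripts <- function(provider, ref_ac, g_start, g_end)
  UseMethod("find_transcripts")

#' @rdname data_provider
#' @export
get_transcripts_for_gene <- function(provider, gene) UseMethod("get_transcripts_for_gene")

#' @rdname data_provider
#' @export
get_alignment_methods <- function(provider, tx_ac, ref_ac = NULL)
  UseMethod("get_alignment_methods")

#' @rdname data_provider
#' @export
get_protein_accession <- function(provider, tx_ac) UseMethod("get_protein_accession")

#' @rdname data_provider
#' @export
get_data_version <- function(provider) UseMethod("get_data_version")

#' Fixture-backed data provider
#'
#' Wraps a `locus_fixture` (from [generate_locus()], [toy_locus()] or
#' [read_locus()]) as a read-only provider implementing the full
#' [data_provider] interface.  Protein sequences of coding transcripts are
#' derived once by translating the annotated CDS (1-letter codes, terminal
#' `*`).
#'
#' @param fixture A `locus_fixture`, or a directory path understood by
#'   [read_locus()].
#' @return An `hgvs_provider`.
#' @examples
#' p <- fixture_provider(toy_locus())
#' get_seq(p, "CTG1", 1, 10)
#' @export
fixture_provider <- function(fixture) {
  if (is.character(fixture)) fixture <- read_locus(fixture)
  if (!inherits(fixture, "locus_fixture"))
    hgvs_error("fixture must be a locus_fixture or a fixture directory", "hgvs_type_error")
  seqs <- c(stats::setNames(list(fixture$contig_seq), fixture$contig_ac), fixture$tx_seqs)
  prot <- list()
  for (rec in fixture$records) {
    if (rec_is_coding(rec) && !is.na(rec$protein_ac) && is.null(prot[[rec$protein_ac]])) {
      cds <- substr(fixture$tx_seqs[[rec$tx_ac]], rec$cds_start_n, rec$cds_end_n)
      prot[[rec$protein_ac]] <- as.character(
        Biostrings::translate(Biostrings::DNAString(cds)))
    }
  }
  structure(list(fixture = fixture, seqs = c(seqs, prot)),
            class = "hgvs_provider")
}

#' @export
get_seq.hgvs_provider <- function(provider, ac, start = 1L, end = NULL) {
  s <- provider$seqs[[ac]]
  if (is.null(s))
    hgvs_error(sprintf("unknown accession '%s'", ac), "hgvs_unknown_accession_error")
  len <- nchar(s)
  if (is.null(end)) end <- len
  start <- .as_int1(start, "start"); end <- .as_int1(end, "end")
  if (start < 1L || end < start || end > len)
    hgvs_error(sprintf("range %d-%d is invalid for '%s' (length %d)", start, end, ac, len),
               "hgvs_range_error")
  toupper(substr(s, start, end))
}

.records_for_tx <- function(provider, tx_ac) {
  Filter(function(r) r$tx_ac == tx_ac, provider$fixture$records)
}

#' @export
get_transcript.hgvs_provider <- function(provider, tx_ac, ref_ac = NULL, aln_method = NULL) {
  recs <- .records_for_tx(provider, tx_ac)
  if (length(recs) == 0L)
    hgvs_error(sprintf("unknown transcript '%s'", tx_ac), "hgvs_unknown_transcript_error")
  if (!is.null(ref_ac)) {
    recs2 <- Filter(function(r) r$ref_ac == ref_ac, recs)
    if (length(recs2) == 0L)
      hgvs_error(sprintf("transcript '%s' has no alignment to reference '%s'", tx_ac, ref_ac),
                 "hgvs_unknown_transcript_error")
    recs <- recs2
  }
  if (!is.null(aln_method)) {
    recs2 <- Filter(function(r) r$aln_method == aln_method, recs)
    if (length(recs2) == 0L)
      hgvs_error(sprintf("no '%s' alignment of transcript '%s'", aln_method, tx_ac),
                 "hgvs_unknown_aln_method_error")
    recs <- recs2
  }
  ord <- order(vapply(recs, function(r) paste(r$ref_ac, r$aln_method), character(1)))
  recs[[ord[1]]]
}

#' @export
find_transcripts.hgvs_provider <- function(provider, ref_ac, g_start, g_end) {
  if (!(ref_ac %in% vapply(provider$fixture$records, function(r) r$ref_ac, character(1))) &&
      ref_ac != provider$fixture$contig_ac)
    hgvs_error(sprintf("unknown reference '%s'", ref_ac), "hgvs_unknown_accession_error")
  g_start <- .as_int1(g_start, "g_start"); g_end <- .as_int1(g_end, "g_end")
  hits <- Filter(function(r) {
    sp <- rec_g_span(r)
    r$ref_ac == ref_ac && g_start <= sp[2] && g_end >= sp[1]
  }, provider$fixture$records)
  ord <- order(vapply(hits, function(r) paste(r$tx_ac, r$aln_method), character(1)))
  hits[ord]
}

#' @export
get_transcripts_for_gene.hgvs_provider <- function(provider, gene) {
  hits <- Filter(function(r) r$gene == gene, provider$fixture$records)
  ord <- order(vapply(hits, function(r) paste(r$tx_ac, r$aln_method), character(1)))
  hits[ord]
}

#' @export
get_alignment_methods.hgvs_provider <- function(provider, tx_ac, ref_ac = NULL) {
  recs <- .records_for_tx(provider, tx_ac)
  if (length(recs) == 0L)
    hgvs_error(sprintf("unknown transcript '%s'", tx_ac), "hgvs_unknown_transcript_error")
  if (!is.null(ref_ac)) recs <- Filter(function(r) r$ref_ac == ref_ac, recs)
  sort(unique(vapply(recs, function(r) r$aln_method, character(1))))
}

#' @export
get_protein_accession.hgvs_provider <- function(provider, tx_ac) {
  recs <- .records_for_tx(provider, tx_ac)
  if (length(recs) == 0L)
    hgvs_error(sprintf("unknown transcript '%s'", tx_ac), "hgvs_unknown_transcript_error")
  acs <- unique(stats::na.omit(vapply(recs, function(r) r$protein_ac, character(1))))
  if (length(acs) == 0L)
    hgvs_error(sprintf("transcript '%s' has no protein product", tx_ac),
               "hgvs_unknown_accession_error")
  acs[1]
}

#' @export
get_data_version.hgvs_provider <- function(provider) provider$fixture$version
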