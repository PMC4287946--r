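# A fixed demonstration locus used in examples, tests and the end-to-end
# projection workflow.  Layout (all coordinates 1-based on contig CTG1):
#
#   TX1  +  exons 101-200 / 301-400 / 501-600, gapless, CDS n.21-260
#        (also aligned by a second method, "blat", whose first exon boundary
#        sits 2 bases earlier: exons 101-198 / 299-400 / 501-600)
#   TX2  +  same exons as TX1 but a different annotated ORF (CDS n.10-240,
#        a shifted reading frame), so c. coordinates change under liftover
#   TX3  +  non-coding; exon 2 carries a 3-base genome-only (D) discrepancy:
#        exons 101-200 / 301-403 [40M 3D 60M] / 501-600
#   TX4  +  non-coding, single exon 101-200 with a 2-base transcript-only
#        (I) discrepancy: [40M 2I 60M]
#   TX5  -  minus strand, exons 1101-1200 / 1301-1400, CDS n.21-194
#
# The shared TX1/TX2 exon sequence is built with no TA/TG dinucleotide, so
# neither reading frame contains a stop codon anywhere; each transcript's
# stop codon is then patched in at a spot that is harmless in the other
# frame.  This keeps both ORFs clean while they overlap on the genome.

#' Demonstration locus
#'
#' A deterministic synthetic locus with the transcript features the mapper
#' must handle: multiple transcripts sharing a genomic region with different
#' CDS annotations (for liftover), an alternative alignment method with a
#' shifted exon boundary, genome-only (`D`) and transcript-only (`I`)
#' alignment discrepancies, and a minus-strand transcript.
#'
#' @param seed Seed for the (fixed) random sequence fill.
#' @return A `locus_fixture`.
#' @examples
#' fx <- toy_locus()
#' vapply(fx$records, function(r) r$tx_ac, character(1))
#' @export
toy_locus <- function(seed = 42L) {
  .with_seed(seed, .toy_locus_impl(seed))
}

# sequence with no TA or TG dinucleotide => no stop codon in any frame
.no_stop_seq <- function(n) {
  out <- character(n)
  prev <- ""
  for (i in seq_len(n)) {
    pool <- if (prev == "T") c("C", "T") else .DNA
    out[i] <- sample(pool, 1L)
    prev <- out[i]
  }
  out
}

.toy_locus_impl <- function(seed) {
  contig <- sample(.DNA, 1500L, replace = TRUE)

  exo <- c(101:200, 301:400, 501:600)       # TX1/TX2 exonic positions
  spliced <- .no_stop_seq(300L)
  spliced[258:260] <- c("T", "A", "A")      # TX1 stop (frame from n.21)
  spliced[238:240] <- c("T", "A", "A")      # TX2 stop (frame from n.10)
  contig[exo] <- spliced

  ex111 <- list(list(g_start = 101L, g_end = 200L),
                list(g_start = 301L, g_end = 400L),
                list(g_start = 501L, g_end = 600L))
  tx1 <- transcript_record("TX1", "GENE1", "+", "CTG1", ex111,
                           cds_start_n = 21L, cds_end_n = 260L,
                           aln_method = "splign", protein_ac = "PRO_TX1")
  # alternative alignment of TX1: first boundary shifted 2 bases 5'
  contig[299:300] <- contig[199:200]
  tx1b <- transcript_record("TX1", "GENE1", "+", "CTG1",
                            list(list(g_start = 101L, g_end = 198L),
                                 list(g_start = 299L, g_end = 400L),
                                 list(g_start = 501L, g_end = 600L)),
                            cds_start_n = 21L, cds_end_n = 260L,
                            aln_method = "blat", protein_ac = "PRO_TX1")
  tx2 <- transcript_record("TX2", "GENE1", "+", "CTG1", ex111,
                           cds_start_n = 10L, cds_end_n = 240L,
                           aln_method = "splign", protein_ac = "PRO_TX2")
  tx3 <- transcript_record("TX3", "GENE1", "+", "CTG1",
                           list(list(g_start = 101L, g_end = 200L),
                                list(g_start = 301L, g_end = 403L,
                                     segments = list(aln_segment("M", 40L),
                                                     aln_segment("D", 3L),
                                                     aln_segment("M", 60L))),
                                list(g_start = 501L, g_end = 600L)),
                           aln_method = "splign")
  tx4 <- transcript_record("TX4", "GENE1", "+", "CTG1",
                           list(list(g_start = 101L, g_end = 200L,
                                     segments = list(aln_segment("M", 40L),
                                                     aln_segment("I", 2L),
                                                     aln_segment("M", 60L)))),
                           aln_method = "splign")
  tx5 <- transcript_record("TX5", "GENE2", "-", "CTG1",
                           list(list(g_start = 1101L, g_end = 1200L),
                                list(g_start = 1301L, g_end = 1400L)),
                           cds_start_n = 21L, cds_end_n = 194L,
                           aln_method = "splign", protein_ac = "PRO_TX5")
  # clean ORF for TX5 (single frame; generated directly)
  tx5_tmp <- .implied_tx_seq(tx5, paste(contig, collapse = ""), .rand_dna(200L))
  tx5_base <- strsplit(tx5_tmp, "")[[1]]
  tx5_base[21:194] <- strsplit(.rand_orf(57L), "")[[1]]
  contig <- .patch_contig(contig, tx5, tx5_base)

  contig_str <- paste(contig, collapse = "")
  ins2 <- .rand_dna(2L)                      # TX4's transcript-only bases
  tx_seqs <- list(
    TX1 = .implied_tx_seq(tx1, contig_str, ""),
    TX2 = .implied_tx_seq(tx2, contig_str, ""),
    TX3 = .implied_tx_seq(tx3, contig_str, ""),
    TX4 = .implied_tx_seq(tx4, contig_str,
                          paste0(strrep("N", 40L), ins2)),
    TX5 = paste(tx5_base, collapse = "")
  )

  fx <- structure(list(contig_ac = "CTG1", contig_seq = contig_str,
                       tx_seqs = tx_seqs,
                       records = list(tx1, tx1b, tx2, tx3, tx4, tx5),
                       seed = seed,
                       config = list(kind = "toy"),
                       version = sprintf("hgvsr-fixture/1 toy seed=%d", seed)),
                  class = "locus_fixture")
  check_locus_fixture(fx)
  fx
}

# ---------------------------------------------------------------------------
# fixture I/O: FASTA for sequences, JSON for records (all coordinates in the
# files are 1-based inclusive, stated in the document header)

#' Write / read a locus fixture
#'
#' `write_locus()` stores a fixture as plain-text files in `dir`:
#' `contig.fa` and `transcripts.fa` (FASTA) and `records.json` (transcript
#' records plus generation metadata; coordinates are 1-based inclusive).
#' `read_locus()` reads them back into an equivalent `locus_fixture`.
#'
#' @param fixture A `locus_fixture`.
#' @param dir Directory (created if needed).
#' @return `write_locus()` returns `dir` invisibly; `read_locus()` returns a
#'   `locus_fixture`.
#' @export
write_locus <- function(fixture, dir) {
  if (!inherits(fixture, "locus_fixture"))
    hgvs_error("not a locus_fixture", "hgvs_type_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ctg <- Biostrings::DNAStringSet(stats::setNames(fixture$contig_seq, fixture$contig_ac))
  Biostrings::writeXStringSet(ctg, file.path(dir, "contig.fa"))
  txs <- Biostrings::DNAStringSet(unlist(fixture$tx_seqs))
  Biostrings::writeXStringSet(txs, file.path(dir, "transcripts.fa"))
  doc <- list(
    format = "hgvsr locus fixture",
    coordinates = "1-based inclusive",
    version = fixture$version,
    seed = fixture$seed,
    config = fixture$config,
    records = lapply(fixture$records, unclass)
  )
  jsonlite::write_json(doc, file.path(dir, "records.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @rdname write_locus
#' @export
read_locus <- function(dir) {
  ctg <- Biostrings::readDNAStringSet(file.path(dir, "contig.fa"))
  txs <- Biostrings::readDNAStringSet(file.path(dir, "transcripts.fa"))
  doc <- jsonlite::read_json(file.path(dir, "records.json"))
  records <- lapply(doc$records, function(r) {
    transcript_record(
      tx_ac = r$tx_ac, gene = r$gene, strand = r$strand, ref_ac = r$ref_ac,
      exons = lapply(r$exons, function(ex)
        list(g_start = ex$g_start, g_end = ex$g_end,
             segments = ex$segments)),
      cds_start_n = r$cds_start_n %||% NA_integer_,
      cds_end_n = r$cds_end_n %||% NA_integer_,
      aln_method = r$aln_method,
      protein_ac = r$protein_ac %||% NA_character_)
  })
  fx <- structure(list(contig_ac = names(ctg)[1],
                       contig_seq = as.character(ctg[[1]]),
                       tx_seqs = as.list(as.character(txs)),
                       records = records,
                       seed = doc$seed,
                       config = doc$config,
                       version = doc$version),
                  class = "locus_fixture")
  check_locus_fixture(fx)
  fx
}
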