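# Synthetic locus fixtures: a genomic contig, transcripts aligned to it
# (possibly with indel discrepancies), and the metadata the mapper and
# validator need.  These stand in for a transcript archive; no network data
# is involved anywhere in the package.

.DNA <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

.rand_dna <- function(n) paste(sample(.DNA, n, replace = TRUE), collapse = "")

.codons_all <- apply(expand.grid(.DNA, .DNA, .DNA, stringsAsFactors = FALSE),
                     1L, paste, collapse = "")
.codons_sense <- setdiff(.codons_all, .STOPS)

# open reading frame: n_codons sense codons + one stop
.rand_orf <- function(n_codons) {
  paste0(paste(sample(.codons_sense, n_codons, replace = TRUE), collapse = ""),
         sample(.STOPS, 1L))
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.with_seed <- function(seed, code) {
  seed <- .as_int1(seed, "seed")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

aln_segment <- function(op, len) {
  if (!(op %in% c("M", "D", "I"))) hgvs_error("segment op must be M, D or I", "hgvs_value_error")
  len <- .as_int1(len, "len")
  if (len < 1L) hgvs_error("segment lengths must be >= 1", "hgvs_value_error")
  list(op = op, len = len)
}

#' Transcript record
#'
#' The payload of the data provider: a transcript's genomic exon spans (stored
#' in genomic ascending order with a strand flag; transcript-order traversal
#' is computed, never stored), per-exon alignment segments (`M` aligned, `D`
#' genome-only, `I` transcript-only, run-length form), CDS bounds in
#' transcript (`n.`) coordinates (`NA` for non-coding transcripts), the gene
#' symbol and the alignment method label.
#'
#' @param tx_ac,gene,ref_ac,aln_method Identifier strings.
#' @param strand `"+"` or `"-"`.
#' @param exons List of `list(g_start, g_end, segments)`; `segments` defaults
#'   to a single `M` segment spanning the exon.
#' @param cds_start_n,cds_end_n CDS bounds in `n.` coordinates, or `NA`.
#' @param protein_ac Protein accession (`NA` for non-coding transcripts).
#' @return A `transcript_record`.
#' @export
transcript_record <- function(tx_ac, gene, strand, ref_ac, exons,
                              cds_start_n = NA_integer_, cds_end_n = NA_integer_,
                              aln_method = "splign", protein_ac = NA_character_) {
  if (!(strand %in% c("+", "-"))) hgvs_error("strand must be '+' or '-'", "hgvs_value_error")
  exons <- lapply(exons, function(ex) {
    ex$g_start <- .as_int1(ex$g_start, "g_start")
    ex$g_end <- .as_int1(ex$g_end, "g_end")
    if (ex$g_end < ex$g_start) hgvs_error("exon g_end < g_start", "hgvs_value_error")
    if (is.null(ex$segments))
      ex$segments <- list(aln_segment("M", ex$g_end - ex$g_start + 1L))
    ex$segments <- lapply(ex$segments, function(s) aln_segment(s$op, s$len))
    ex
  })
  starts <- vapply(exons, function(e) e$g_start, integer(1))
  ends <- vapply(exons, function(e) e$g_end, integer(1))
  if (is.unsorted(starts, strictly = TRUE) || any(starts[-1] <= ends[-length(ends)]))
    hgvs_error("exons must be non-overlapping and in genomic ascending order", "hgvs_value_error")
  rec <- structure(list(tx_ac = tx_ac, gene = gene, strand = strand,
                        ref_ac = ref_ac, exons = exons,
                        cds_start_n = suppressWarnings(as.integer(cds_start_n)),
                        cds_end_n = suppressWarnings(as.integer(cds_end_n)),
                        aln_method = aln_method, protein_ac = protein_ac),
                   class = "transcript_record")
  .check_record_shape(rec)
  rec
}

.check_record_shape <- function(rec) {
  for (i in seq_along(rec$exons)) {
    ex <- rec$exons[[i]]
    ops <- vapply(ex$segments, `[[`, character(1), "op")
    lens <- vapply(ex$segments, `[[`, integer(1), "len")
    if (any(ops[-1] == ops[-length(ops)]))
      hgvs_error(sprintf("exon %d: adjacent segments share an op (not run-length canonical)", i),
                 "hgvs_record_error")
    g_len <- sum(lens[ops != "I"])
    if (g_len != ex$g_end - ex$g_start + 1L)
      hgvs_error(sprintf("exon %d: genomic segment lengths (%d) do not cover the exon span (%d)",
                         i, g_len, ex$g_end - ex$g_start + 1L),
                 "hgvs_record_error")
  }
  len <- tx_length(rec)
  if (!is.na(rec$cds_start_n)) {
    if (is.na(rec$cds_end_n) || rec$cds_start_n < 1L ||
        rec$cds_start_n >= rec$cds_end_n || rec$cds_end_n > len)
      hgvs_error("CDS bounds must satisfy 1 <= cds_start_n < cds_end_n <= transcript length",
                 "hgvs_record_error")
  }
  invisible(TRUE)
}

#' @rdname transcript_record
#' @param rec A `transcript_record`.
#' @export
tx_length <- function(rec) {
  sum(vapply(rec$exons, function(ex) {
    sum(vapply(ex$segments, function(s) if (s$op == "D") 0L else s$len, integer(1)))
  }, integer(1)))
}

rec_is_coding <- function(rec) !is.na(rec$cds_start_n)

rec_g_span <- function(rec) {
  c(rec$exons[[1]]$g_start, rec$exons[[length(rec$exons)]]$g_end)
}

# exons (and their segments) in transcript 5'->3' order
exons_tx_order <- function(rec) {
  exs <- rec$exons
  if (rec$strand == "-") {
    exs <- rev(exs)
    exs <- lapply(exs, function(ex) { ex$segments <- rev(ex$segments); ex })
  }
  exs
}

# reconstruct the transcript sequence implied by a record, taking
# transcript-only (I) bases from `tx_seq`; errors if aligned bases disagree
.implied_tx_seq <- function(rec, contig_seq, tx_seq) {
  out <- character(0)
  n <- 0L
  for (ex in exons_tx_order(rec)) {
    gcur <- if (rec$strand == "+") ex$g_start else ex$g_end
    for (seg in ex$segments) {
      if (seg$op == "M") {
        gs <- if (rec$strand == "+") substr(contig_seq, gcur, gcur + seg$len - 1L)
              else revcomp(substr(contig_seq, gcur - seg$len + 1L, gcur))
        out <- c(out, gs)
        gcur <- gcur + if (rec$strand == "+") seg$len else -seg$len
        n <- n + seg$len
      } else if (seg$op == "D") {
        gcur <- gcur + if (rec$strand == "+") seg$len else -seg$len
      } else {
        out <- c(out, substr(tx_seq, n + 1L, n + seg$len))
        n <- n + seg$len
      }
    }
  }
  paste(out, collapse = "")
}

#' Check a locus fixture's internal consistency
#'
#' Verifies, for every transcript record, that segment lengths reconcile with
#' the exon spans, that the transcript sequence implied by splicing the
#' genomic exons and applying the alignment segments equals the stored
#' transcript sequence, and that CDS bounds are sane.
#'
#' @param fixture A `locus_fixture`.
#' @return `TRUE` (invisibly); errors describe the first violated invariant.
#' @export
check_locus_fixture <- function(fixture) {
  if (!inherits(fixture, "locus_fixture"))
    hgvs_error("not a locus_fixture", "hgvs_type_error")
  for (rec in fixture$records) {
    .check_record_shape(rec)
    tx <- fixture$tx_seqs[[rec$tx_ac]]
    if (is.null(tx))
      hgvs_error(sprintf("missing transcript sequence for %s", rec$tx_ac), "hgvs_record_error")
    if (tx_length(rec) != nchar(tx))
      hgvs_error(sprintf("%s/%s: segment lengths imply transcript length %d but sequence has %d",
                         rec$tx_ac, rec$aln_method, tx_length(rec), nchar(tx)),
                 "hgvs_record_error")
    imp <- .implied_tx_seq(rec, fixture$contig_seq, tx)
    if (!identical(imp, tx))
      hgvs_error(sprintf("%s/%s: implied transcript sequence differs from stored sequence",
                         rec$tx_ac, rec$aln_method), "hgvs_record_error")
  }
  invisible(TRUE)
}

#' Configuration for the synthetic-locus generator
#'
#' Defaults describe a small multi-exon coding locus: a handful of
#' transcripts, each with a few 80-150 bp exons separated by 60-200 bp
#' introns, CDS starting in a configurable exon, and optional genome-
#' transcript indel discrepancies (`D` = genome-only, `I` = transcript-only
#' segments).  When `alt_aln_method` is set, a second alignment of each
#' transcript is emitted whose first exon boundary is shifted by `alt_shift`
#' bases (with the flanking intron sequence made compatible), emulating the
#' differing exon structures two alignment methods can produce.
#'
#' @param n_transcripts Number of transcripts on the contig.
#' @param exons_per_tx Exons per transcript (>= 1).
#' @param exon_len,intron_len,intergenic Length ranges `c(min, max)`.
#' @param strands Vector of `"+"`/`"-"` recycled over transcripts, or `NULL`
#'   to draw randomly.
#' @param coding Emit CDS annotations (and clean open reading frames).
#' @param cds_start_exon Exon (in transcript order) containing the CDS start.
#' @param indels `list(count =, len = c(min, max), ops = c("D","I"))`:
#'   number of indel discrepancies to scatter per transcript (at most one per
#'   exon, away from exon boundaries).
#' @param aln_method,alt_aln_method,alt_shift Alignment method labels and the
#'   exon-boundary shift between them.
#' @param ref_ac Contig accession.
#' @return A config list for [generate_locus()].
#' @export
locus_config <- function(n_transcripts = 2L, exons_per_tx = 3L,
                         exon_len = c(80L, 150L), intron_len = c(60L, 200L),
                         intergenic = c(150L, 300L), strands = NULL,
                         coding = TRUE, cds_start_exon = 1L,
                         indels = list(count = 0L, len = c(1L, 4L), ops = c("D", "I")),
                         aln_method = "splign", alt_aln_method = NULL,
                         alt_shift = 2L, ref_ac = "CTG1") {
  cfg <- list(n_transcripts = .as_int1(n_transcripts, "n_transcripts"),
              exons_per_tx = .as_int1(exons_per_tx, "exons_per_tx"),
              exon_len = as.integer(exon_len), intron_len = as.integer(intron_len),
              intergenic = as.integer(intergenic), strands = strands,
              coding = isTRUE(coding), cds_start_exon = .as_int1(cds_start_exon, "cds_start_exon"),
              indels = indels, aln_method = aln_method,
              alt_aln_method = alt_aln_method, alt_shift = .as_int1(alt_shift, "alt_shift"),
              ref_ac = ref_ac)
  if (cfg$exons_per_tx < 1L || cfg$n_transcripts < 1L)
    hgvs_error("need at least one transcript with at least one exon", "hgvs_generation_error")
  if (cfg$cds_start_exon > cfg$exons_per_tx)
    hgvs_error("cds_start_exon exceeds the number of exons", "hgvs_generation_error")
  if (cfg$exon_len[1] < 40L)
    hgvs_error("exons shorter than 40 bp leave no room for CDS and indel placement", "hgvs_generation_error")
  if (!is.null(cfg$alt_aln_method) && cfg$exons_per_tx < 2L)
    hgvs_error("an alternative alignment needs at least two exons", "hgvs_generation_error")
  cfg
}

.rint <- function(rng) if (rng[1] >= rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)

#' Generate a synthetic locus fixture
#'
#' Deterministically (for a fixed seed) builds a contig, transcripts aligned
#' to it and their sequences, honouring the configured strand mix, CDS
#' placement, indel discrepancies and optional alternative alignment method.
#' Coding transcripts get a clean open reading frame (no internal stop, a
#' final stop codon) so protein inference is well defined.
#'
#' @param config See [locus_config()].
#' @param seed Integer seed; fixed seed implies byte-identical fixtures.
#' @return A `locus_fixture`: contig sequence, transcript sequences, records,
#'   seed and config.
#' @examples
#' fx <- generate_locus(locus_config(n_transcripts = 1), seed = 42)
#' fx$records[[1]]$tx_ac
#' @export
generate_locus <- function(config = locus_config(), seed) {
  .with_seed(seed, .generate_locus_impl(config, seed))
}

.generate_locus_impl <- function(cfg, seed) {
  contig <- character(0)     # per-base vector, grown transcript by transcript
  records <- list()
  tx_seqs <- list()
  cursor <- .rint(cfg$intergenic)

  for (t in seq_len(cfg$n_transcripts)) {
    tx_ac <- sprintf("TX%d", t)
    gene <- sprintf("GENE%d", t)
    strand <- if (!is.null(cfg$strands)) cfg$strands[((t - 1L) %% length(cfg$strands)) + 1L]
              else sample(c("+", "-"), 1L)

    ex_lens <- vapply(seq_len(cfg$exons_per_tx), function(i) .rint(cfg$exon_len), integer(1))
    in_lens <- if (cfg$exons_per_tx > 1L)
      vapply(seq_len(cfg$exons_per_tx - 1L), function(i) .rint(cfg$intron_len), integer(1))
    else integer(0)

    exons <- list()
    g <- cursor + 1L
    for (i in seq_len(cfg$exons_per_tx)) {
      exons[[i]] <- list(g_start = g, g_end = g + ex_lens[i] - 1L)
      g <- g + ex_lens[i] + if (i < cfg$exons_per_tx) in_lens[i] else 0L
    }
    tx_g_end <- exons[[length(exons)]]$g_end

    # scatter indel discrepancies (at most one per exon, interior only);
    # keep the first two exons gapless when an alternative alignment with a
    # shifted first boundary is requested
    n_ind <- cfg$indels$count %||% 0L
    protected <- if (!is.null(cfg$alt_aln_method)) c(1L, 2L) else integer(0)
    candidates <- setdiff(seq_len(cfg$exons_per_tx), protected)
    if (n_ind > 0L && length(candidates) == 0L)
      hgvs_error("no exon available for indel placement under this config", "hgvs_generation_error")
    ind_exons <- if (n_ind > 0L) {
      pool <- rep(candidates, length.out = max(n_ind, length(candidates)))
      pool[sample.int(length(pool), n_ind)]
    } else integer(0)
    for (xi in unique(ind_exons)) {
      op <- sample(cfg$indels$ops, 1L)
      k <- .rint(cfg$indels$len)
      glen <- ex_lens[xi]
      a <- .rint(c(8L, glen - 8L - if (op == "D") k else 0L))
      if (op == "D") {
        exons[[xi]]$segments <- list(aln_segment("M", a), aln_segment("D", k),
                                     aln_segment("M", glen - a - k))
      } else {
        exons[[xi]]$segments <- list(aln_segment("M", a), aln_segment("I", k),
                                     aln_segment("M", glen - a))
      }
    }

    # grow the contig past this transcript
    need <- tx_g_end + .rint(cfg$intergenic)
    if (need > length(contig))
      contig <- c(contig, sample(.DNA, need - length(contig), replace = TRUE))

    rec <- transcript_record(tx_ac, gene, strand, cfg$ref_ac, exons,
                             aln_method = cfg$aln_method)
    len <- tx_length(rec)

    cds <- c(NA_integer_, NA_integer_)
    if (cfg$coding) {
      # transcript-order span of the exon that must contain the CDS start
      spans <- cumsum(vapply(exons_tx_order(rec), function(ex)
        sum(vapply(ex$segments, function(s) if (s$op == "D") 0L else s$len, integer(1))),
        integer(1)))
      lo <- if (cfg$cds_start_exon == 1L) 2L else spans[cfg$cds_start_exon - 1L] + 1L
      # keep room for >= 3 codons plus a 3' UTR of >= 6 bases
      hi <- min(spans[cfg$cds_start_exon], len - 14L)
      if (hi < lo)
        hgvs_error("transcript too short for a CDS under this config", "hgvs_generation_error")
      cds_start <- .rint(c(lo, hi))
      n_codons <- (len - cds_start + 1L - 6L) %/% 3L
      cds <- c(cds_start, cds_start + 3L * n_codons - 1L)
    }

    # derive the transcript sequence, then overwrite the CDS with a clean ORF
    # and patch the aligned bases back into the contig
    contig_str <- paste(contig, collapse = "")
    tmp_tx <- .implied_tx_seq(rec, contig_str, .rand_dna(len))  # I bases random
    base <- strsplit(tmp_tx, "")[[1]]
    if (cfg$coding) {
      orf <- strsplit(.rand_orf(((cds[2] - cds[1] + 1L) %/% 3L) - 1L), "")[[1]]
      base[cds[1]:cds[2]] <- orf
    }
    tx_seq <- paste(base, collapse = "")
    contig <- .patch_contig(contig, rec, base)

    rec$cds_start_n <- cds[1]; rec$cds_end_n <- cds[2]
    if (cfg$coding) rec$protein_ac <- sprintf("PRO_%s", tx_ac)
    .check_record_shape(rec)
    records[[length(records) + 1L]] <- rec
    tx_seqs[[tx_ac]] <- tx_seq

    # alternative alignment: shift the first exon boundary by alt_shift and
    # make the intron start compatible with the moved exonic bases
    if (!is.null(cfg$alt_aln_method)) {
      k <- cfg$alt_shift
      b <- exons[[1]]$g_end; cc <- exons[[2]]$g_start
      if (cc - b - 1L <= k + 2L)
        hgvs_error("first intron too short for the requested alignment shift", "hgvs_generation_error")
      contig[(cc - k):(cc - 1L)] <- contig[(b - k + 1L):b]
      alt_exons <- exons
      alt_exons[[1]]$g_end <- b - k
      alt_exons[[1]]$segments <- NULL
      alt_exons[[2]]$g_start <- cc - k
      alt_exons[[2]]$segments <- NULL
      alt <- transcript_record(tx_ac, gene, strand, cfg$ref_ac, alt_exons,
                               cds_start_n = cds[1], cds_end_n = cds[2],
                               aln_method = cfg$alt_aln_method,
                               protein_ac = rec$protein_ac)
      records[[length(records) + 1L]] <- alt
    }

    cursor <- need
  }

  fx <- structure(list(contig_ac = cfg$ref_ac,
                       contig_seq = paste(contig, collapse = ""),
                       tx_seqs = tx_seqs, records = records,
                       seed = seed, config = cfg,
                       version = sprintf("hgvsr-fixture/1 seed=%d", seed)),
                  class = "locus_fixture")
  check_locus_fixture(fx)
  fx
}

# write the transcript's aligned (M) bases back into the contig vector
.patch_contig <- function(contig, rec, tx_base) {
  n <- 0L
  for (ex in exons_tx_order(rec)) {
    gcur <- if (rec$strand == "+") ex$g_start else ex$g_end
    step <- if (rec$strand == "+") 1L else -1L
    for (seg in ex$segments) {
      if (seg$op == "M") {
        for (j in seq_len(seg$len)) {
          b <- tx_base[n + j]
          contig[gcur] <- if (rec$strand == "+") b else chartr("ACGT", "TGCA", b)
          gcur <- gcur + step
        }
        n <- n + seg$len
      } else if (seg$op == "D") {
        gcur <- gcur + step * seg$len
      } else {
        n <- n + seg$len
      }
    }
  }
  contig
}
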