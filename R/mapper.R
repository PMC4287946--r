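# Variant-level projections.  Positions go through the alignment map; edit
# sequences are reverse-complemented (and interval endpoints swapped) for
# minus-strand transcripts; clamps inside alignment discrepancies and edits
# spanning a splice boundary are surfaced as warnings, never silent.

.comp_base <- function(s) chartr("ACGT", "TGCA", s)

.edit_revcomp <- function(e) {
  k <- edit_kind(e)
  rc <- function(s) if (is.null(s)) NULL else revcomp(s)
  switch(k,
         sub = edit_sub(.comp_base(e$ref), .comp_base(e$alt)),
         del = edit_del(rc(e$ref)),
         ins = edit_ins(rc(e$alt)),
         delins = edit_delins(rc(e$ref), rc(e$alt)),
         dup = edit_dup(rc(e$ref)),
         identity = edit_identity(rc(e$ref)),
         "repeat" = edit_repeat(rc(e$unit), e$min, e$max),
         hgvs_error(sprintf("cannot reverse-complement a '%s' edit", k), "hgvs_type_error"))
}

.hgvs_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "hgvs_warning", "warning", "condition")))
}

.warn_gap <- function(m1, m2, what) {
  if (isTRUE(m1$gap) || isTRUE(m2$gap))
    .hgvs_warn(sprintf("%s: a position fell inside a genome-transcript alignment discrepancy and was clamped", what),
               "hgvs_gap_warning")
}

.warn_splice <- function(np1, np2, gs, ge, what) {
  ex1 <- np1$offset == 0L; ex2 <- np2$offset == 0L
  if (ex1 != ex2)
    .hgvs_warn(sprintf("%s: edit spans an exon/intron boundary; endpoints mapped positionally", what),
               "hgvs_splice_warning")
  else if (ex1 && ex2 && (ge - gs) != abs(np2$base - np1$base))
    .hgvs_warn(sprintf("%s: edit spans an alignment discontinuity; endpoints mapped positionally", what),
               "hgvs_splice_warning")
}

#' Project a transcript variant onto its genomic reference
#'
#' Maps a `c.` (or `n.`) variant to a `g.` variant through the transcript's
#' genome alignment.  Intronic offsets are resolved through the intron
#' arithmetic of [g_to_n()]; on minus-strand transcripts the interval
#' endpoints are swapped and the edit's sequences reverse-complemented.
#' Positions clamped inside alignment discrepancies and edits spanning a
#' splice boundary raise warnings (`hgvs_gap_warning`,
#' `hgvs_splice_warning`).
#'
#' @param v A `c.` or `n.` [sequence_variant()].
#' @param provider A [data_provider] implementation.
#' @param ref_ac Genomic reference accession (`NULL`: the transcript's only
#'   reference).
#' @param aln_method Alignment method label (`NULL`: the only / first).
#' @return A `g.` [sequence_variant()].
#' @examples
#' p <- fixture_provider(toy_locus())
#' v <- parse_hgvs(paste0("TX1:c.30", get_seq(p, "TX1", 50, 50), ">T"))
#' c_to_g(v, p)
#' @export
c_to_g <- function(v, provider, ref_ac = NULL, aln_method = NULL) {
  if (!inherits(v, "sequence_variant") || !(v$type %in% c("c", "n")))
    hgvs_error("c_to_g expects a c. or n. variant", "hgvs_type_error")
  rec <- get_transcript(provider, v$ac, ref_ac, aln_method)
  map <- build_alignment_map(rec)
  pe <- v$posedit
  np1 <- if (v$type == "c") c_to_n(rec, pe$pos$start) else pe$pos$start
  np2 <- if (v$type == "c") c_to_n(rec, pe$pos$end) else pe$pos$end
  m1 <- .n_to_g1(map, np1$base, np1$offset)
  m2 <- .n_to_g1(map, np2$base, np2$offset)
  if (rec$strand == "+") { gs <- m1$g; ge <- m2$g; e <- pe$edit }
  else { gs <- m2$g; ge <- m1$g; e <- .edit_revcomp(pe$edit) }
  .warn_gap(m1, m2, format(v))
  .warn_splice(np1, np2, gs, ge, format(v))
  iv <- hgvs_interval(simple_position(gs), simple_position(ge), validate = FALSE)
  sequence_variant(rec$ref_ac, "g", posedit(iv, e), validate = FALSE)
}

#' Project a genomic variant onto a transcript
#'
#' Maps a `g.` (or `m.`) variant onto a transcript aligned to the same
#' reference: exonic positions map exactly, intronic positions become
#' base-offset coordinates, and positions inside genome-only discrepancies
#' are clamped with a warning.  Coding transcripts yield a `c.` variant;
#' non-coding transcripts a `n.` variant.
#'
#' @param v A `g.`/`m.` [sequence_variant()] on the transcript's reference.
#' @param tx_ac Target transcript accession.
#' @inheritParams c_to_g
#' @return A `c.` (or `n.`) [sequence_variant()].
#' @export
g_to_c <- function(v, tx_ac, provider, aln_method = NULL) {
  if (!inherits(v, "sequence_variant") || !(v$type %in% c("g", "m")))
    hgvs_error("g_to_c expects a g. or m. variant", "hgvs_type_error")
  rec <- get_transcript(provider, tx_ac, ref_ac = v$ac, aln_method = aln_method)
  map <- build_alignment_map(rec)
  pe <- v$posedit
  r1 <- .g_to_n1(map, pe$pos$start$base)
  r2 <- .g_to_n1(map, pe$pos$end$base)
  if (rec$strand == "+") { t1 <- r1; t2 <- r2; e <- pe$edit }
  else { t1 <- r2; t2 <- r1; e <- .edit_revcomp(pe$edit) }
  n1 <- base_offset_position(t1$base, t1$offset, "seq_start")
  n2 <- base_offset_position(t2$base, t2$offset, "seq_start")
  .warn_gap(r1, r2, format(v))
  .warn_splice(t1, t2, pe$pos$start$base, pe$pos$end$base, format(v))
  if (rec_is_coding(rec)) {
    iv <- hgvs_interval(n_to_c(rec, n1), n_to_c(rec, n2), validate = FALSE)
    sequence_variant(tx_ac, "c", posedit(iv, e), validate = FALSE)
  } else {
    iv <- hgvs_interval(n1, n2, validate = FALSE)
    sequence_variant(tx_ac, "n", posedit(iv, e), validate = FALSE)
  }
}

#' Lift a transcript variant over to another transcript
#'
#' Re-expresses a `c.`/`n.` variant on a different transcript (or a different
#' alignment of the same transcript) by composing [c_to_g()] under the source
#' alignment with [g_to_c()] under the target alignment.  Both transcripts
#' must align to the same genomic reference.
#'
#' @param v The source `c.`/`n.` [sequence_variant()].
#' @param to_tx Target transcript accession.
#' @param provider A [data_provider] implementation.
#' @param from_aln,to_aln Alignment method labels for source and target
#'   (`NULL`: the only / first available).
#' @param ref_ac Shared genomic reference (`NULL`: resolved from the source).
#' @return A `c.` (or `n.`) [sequence_variant()] on `to_tx`.
#' @examples
#' p <- fixture_provider(toy_locus())
#' v <- parse_hgvs(paste0("TX1:c.30", get_seq(p, "TX1", 50, 50), ">T"))
#' liftover(v, "TX2", p)
#' @export
liftover <- function(v, to_tx, provider, from_aln = NULL, to_aln = NULL, ref_ac = NULL) {
  gv <- c_to_g(v, provider, ref_ac, from_aln)
  tryCatch(
    g_to_c(gv, to_tx, provider, aln_method = to_aln),
    hgvs_unknown_transcript_error = function(e)
      hgvs_error(sprintf("liftover failed: transcript '%s' shares no genomic reference '%s' with '%s'",
                         to_tx, gv$ac, v$ac), "hgvs_liftover_error"))
}

#' Project a variant to another coordinate system
#'
#' Convenience dispatcher over [c_to_g()], [g_to_c()], [c_to_p()],
#' [n_to_c()]/[c_to_n()] and [to_rna_variant()].
#'
#' @param v A [sequence_variant()].
#' @param to Target system: one of `"g"`, `"c"`, `"n"`, `"p"`, `"r"`.
#' @param provider A [data_provider] implementation (not needed for pure
#'   `c.`/`n.` arithmetic when `rec` is supplied).
#' @param tx_ac Target transcript for `g. -> c./n.` projections.
#' @param aln_method Alignment method label or `NULL`.
#' @return A [sequence_variant()] in the target system.
#' @export
map_variant <- function(v, to, provider = NULL, tx_ac = NULL, aln_method = NULL) {
  if (!inherits(v, "sequence_variant"))
    hgvs_error("map_variant expects a sequence_variant", "hgvs_type_error")
  if (v$type == to) return(v)
  if (to == "r") return(to_rna_variant(v))
  if (to == "g") {
    if (v$type %in% c("c", "n")) return(c_to_g(v, provider, aln_method = aln_method))
    hgvs_error(sprintf("cannot project %s. to g.", v$type), "hgvs_unsupported_error")
  }
  if (to == "p") {
    if (v$type == "c") return(c_to_p(v, provider, aln_method = aln_method))
    if (v$type %in% c("g", "m")) {
      if (is.null(tx_ac)) hgvs_error("g. -> p. needs a target transcript", "hgvs_value_error")
      return(c_to_p(g_to_c(v, tx_ac, provider, aln_method), provider, aln_method = aln_method))
    }
    hgvs_error(sprintf("cannot project %s. to p.", v$type), "hgvs_unsupported_error")
  }
  if (to %in% c("c", "n")) {
    if (v$type %in% c("g", "m")) {
      if (is.null(tx_ac)) hgvs_error("g. -> c./n. needs a target transcript", "hgvs_value_error")
      out <- g_to_c(v, tx_ac, provider, aln_method)
      if (out$type != to)
        hgvs_error(sprintf("transcript '%s' yields %s. coordinates, not %s.", tx_ac, out$type, to),
                   "hgvs_unsupported_error")
      return(out)
    }
    if (v$type %in% c("c", "n")) {
      rec <- get_transcript(provider, v$ac, aln_method = aln_method)
      conv <- if (to == "c") function(p) n_to_c(rec, p) else function(p) c_to_n(rec, p)
      pe <- v$posedit
      iv <- hgvs_interval(conv(pe$pos$start), conv(pe$pos$end), validate = FALSE)
      return(sequence_variant(v$ac, to, posedit(iv, pe$edit), validate = FALSE))
    }
  }
  hgvs_error(sprintf("unsupported projection %s. -> %s.", v$type, to), "hgvs_unsupported_error")
}
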