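# Protein consequence inference: apply the CDS edit, translate reference and
# edited sequences with the standard nuclear code, and describe the
# difference.  Frameshift translation continues past the annotated CDS into
# the 3' UTR until a stop codon (or the end of the transcript).

# translate a DNA string with the standard nuclear code; returns a character
# vector of 1-letter codes truncated at (and including) the first stop
.translate_aa <- function(dna) {
  n_codon <- nchar(dna) %/% 3L
  if (n_codon == 0L) return(character(0))
  starts <- 3L * (seq_len(n_codon) - 1L) + 1L
  codons <- substring(dna, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  st <- match("*", aa)
  if (!is.na(st)) aa[seq_len(st)] else aa
}

.aa3_of <- function(one) if (one == "*") "Ter" else aa_to3(one)

# apply a nucleotide edit at CDS-relative 1-based coordinates [c1, c2] of
# `seq`; returns the edited string and the length change
.apply_edit_seq <- function(seq, c1, c2, edit) {
  k <- edit_kind(edit)
  left <- substr(seq, 1L, c1 - 1L)
  mid <- substr(seq, c1, c2)
  right <- substr(seq, c2 + 1L, nchar(seq))
  switch(k,
    sub = list(seq = paste0(left, edit$alt, right), dlen = 0L),
    identity = list(seq = seq, dlen = 0L),
    del = list(seq = paste0(left, right), dlen = -(c2 - c1 + 1L)),
    ins = list(seq = paste0(substr(seq, 1L, c1), edit$alt, substr(seq, c1 + 1L, nchar(seq))),
               dlen = nchar(edit$alt)),
    delins = list(seq = paste0(left, edit$alt, right),
                  dlen = nchar(edit$alt) - (c2 - c1 + 1L)),
    dup = list(seq = paste0(left, mid, mid, right), dlen = c2 - c1 + 1L),
    hgvs_error(sprintf("protein inference is not defined for '%s' edits", k),
               "hgvs_unsupported_error"))
}

#' Infer the protein consequence of a CDS variant
#'
#' Projects an exonic CDS variant to a predicted protein variant: the edit is
#' applied to the coding sequence, both reference and edited sequences are
#' translated with the standard nuclear code, and the difference is
#' classified.  Outcomes: `p.(=)` when the protein is unchanged; a
#' substitution for a single changed residue (to `Ter` for a nonsense
#' change); an in-frame deletion / insertion / delins for length-preserving
#' differences (mod 3); and a frameshift at the first changed residue for
#' other length changes, with the stop position in the new reading frame
#' (scanning through the 3' UTR; `Ter` position omitted if no stop is reached
#' before the transcript ends).
#'
#' Intronic or UTR positions are not projectable to protein coordinates and
#' raise an `hgvs_unsupported_error` (describe such variants at the `g.` or
#' `n.` level); a CDS whose length is not a multiple of 3 raises an
#' `hgvs_data_error`.
#'
#' @param v An exonic `c.` [sequence_variant()] (all offsets 0, positions
#'   within the CDS).
#' @param provider A [data_provider] implementation.
#' @param aln_method Alignment method label or `NULL`.
#' @return A `p.` [sequence_variant()] with `inferred = TRUE` (formatted with
#'   parentheses).
#' @examples
#' p <- fixture_provider(toy_locus())
#' v <- parse_hgvs(paste0("TX1:c.30", get_seq(p, "TX1", 50, 50), ">T"))
#' c_to_p(v, p)
#' @export
c_to_p <- function(v, provider, aln_method = NULL) {
  if (!inherits(v, "sequence_variant") || v$type != "c")
    hgvs_error("c_to_p expects a c. variant", "hgvs_type_error")
  rec <- get_transcript(provider, v$ac, aln_method = aln_method)
  if (!rec_is_coding(rec))
    hgvs_error(sprintf("%s is non-coding", v$ac), "hgvs_unsupported_error")
  s <- rec$cds_start_n; e <- rec$cds_end_n
  cds_len <- e - s + 1L
  if (cds_len %% 3L != 0L)
    hgvs_error(sprintf("CDS of %s has length %d, not a multiple of 3", v$ac, cds_len),
               "hgvs_data_error")
  p1 <- v$posedit$pos$start; p2 <- v$posedit$pos$end
  if (p1$offset != 0L || p2$offset != 0L || p1$datum != "cds_start" ||
      p2$datum != "cds_start" || p1$base < 1L || p2$base > cds_len)
    hgvs_error("only exonic CDS positions project to protein coordinates; describe intronic/UTR variants at the g. or n. level",
               "hgvs_unsupported_error")

  tx <- get_seq(provider, v$ac)
  cds_plus_utr <- substr(tx, s, nchar(tx))
  edited <- .apply_edit_seq(cds_plus_utr, p1$base, p2$base, v$posedit$edit)

  ref_aa <- .translate_aa(substr(tx, s, e))
  p_ac <- tryCatch(get_protein_accession(provider, v$ac),
                   hgvs_error = function(err) paste0(v$ac, "_prot"))

  pe <- if (edited$dlen %% 3L == 0L) {
    alt_aa <- .translate_aa(substr(edited$seq, 1L, cds_len + edited$dlen))
    .diff_inframe(ref_aa, alt_aa)
  } else {
    alt_aa <- .translate_aa(edited$seq)
    .diff_frameshift(ref_aa, alt_aa)
  }
  sequence_variant(p_ac, "p", pe)
}

.aa_iv <- function(ref_aa, i, j = i) {
  hgvs_interval(aa_position(i, .aa3_of(ref_aa[i])),
                aa_position(j, .aa3_of(ref_aa[j])), validate = FALSE)
}

.diff_inframe <- function(A, B) {
  if (identical(A, B)) return(posedit(NULL, edit_aa_identity(), inferred = TRUE))
  la <- length(A); lb <- length(B)
  # a change whose first affected residue is a new stop is a nonsense
  # substitution (p.(Xxx123Ter)), regardless of what follows
  i <- 1L
  while (i <= min(la, lb) && A[i] == B[i]) i <- i + 1L
  if (i <= min(la, lb) && B[i] == "*")
    return(posedit(.aa_iv(A, i), edit_aa_sub("Ter"), inferred = TRUE))
  if (la == lb) {
    d <- which(A != B)
    if (length(d) == 1L)
      return(posedit(.aa_iv(A, d), edit_aa_sub(.aa3_of(B[d])), inferred = TRUE))
  }
  # common prefix / suffix; the middle is the replaced block
  p <- 0L
  while (p < min(la, lb) && A[p + 1L] == B[p + 1L]) p <- p + 1L
  smax <- min(la, lb) - p
  s0 <- 0L
  while (s0 < smax && A[la - s0] == B[lb - s0]) s0 <- s0 + 1L
  # a pure insertion at either terminus has no flanking residue pair; widen
  # the replaced block to include the boundary residue (delins form)
  if (p + 1L > la - s0 && p == 0L) s0 <- s0 - 1L
  if (p + 1L > la - s0 && p >= la) p <- p - 1L
  ref_idx <- if (p + 1L <= la - s0) (p + 1L):(la - s0) else integer(0)
  alt_res <- if (p + 1L <= lb - s0) B[(p + 1L):(lb - s0)] else character(0)
  if (length(ref_idx) == 0L) {
    # pure insertion between residues p and p+1
    iv <- hgvs_interval(aa_position(p, .aa3_of(A[p])),
                        aa_position(p + 1L, .aa3_of(A[p + 1L])), validate = FALSE)
    return(posedit(iv, edit_aa_delins(vapply(alt_res, .aa3_of, character(1), USE.NAMES = FALSE),
                                      ins_only = TRUE), inferred = TRUE))
  }
  iv <- .aa_iv(A, ref_idx[1], ref_idx[length(ref_idx)])
  if (length(alt_res) == 0L)
    posedit(iv, edit_aa_delins(NULL), inferred = TRUE)
  else
    posedit(iv, edit_aa_delins(vapply(alt_res, .aa3_of, character(1), USE.NAMES = FALSE)),
            inferred = TRUE)
}

.diff_frameshift <- function(A, B) {
  la <- length(A); lb <- length(B)
  i <- 1L
  while (i <= min(la, lb) && A[i] == B[i]) i <- i + 1L
  if (i > la && i > lb)   # frame shifted but the translated product is unchanged
    return(posedit(NULL, edit_aa_identity(), inferred = TRUE))
  if (i > la) i <- la     # degenerate: change only past the reference stop
  if (i <= lb && B[i] == "*")
    return(posedit(.aa_iv(A, i), edit_aa_sub("Ter"), inferred = TRUE))
  alt <- if (i <= lb) .aa3_of(B[i]) else NULL
  st <- if (i <= lb) match("*", B[i:lb]) else NA_integer_
  posedit(.aa_iv(A, i), edit_aa_fs(alt, if (is.na(st)) NA_integer_ else st),
          inferred = TRUE)
}
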