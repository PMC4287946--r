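# Validation is split for performance and dependency reasons: intrinsic
# checks need only the object itself; extrinsic checks consult a data
# provider.  Findings are collected into a report, never raised.

.finding <- function(code, message, span = NA_character_) {
  list(code = code, message = message, span = span)
}

.report <- function(findings) {
  structure(list(level = if (length(findings)) "error" else "ok",
                 findings = findings),
            class = "validation_report")
}

#' @export
format.validation_report <- function(x, ...) {
  if (x$level == "ok") return("OK")
  vapply(x$findings, function(f) sprintf("ERROR %s %s", f$code, f$message), character(1))
}

#' @export
print.validation_report <- function(x, ...) {
  writeLines(format(x))
  invisible(x)
}

#' @rdname validate_intrinsic
#' @export
report_ok <- function(report) inherits(report, "validation_report") && report$level == "ok"

# span of an interval in bases, when it is well defined without reference
# data: both endpoints exonic (offset 0) -> base span; same anchor base ->
# offset span; otherwise NA
.interval_span <- function(iv) {
  s <- iv$start; e <- iv$end
  if (inherits(s, "simple_position")) return(e$base - s$base + 1L)
  if (inherits(s, "aa_position")) return(e$base - s$base + 1L)
  if (s$datum == e$datum && s$offset == 0L && e$offset == 0L) {
    sp <- e$base - s$base + 1L
    # CDS-relative coordinates skip 0: -1 and 1 are adjacent
    if (s$datum == "cds_start" && s$base < 0L && e$base > 0L) sp <- sp - 1L
    return(sp)
  }
  if (s$datum == e$datum && s$base == e$base) return(e$offset - s$offset + 1L)
  NA_integer_
}

# insertion sites must be two adjacent positions (flanking-base semantics);
# an exonic/intronic pair like 688 and 688+1 is adjacent
.ins_adjacent <- function(iv) {
  s <- iv$start; e <- iv$end
  if (inherits(s, "base_offset_position")) {
    if (s$datum != e$datum) return(NA)          # not decidable without reference
    db <- e$base - s$base
    if (s$datum == "cds_start" && s$base == -1L && e$base == 1L) db <- 1L
    (db == 1L && s$offset == 0L && e$offset == 0L) ||
      (db == 0L && e$offset - s$offset == 1L)
  } else {
    e$base - s$base == 1L
  }
}

#' Validate a variant
#'
#' `validate_intrinsic()` checks internal correctness of the object alone:
#' the interval start must not exceed its end; an insertion's location range
#' must have length one (two adjacent flanking positions); an explicitly
#' stated ref sequence must match the interval span for substitutions,
#' deletions, delins, duplications and identity assertions; and edit
#' sequences must be drawn from the sequence type's alphabet.
#'
#' `validate_extrinsic()` checks the variant against reference data: the
#' accession must be known to the provider, positions must lie within the
#' sequence, and stated ref bases (or the reference residue of a protein
#' substitution) must match the provider's sequence.  Intronic `c.`/`n.`
#' positions are checked after projection to genomic coordinates through the
#' transcript's alignment.  Provider lookup failures become findings, not
#' errors.
#'
#' `validate_variant()` runs both, skipping the extrinsic stage when
#' intrinsic validation already failed (documented short-circuit) or when no
#' provider is given.
#'
#' @param v A [sequence_variant()].
#' @param provider A [data_provider] implementation.
#' @param aln_method Alignment method for intronic projection (`NULL`: the
#'   only / first available).
#' @param report A `validation_report`.
#' @return A `validation_report`: `level` (`"ok"`/`"error"`) and a list of
#'   findings `(code, message, span)`.  `report_ok()` is a convenience
#'   predicate.
#' @examples
#' validate_intrinsic(parse_hgvs("X:g.10_10insA"))  # insertion span error
#' @export
validate_intrinsic <- function(v) {
  if (!inherits(v, "sequence_variant"))
    hgvs_error("validate_intrinsic expects a sequence_variant", "hgvs_type_error")
  f <- list()
  pe <- v$posedit
  cat_ <- variant_category(v)
  iv <- pe$pos

  if (!is.null(iv)) {
    ord <- tryCatch(position_order(iv$start, iv$end), hgvs_error = function(e) NA_integer_)
    if (is.na(ord)) {
      f[[length(f) + 1L]] <- .finding("incomparable_positions",
                                      "interval bounds are not comparable", format(iv))
    } else if (ord > 0L) {
      f[[length(f) + 1L]] <- .finding("start_gt_end",
                                      "interval start is greater than its end", format(iv))
    }
  }

  if (cat_ %in% c("ins") || (cat_ == "aa_delins" && isTRUE(pe$edit$ins_only))) {
    adj <- if (!is.null(iv) && (is.na(ord) || ord <= 0L)) .ins_adjacent(iv) else FALSE
    if (!isTRUE(adj) && !is.na(adj))
      f[[length(f) + 1L]] <- .finding("ins_span",
                                      "the location range of an insertion must have length one (two adjacent flanking positions)",
                                      format(iv))
  }

  if (cat_ %in% c("sub", "del", "delins", "dup", "identity") && !is.null(pe$edit$ref)) {
    sp <- .interval_span(iv)
    if (!is.na(sp) && nchar(pe$edit$ref) != sp)
      f[[length(f) + 1L]] <- .finding("ref_length",
                                      sprintf("stated ref has %d base(s) but the interval spans %d",
                                              nchar(pe$edit$ref), sp), format(iv))
  }
  if (cat_ == "sub" && !is.null(iv) && !interval_is_point(iv))
    f[[length(f) + 1L]] <- .finding("sub_span",
                                    "a substitution replaces a single base", format(iv))

  if (!(v$type == "p")) {
    alpha <- .type_alphabet(v$type)
    for (s in edit_seq_strings(pe$edit))
      if (!.alphabet_ok(s, alpha))
        f[[length(f) + 1L]] <- .finding("alphabet",
                                        sprintf("edit sequence '%s' is not in the %s. alphabet", s, v$type))
  }
  .report(f)
}

# expected reference bases at a c./n. interval, in transcript orientation;
# exonic endpoints read the transcript sequence, intronic endpoints force a
# genomic projection
.expected_tx_ref <- function(v, provider, aln_method) {
  pe <- v$posedit
  rec <- get_transcript(provider, v$ac, aln_method = aln_method)
  n1 <- if (v$type == "c") c_to_n(rec, pe$pos$start) else pe$pos$start
  n2 <- if (v$type == "c") c_to_n(rec, pe$pos$end) else pe$pos$end
  len <- tx_length(rec)
  if (n1$base < 1L || n2$base > len)
    hgvs_error(sprintf("position exceeds the bounds of %s (length %d)", v$ac, len),
               "hgvs_range_error")
  if (n1$offset == 0L && n2$offset == 0L)
    return(get_seq(provider, v$ac, n1$base, n2$base))
  map <- build_alignment_map(rec)
  m1 <- .n_to_g1(map, n1$base, n1$offset)
  m2 <- .n_to_g1(map, n2$base, n2$offset)
  gs <- min(m1$g, m2$g); ge <- max(m1$g, m2$g)
  seq <- get_seq(provider, rec$ref_ac, gs, ge)
  if (rec$strand == "-") revcomp(seq) else seq
}

#' @rdname validate_intrinsic
#' @export
validate_extrinsic <- function(v, provider, aln_method = NULL) {
  if (!inherits(v, "sequence_variant"))
    hgvs_error("validate_extrinsic expects a sequence_variant", "hgvs_type_error")
  f <- list()
  pe <- v$posedit
  add <- function(code, msg) f[[length(f) + 1L]] <<- .finding(code, msg, format(v))

  expected <- tryCatch({
    if (v$type %in% c("g", "m")) {
      get_seq(provider, v$ac, pe$pos$start$base, pe$pos$end$base)
    } else if (v$type %in% c("c", "n")) {
      .expected_tx_ref(v, provider, aln_method)
    } else if (v$type == "p") {
      if (is.null(pe$pos)) "" else {
        aa <- get_seq(provider, v$ac, pe$pos$start$base, pe$pos$start$base)
        .aa3_of(aa)
      }
    } else {
      hgvs_error("r. variants are validated via their c./n. source", "hgvs_unsupported_error")
    }
  },
  hgvs_unknown_accession_error = function(e) { add("unknown_accession", conditionMessage(e)); NULL },
  hgvs_unknown_transcript_error = function(e) { add("unknown_accession", conditionMessage(e)); NULL },
  hgvs_unknown_aln_method_error = function(e) { add("unknown_aln_method", conditionMessage(e)); NULL },
  hgvs_range_error = function(e) { add("out_of_bounds", conditionMessage(e)); NULL },
  hgvs_error = function(e) { add("provider_error", conditionMessage(e)); NULL })

  if (!is.null(expected)) {
    if (v$type == "p") {
      ref_aa <- pe$pos$start$aa
      if (nzchar(expected) && expected != ref_aa)
        add("ref_aa_mismatch",
            sprintf("stated reference residue %s differs from translated %s at position %d",
                    ref_aa, expected, pe$pos$start$base))
    } else {
      stated <- switch(variant_category(v),
                       sub = , del = , delins = , dup = , identity = pe$edit$ref,
                       NULL)
      if (!is.null(stated) && !identical(toupper(stated), expected))
        add("ref_mismatch",
            sprintf("stated reference '%s' differs from the reference sequence '%s'",
                    stated, expected))
    }
  }
  .report(f)
}

#' @rdname validate_intrinsic
#' @export
validate_variant <- function(v, provider = NULL, aln_method = NULL) {
  rep1 <- validate_intrinsic(v)
  if (rep1$level == "error" || is.null(provider)) return(rep1)
  validate_extrinsic(v, provider, aln_method)
}
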