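# Canonical HGVS rendering.  format() is pure: equal objects give identical
# bytes, and every output re-parses to an equal object (the round-trip
# contract shared with the parser).

#' Render model objects as HGVS text
#'
#' S3 `format()` methods turn any model object — a full [sequence_variant()],
#' a [posedit()], an interval, a position or an edit — into its canonical
#' HGVS spelling.  Canonical means: a point interval renders as a single
#' position (`688+403`, never `688+403_688+403`), inferred protein edits are
#' wrapped in parentheses, and amino acids use 3-letter codes unless
#' `aa_format = "one"`.
#'
#' @param x A model object.
#' @param aa_format `"three"` (default) or `"one"` letter amino-acid codes.
#' @param ... Unused.
#' @return A single character string.
#' @examples
#' format(parse_hgvs("NM_182763.2:c.688+403C>T"))
#' @name format_hgvs
NULL

.fmt_aa <- function(aa3, aa_format) {
  if (aa_format == "one") aa_to1(aa3) else aa3
}

#' @rdname format_hgvs
#' @export
format.simple_position <- function(x, ...) as.character(x$base)

#' @rdname format_hgvs
#' @export
format.base_offset_position <- function(x, ...) {
  base <- if (x$datum == "cds_end") paste0("*", x$base) else as.character(x$base)
  off <- if (x$offset > 0L) paste0("+", x$offset)
         else if (x$offset < 0L) as.character(x$offset)
         else ""
  paste0(base, off)
}

#' @rdname format_hgvs
#' @export
format.aa_position <- function(x, aa_format = c("three", "one"), ...) {
  aa_format <- match.arg(aa_format)
  paste0(.fmt_aa(x$aa, aa_format), x$base)
}

#' @rdname format_hgvs
#' @export
format.hgvs_interval <- function(x, aa_format = c("three", "one"), ...) {
  aa_format <- match.arg(aa_format)
  if (interval_is_point(x)) format(x$start, aa_format = aa_format)
  else paste0(format(x$start, aa_format = aa_format), "_",
              format(x$end, aa_format = aa_format))
}

#' @rdname format_hgvs
#' @export
format.hgvs_edit <- function(x, aa_format = c("three", "one"), ...) {
  aa_format <- match.arg(aa_format)
  k <- edit_kind(x)
  aa <- function(v) paste(vapply(v, .fmt_aa, character(1), aa_format = aa_format),
                          collapse = "")
  switch(k,
         sub = paste0(x$ref, ">", x$alt),
         del = paste0("del", x$ref %||% ""),
         ins = paste0("ins", x$alt),
         delins = paste0("del", x$ref %||% "", "ins", x$alt),
         dup = paste0("dup", x$ref %||% ""),
         identity = paste0(x$ref %||% "", "="),
         "repeat" = paste0(x$unit, "[", x$min,
                           if (x$min != x$max) paste0("_", x$max), "]"),
         aa_sub = aa(x$alt),
         aa_delins = if (x$ins_only) paste0("ins", aa(x$alt))
                     else if (is.null(x$alt)) "del"
                     else paste0("delins", aa(x$alt)),
         aa_fs = paste0(if (!is.null(x$alt)) aa(x$alt), "fs",
                        if (!is.na(x$terminus))
                          paste0(.fmt_aa("Ter", aa_format), x$terminus)),
         aa_identity = "=",
         hgvs_error(sprintf("cannot format edit kind '%s'", k), "hgvs_type_error"))
}

#' @rdname format_hgvs
#' @export
format.hgvs_posedit <- function(x, aa_format = c("three", "one"), ...) {
  aa_format <- match.arg(aa_format)
  body <- paste0(if (!is.null(x$pos)) format(x$pos, aa_format = aa_format),
                 format(x$edit, aa_format = aa_format))
  if (x$inferred) paste0("(", body, ")") else body
}

#' @rdname format_hgvs
#' @export
format.sequence_variant <- function(x, aa_format = c("three", "one"), ...) {
  aa_format <- match.arg(aa_format)
  paste0(x$ac, ":", x$type, ".", format(x$posedit, aa_format = aa_format))
}

#' @export
as.character.sequence_variant <- function(x, ...) format(x, ...)

#' @export
print.sequence_variant <- function(x, ...) {
  cat(format(x, ...), "\n", sep = "")
  invisible(x)
}

#' @export
print.hgvs_posedit <- function(x, ...) {
  cat(format(x, ...), "\n", sep = "")
  invisible(x)
}

#' @export
print.hgvs_position <- function(x, ...) {
  cat(format(x, ...), "\n", sep = "")
  invisible(x)
}

#' @export
print.hgvs_interval <- function(x, ...) {
  cat(format(x, ...), "\n", sep = "")
  invisible(x)
}

#' Transliterate a DNA-level variant to RNA (`r.`) spelling
#'
#' Coordinates of `r.` variants coincide with the source `c.`/`n.`
#' coordinates; only the alphabet changes (upper-case DNA to lower-case RNA,
#' `T` to `u`).
#'
#' @param v A `c.` or `n.` [sequence_variant()].
#' @return The equivalent `r.` variant.
#' @export
to_rna_variant <- function(v) {
  if (!inherits(v, "sequence_variant") || !(v$type %in% c("c", "n")))
    hgvs_error("r. transliteration is defined for c. and n. variants", "hgvs_type_error")
  tr <- function(s) if (is.null(s)) NULL else chartr("ACGT", "acgu", s)
  e <- v$posedit$edit
  for (f in c("ref", "alt", "unit")) if (!is.null(e[[f]])) e[[f]] <- tr(e[[f]])
  # r. keeps the numbering of its source (CDS-relative from c., plain from n.)
  sequence_variant(v$ac, "r", posedit(v$posedit$pos, e, v$posedit$inferred),
                   validate = FALSE)
}
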