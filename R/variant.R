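.seq_types <- c("g", "m", "c", "n", "r", "p")

# legal edit-string alphabet per sequence type (protein handled separately)
.type_alphabet <- function(type) {
  switch(type,
         g = , m = , c = , n = "ACGT",
         r = "acgu",
         NULL)
}

.alphabet_ok <- function(s, alpha) {
  !is.null(s) && !grepl(sprintf("[^%s]", alpha), s)
}

edit_seq_strings <- function(e) {
  out <- switch(edit_kind(e),
                sub = c(e$ref, e$alt),
                del = e$ref,
                ins = e$alt,
                delins = c(e$ref, e$alt),
                dup = e$ref,
                identity = e$ref,
                "repeat" = e$unit,
                character(0))
  if (is.null(out)) character(0) else out
}

#' Position + edit
#'
#' Pairs a location [hgvs_interval()] with an edit.  For protein variants the
#' `inferred` flag marks a predicted consequence, rendered inside parentheses
#' (`p.(...)`); `pos` may be `NULL` only for the protein identity edit
#' (`p.=` / `p.(=)`), which has no location.
#'
#' @param pos An [hgvs_interval()] (or `NULL` for protein identity).
#' @param edit An edit (see [edit_sub()] and friends).
#' @param inferred Predicted (protein) consequence, formatted in parentheses.
#' @return An `hgvs_posedit` object.
#' @export
posedit <- function(pos, edit, inferred = FALSE) {
  if (!inherits(edit, "hgvs_edit"))
    hgvs_error("edit must be an hgvs_edit", "hgvs_type_error")
  if (is.null(pos)) {
    if (!inherits(edit, "edit_aa_identity"))
      hgvs_error("only the protein identity edit may omit its position", "hgvs_type_error")
  } else if (!inherits(pos, "hgvs_interval")) {
    hgvs_error("pos must be an hgvs_interval", "hgvs_type_error")
  } else {
    aa_pos <- inherits(pos$start, "aa_position")
    if (aa_pos != inherits(edit, "aa_edit"))
      hgvs_error("position kind and edit kind refer to different sequence types", "hgvs_type_error")
  }
  structure(list(pos = pos, edit = edit, inferred = isTRUE(inferred)),
            class = "hgvs_posedit")
}

#' HGVS sequence variant
#'
#' The unit every component of the package consumes and produces: a sequence
#' `accession`, a sequence `type` (one of `g`, `m`, `c`, `n`, `r`, `p`) and a
#' [posedit()].  The constructor checks that the position kind matches the
#' sequence type (base-offset positions for `c`/`n`/`r`, plain positions for
#' `g`/`m`, residue positions for `p`) and that edit sequences are drawn from
#' the type's alphabet (DNA for `g`/`m`/`c`/`n`, lower-case RNA for `r`).
#' `validate = FALSE` skips these checks so that inconsistent objects can be
#' built for (and reported by) [validate_intrinsic()].
#'
#' @param ac Versioned sequence accession, e.g. `"NM_182763.2"`.
#' @param type Sequence type letter.
#' @param posedit A [posedit()].
#' @param validate Enforce type-compatibility invariants.
#' @return A `sequence_variant` object.
#' @examples
#' v <- sequence_variant("NM_182763.2", "c",
#'   posedit(hgvs_interval(base_offset_position(688, 403)), edit_sub("C", "T")))
#' format(v)
#' @export
sequence_variant <- function(ac, type, posedit, validate = TRUE) {
  if (!is.character(ac) || length(ac) != 1L || is.na(ac) || !nzchar(ac))
    hgvs_error("accession must be a non-empty string", "hgvs_value_error")
  if (!is.character(type) || length(type) != 1L || !(type %in% .seq_types))
    hgvs_error("type must be one of g, m, c, n, r, p", "hgvs_value_error")
  if (!inherits(posedit, "hgvs_posedit"))
    hgvs_error("posedit must be an hgvs_posedit", "hgvs_type_error")
  if (validate) .check_variant_compat(type, posedit)
  structure(list(ac = ac, type = type, posedit = posedit),
            class = "sequence_variant")
}

.check_variant_compat <- function(type, pe) {
  pos_cls <- switch(type,
                    g = , m = "simple_position",
                    c = , n = , r = "base_offset_position",
                    p = "aa_position")
  if (!is.null(pe$pos)) {
    if (class(pe$pos$start)[1] != pos_cls)
      hgvs_error(sprintf("'%s.' variants require %s positions", type, pos_cls),
                 "hgvs_type_error")
    if (type == "n" &&
        (pe$pos$start$datum != "seq_start" || pe$pos$end$datum != "seq_start"))
      hgvs_error("'n.' positions use the seq_start datum", "hgvs_type_error")
    if (type == "c" &&
        (pe$pos$start$datum == "seq_start" || pe$pos$end$datum == "seq_start"))
      hgvs_error("'c.' positions are CDS-relative", "hgvs_type_error")
  }
  if (type == "p") {
    if (!inherits(pe$edit, "aa_edit"))
      hgvs_error("'p.' variants require protein edits", "hgvs_type_error")
  } else {
    if (inherits(pe$edit, "aa_edit"))
      hgvs_error("protein edits require a 'p.' variant", "hgvs_type_error")
    alpha <- .type_alphabet(type)
    for (s in edit_seq_strings(pe$edit))
      if (!.alphabet_ok(s, alpha))
        hgvs_error(sprintf("edit sequence '%s' is not in the %s. alphabet", s, type),
                   "hgvs_value_error")
  }
  invisible(TRUE)
}
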