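# Edits are a tagged union: one constructor and class per kind.  Nucleotide
# edits carry raw ref/alt strings; the owning sequence type decides the legal
# alphabet (checked in sequence_variant() and by the intrinsic validator).

.new_edit <- function(kind, fields, protein = FALSE) {
  structure(fields,
            class = c(paste0("edit_", kind),
                      if (protein) "aa_edit" else "nt_edit",
                      "hgvs_edit"))
}

.chk_seq <- function(x, what, allow_null = TRUE) {
  if (is.null(x)) {
    if (!allow_null) hgvs_error(sprintf("%s is required", what), "hgvs_value_error")
    return(NULL)
  }
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    hgvs_error(sprintf("%s must be a non-empty string", what), "hgvs_value_error")
  x
}

#' Sequence edits
#'
#' Constructors for the edit part of a variant.  Nucleotide edits:
#' substitution (`edit_sub`), deletion (`edit_del`, with an optional explicit
#' deleted sequence), insertion (`edit_ins`), deletion-insertion
#' (`edit_delins`), duplication (`edit_dup`) and repeat (`edit_repeat`, a
#' repeat `unit` observed between `min` and `max` times).  `edit_identity`
#' asserts the reference (`=`), optionally naming the reference base(s).
#'
#' Protein edits: `edit_aa_sub` (the reference residue lives in the interval's
#' [aa_position()]), `edit_aa_delins` (covers in-frame deletions, insertions
#' between two flanking residues when `ins_only = TRUE`, and
#' deletion-insertions), `edit_aa_fs` (frameshift from the first changed
#' residue, with the new-frame stop position in `terminus`, `NA` when no stop
#' is reached) and `edit_aa_identity` (`=`, no protein change).
#'
#' @param ref,alt Reference / alternate sequence strings.
#' @param unit Repeat unit sequence.
#' @param min,max Repeat count bounds, `1 <= min <= max`.
#' @param ins_only For protein delins: insertion between two flanking residues.
#' @param terminus Frameshift: 1-based position of the first stop in the new
#'   reading frame, counting the first changed residue as 1 (`NA` = none found).
#' @return An edit object inheriting from `hgvs_edit`.
#' @examples
#' edit_sub("C", "T")             # C>T
#' edit_delins(alt = "AA")        # delinsAA
#' edit_repeat("AGC", 3, 6)       # AGC[3_6]
#' edit_aa_fs(alt = "Pro", terminus = 23)  # ProfsTer23
#' @export
edit_sub <- function(ref, alt) {
  ref <- .chk_seq(ref, "ref", allow_null = FALSE)
  alt <- .chk_seq(alt, "alt", allow_null = FALSE)
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    hgvs_error("substitutions replace exactly one base", "hgvs_value_error")
  .new_edit("sub", list(ref = ref, alt = alt))
}

#' @rdname edit_sub
#' @export
edit_del <- function(ref = NULL) .new_edit("del", list(ref = .chk_seq(ref, "ref")))

#' @rdname edit_sub
#' @export
edit_ins <- function(alt) .new_edit("ins", list(alt = .chk_seq(alt, "alt", allow_null = FALSE)))

#' @rdname edit_sub
#' @export
edit_delins <- function(ref = NULL, alt) {
  ref <- .chk_seq(ref, "ref")
  alt <- .chk_seq(alt, "alt", allow_null = FALSE)
  if (!is.null(ref) && nchar(ref) == 1L && nchar(alt) == 1L)
    hgvs_error("a single-base replacement is a substitution, not delins", "hgvs_value_error")
  .new_edit("delins", list(ref = ref, alt = alt))
}

#' @rdname edit_sub
#' @export
edit_dup <- function(ref = NULL) .new_edit("dup", list(ref = .chk_seq(ref, "ref")))

#' @rdname edit_sub
#' @export
edit_identity <- function(ref = NULL) .new_edit("identity", list(ref = .chk_seq(ref, "ref")))

#' @rdname edit_sub
#' @export
edit_repeat <- function(unit, min, max = min) {
  unit <- .chk_seq(unit, "unit", allow_null = FALSE)
  min <- .as_int1(min, "min")
  max <- .as_int1(max, "max")
  if (min < 1L || min > max)
    hgvs_error("repeat counts must satisfy 1 <= min <= max", "hgvs_value_error")
  .new_edit("repeat", list(unit = unit, min = min, max = max))
}

#' @rdname edit_sub
#' @export
edit_aa_sub <- function(alt) {
  .new_edit("aa_sub", list(alt = aa_to3(alt)), protein = TRUE)
}

#' @rdname edit_sub
#' @export
edit_aa_delins <- function(alt = NULL, ins_only = FALSE) {
  if (!is.null(alt)) {
    alt <- vapply(alt, aa_to3, character(1), USE.NAMES = FALSE)
  } else if (ins_only) {
    hgvs_error("an insertion needs inserted residues", "hgvs_value_error")
  }
  .new_edit("aa_delins", list(alt = alt, ins_only = isTRUE(ins_only)), protein = TRUE)
}

#' @rdname edit_sub
#' @export
edit_aa_fs <- function(alt = NULL, terminus = NA_integer_) {
  if (!is.null(alt)) alt <- aa_to3(alt)
  if (!is.na(terminus)) {
    terminus <- .as_int1(terminus, "terminus")
    if (terminus < 1L) hgvs_error("terminus must be >= 1", "hgvs_value_error")
  } else {
    terminus <- NA_integer_
  }
  .new_edit("aa_fs", list(alt = alt, terminus = terminus), protein = TRUE)
}

#' @rdname edit_sub
#' @export
edit_aa_identity <- function() .new_edit("aa_identity", list(), protein = TRUE)

edit_kind <- function(e) sub("^edit_", "", class(e)[1])

#' Classify a variant by its edit
#'
#' The category is determined solely by the edit's union tag:
#' `sub`, `del`, `ins`, `delins`, `dup`, `repeat`, `identity` for nucleotide
#' variants and `aa_sub`, `aa_delins`, `aa_fs`, `aa_identity` for protein
#' variants.
#'
#' @param v A [sequence_variant()] (or a bare edit / posedit).
#' @return A single string naming the category.
#' @export
variant_category <- function(v) {
  e <- if (inherits(v, "hgvs_edit")) v
       else if (inherits(v, "hgvs_posedit")) v$edit
       else if (inherits(v, "sequence_variant")) v$posedit$edit
       else hgvs_error("cannot classify this object", "hgvs_type_error")
  edit_kind(e)
}
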