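# PEG-style recursive-descent parser.  Every production is a named function
# in the rule registry and can be invoked on its own through parse_rule();
# ordered choice with explicit backtracking gives the usual PEG semantics
# (first matching alternative wins, no reconsideration after local success).

.cur_new <- function(text) {
  e <- new.env(parent = emptyenv())
  e$text <- text
  e$n <- nchar(text)
  e$pos <- 1L
  e$max <- 1L          # deepest failure position (for error reports)
  e$max_rule <- ""
  e
}

.fail <- function(cur, p0, rule = NULL) {
  if (cur$pos >= cur$max) {
    cur$max <- cur$pos
    if (!is.null(rule)) cur$max_rule <- rule
  }
  cur$pos <- p0
  NULL
}

.eat_rx <- function(cur, rx) {
  m <- regexpr(rx, substr(cur$text, cur$pos, cur$n), perl = TRUE)
  if (m[1] == -1L) return(NULL)
  len <- attr(m, "match.length")
  s <- substr(cur$text, cur$pos, cur$pos + len - 1L)
  cur$pos <- cur$pos + len
  s
}

.eat_lit <- function(cur, lit) {
  k <- nchar(lit)
  if (substr(cur$text, cur$pos, cur$pos + k - 1L) == lit) {
    cur$pos <- cur$pos + k
    lit
  } else NULL
}

.eat_int <- function(cur) {
  s <- .eat_rx(cur, "^[0-9]{1,9}")
  if (is.null(s)) NULL else as.integer(s)
}

# --- terminals ---------------------------------------------------------------

.r_accession <- function(cur) {
  p0 <- cur$pos
  s <- .eat_rx(cur, "^[A-Za-z][A-Za-z0-9_.-]*")
  if (is.null(s)) return(.fail(cur, p0, "accession"))
  s
}

.r_simple_position <- function(cur) {
  p0 <- cur$pos
  b <- .eat_int(cur)
  if (is.null(b) || b < 1L) return(.fail(cur, p0, "simple_position"))
  simple_position(b)
}

# CDS-relative position: optional '*' (3' UTR) or '-' (5' UTR), base, offset
.r_base_offset_position <- function(cur) {
  p0 <- cur$pos
  if (!is.null(.eat_lit(cur, "*"))) {
    b <- .eat_int(cur)
    if (is.null(b) || b < 1L) return(.fail(cur, p0, "base_offset_position"))
    datum <- "cds_end"
  } else {
    neg <- !is.null(.eat_lit(cur, "-"))
    b <- .eat_int(cur)
    if (is.null(b) || b < 1L) return(.fail(cur, p0, "base_offset_position"))  # no c.0
    if (neg) b <- -b
    datum <- "cds_start"
  }
  off <- .eat_rx(cur, "^[+-][0-9]{1,9}")
  off <- if (is.null(off)) 0L else as.integer(off)
  base_offset_position(b, off, datum)
}

# transcript-from-start position (n.): positive base, optional intronic offset
.r_n_position <- function(cur) {
  p0 <- cur$pos
  b <- .eat_int(cur)
  if (is.null(b) || b < 1L) return(.fail(cur, p0, "n_position"))
  off <- .eat_rx(cur, "^[+-][0-9]{1,9}")
  off <- if (is.null(off)) 0L else as.integer(off)
  base_offset_position(b, off, "seq_start")
}

.aa3_rx <- "^(Ala|Arg|Asn|Asp|Cys|Gln|Glu|Gly|His|Ile|Leu|Lys|Met|Phe|Pro|Ser|Thr|Trp|Tyr|Val|Ter)"

.r_aa_token <- function(cur) {
  s <- .eat_rx(cur, .aa3_rx)
  if (!is.null(s)) return(s)
  s <- .eat_rx(cur, "^[ACDEFGHIKLMNPQRSTVWY*]")
  if (is.null(s)) return(NULL)
  aa_to3(s)
}

.r_aa_position <- function(cur) {
  p0 <- cur$pos
  aa <- .r_aa_token(cur)
  if (is.null(aa)) return(.fail(cur, p0, "aa_position"))
  b <- .eat_int(cur)
  if (is.null(b) || b < 1L) return(.fail(cur, p0, "aa_position"))
  aa_position(b, aa)
}

.r_aa_seq <- function(cur) {
  out <- character(0)
  repeat {
    aa <- .r_aa_token(cur)
    if (is.null(aa)) break
    out <- c(out, aa)
  }
  if (length(out) == 0L) NULL else out
}

# --- intervals ---------------------------------------------------------------

.r_interval <- function(cur, pos_rule, name) {
  p0 <- cur$pos
  a <- pos_rule(cur)
  if (is.null(a)) return(.fail(cur, p0, name))
  if (!is.null(.eat_lit(cur, "_"))) {
    b <- pos_rule(cur)
    if (is.null(b)) return(.fail(cur, p0, name))
    hgvs_interval(a, b, validate = FALSE)
  } else {
    hgvs_interval(a, a, validate = FALSE)
  }
}

.r_g_interval <- function(cur) .r_interval(cur, .r_simple_position, "g_interval")
.r_c_interval <- function(cur) .r_interval(cur, .r_base_offset_position, "c_interval")
.r_n_interval <- function(cur) .r_interval(cur, .r_n_position, "n_interval")
.r_p_interval <- function(cur) .r_interval(cur, .r_aa_position, "p_interval")

# --- nucleotide edits --------------------------------------------------------

.r_nt_edit <- function(cur, alpha, name) {
  one <- sprintf("^[%s]", alpha)
  many <- sprintf("^[%s]+", alpha)
  p0 <- cur$pos

  # substitution: X>Y
  ref <- .eat_rx(cur, one)
  if (!is.null(ref) && !is.null(.eat_lit(cur, ">"))) {
    alt <- .eat_rx(cur, one)
    if (!is.null(alt)) return(edit_sub(ref, alt))
  }
  cur$pos <- p0

  # del / delins (explicit deleted sequence optional)
  if (!is.null(.eat_lit(cur, "del"))) {
    ref <- .eat_rx(cur, many)
    if (!is.null(.eat_lit(cur, "ins"))) {
      alt <- .eat_rx(cur, many)
      if (is.null(alt)) return(.fail(cur, p0, name))
      if (!is.null(ref) && nchar(ref) == 1L && nchar(alt) == 1L)
        return(.fail(cur, p0, name))  # 1-base replacement must be written X>Y
      return(edit_delins(ref, alt))
    }
    return(edit_del(ref))
  }

  # dup
  if (!is.null(.eat_lit(cur, "dup"))) {
    return(edit_dup(.eat_rx(cur, many)))
  }

  # ins
  if (!is.null(.eat_lit(cur, "ins"))) {
    alt <- .eat_rx(cur, many)
    if (is.null(alt)) return(.fail(cur, p0, name))
    return(edit_ins(alt))
  }

  # repeat: UNIT[min] or UNIT[min_max]
  unit <- .eat_rx(cur, many)
  if (!is.null(unit) && !is.null(.eat_lit(cur, "["))) {
    mn <- .eat_int(cur)
    if (!is.null(mn)) {
      mx <- if (!is.null(.eat_lit(cur, "_"))) .eat_int(cur) else mn
      if (!is.null(mx) && !is.null(.eat_lit(cur, "]")) && mn >= 1L && mn <= mx)
        return(edit_repeat(unit, mn, mx))
    }
    return(.fail(cur, p0, name))
  }
  cur$pos <- p0

  # identity: (REF)=
  ref <- .eat_rx(cur, many)
  if (!is.null(.eat_lit(cur, "="))) return(edit_identity(ref))
  .fail(cur, p0, name)
}

.r_dna_edit <- function(cur) .r_nt_edit(cur, "ACGT", "dna_edit")
.r_rna_edit <- function(cur) .r_nt_edit(cur, "acgu", "rna_edit")

# --- protein edits -----------------------------------------------------------

.r_fs_suffix <- function(cur) {
  # after the literal "fs": optional Ter<pos>, Ter?, *<pos> or *?
  p0 <- cur$pos
  if (is.null(.eat_lit(cur, "Ter")) && is.null(.eat_lit(cur, "*")))
    return(NA_integer_)
  t <- .eat_int(cur)
  if (!is.null(t) && t >= 1L) return(t)
  if (!is.null(.eat_lit(cur, "?"))) return(NA_integer_)
  cur$pos <- p0
  NA_integer_
}

.r_p_posedit <- function(cur) {
  p0 <- cur$pos
  inferred <- !is.null(.eat_lit(cur, "("))
  close_ok <- function() !inferred || !is.null(.eat_lit(cur, ")"))

  if (!is.null(.eat_lit(cur, "="))) {
    if (!close_ok()) return(.fail(cur, p0, "p_posedit"))
    return(posedit(NULL, edit_aa_identity(), inferred))
  }

  iv <- .r_p_interval(cur)
  if (is.null(iv)) return(.fail(cur, p0, "p_posedit"))

  edit <- NULL
  p1 <- cur$pos

  # frameshift with explicit new residue: AlafsTer12, Alafs
  alt <- .r_aa_token(cur)
  if (!is.null(alt) && !is.null(.eat_lit(cur, "fs"))) {
    edit <- edit_aa_fs(alt, .r_fs_suffix(cur))
  } else {
    cur$pos <- p1
    if (!is.null(.eat_lit(cur, "fs"))) {
      edit <- edit_aa_fs(NULL, .r_fs_suffix(cur))
    } else if (!is.null(.eat_lit(cur, "del"))) {
      if (!is.null(.eat_lit(cur, "ins"))) {
        alt <- .r_aa_seq(cur)
        if (is.null(alt)) return(.fail(cur, p0, "p_posedit"))
        edit <- edit_aa_delins(alt)
      } else {
        edit <- edit_aa_delins(NULL)
      }
    } else if (!is.null(.eat_lit(cur, "ins"))) {
      alt <- .r_aa_seq(cur)
      if (is.null(alt)) return(.fail(cur, p0, "p_posedit"))
      edit <- edit_aa_delins(alt, ins_only = TRUE)
    } else {
      alt <- .r_aa_token(cur)
      if (is.null(alt)) return(.fail(cur, p0, "p_posedit"))
      edit <- edit_aa_sub(alt)
    }
  }
  if (!close_ok()) return(.fail(cur, p0, "p_posedit"))
  posedit(iv, edit, inferred)
}

# --- posedits per sequence type ---------------------------------------------

.r_posedit_for <- function(iv_rule, edit_rule, name) {
  function(cur) {
    p0 <- cur$pos
    iv <- iv_rule(cur)
    if (is.null(iv)) return(.fail(cur, p0, name))
    e <- edit_rule(cur)
    if (is.null(e)) return(.fail(cur, p0, name))
    posedit(iv, e)
  }
}

.r_g_posedit <- .r_posedit_for(.r_g_interval, .r_dna_edit, "g_posedit")
.r_c_posedit <- .r_posedit_for(.r_c_interval, .r_dna_edit, "c_posedit")
.r_n_posedit <- .r_posedit_for(.r_n_interval, .r_dna_edit, "n_posedit")
.r_r_posedit <- .r_posedit_for(.r_c_interval, .r_rna_edit, "r_posedit")

# --- whole variant -----------------------------------------------------------

.posedit_rule_for_type <- function(type) {
  switch(type,
         g = , m = .r_g_posedit,
         c = .r_c_posedit,
         n = .r_n_posedit,
         r = .r_r_posedit,
         p = .r_p_posedit)
}

.r_hgvs_variant <- function(cur) {
  p0 <- cur$pos
  ac <- .r_accession(cur)
  if (is.null(ac)) return(.fail(cur, p0, "hgvs_variant"))
  gene <- NULL
  if (!is.null(.eat_lit(cur, "("))) {
    gene <- .eat_rx(cur, "^[A-Za-z0-9_.-]+")
    if (is.null(gene) || is.null(.eat_lit(cur, ")")))
      return(.fail(cur, p0, "hgvs_variant"))
  }
  if (is.null(.eat_lit(cur, ":"))) return(.fail(cur, p0, "hgvs_variant"))
  type <- .eat_rx(cur, "^[gmcnrp]\\.")
  if (is.null(type)) return(.fail(cur, p0, "hgvs_variant"))
  type <- substr(type, 1L, 1L)
  pe <- .posedit_rule_for_type(type)(cur)
  if (is.null(pe)) return(.fail(cur, p0, "hgvs_variant"))
  if (!is.null(gene))
    warning(warningCondition(
      sprintf("gene symbol annotation '(%s)' was discarded", gene),
      class = c("hgvs_gene_annotation_warning", "warning", "condition")))
  tryCatch(sequence_variant(ac, type, pe),
           hgvs_error = function(e) .fail(cur, p0, "hgvs_variant"))
}

.hgvs_rules <- list(
  hgvs_variant = .r_hgvs_variant,
  accession = .r_accession,
  simple_position = .r_simple_position,
  base_offset_position = .r_base_offset_position,
  n_position = .r_n_position,
  aa_position = .r_aa_position,
  g_interval = .r_g_interval,
  c_interval = .r_c_interval,
  n_interval = .r_n_interval,
  p_interval = .r_p_interval,
  dna_edit = .r_dna_edit,
  rna_edit = .r_rna_edit,
  g_posedit = .r_g_posedit,
  m_posedit = .r_g_posedit,
  c_posedit = .r_c_posedit,
  n_posedit = .r_n_posedit,
  r_posedit = .r_r_posedit,
  p_posedit = .r_p_posedit
)

#' Names of the grammar's productions
#'
#' @return Character vector of rule names accepted by [parse_rule()].
#' @export
hgvs_rules <- function() names(.hgvs_rules)

.parse_error <- function(cur) {
  hgvs_error(
    sprintf("parse error at character %d of '%s'%s",
            cur$max, cur$text,
            if (nzchar(cur$max_rule)) sprintf(" (while matching rule '%s')", cur$max_rule) else ""),
    "hgvs_parse_error",
    position = cur$max, rule = cur$max_rule, input = cur$text)
}

#' Parse an HGVS variant string
#'
#' Parses a complete `accession:type.posedit` string into a
#' [sequence_variant()].  The whole input must be consumed; trailing
#' characters are a parse error.  A gene symbol in parentheses after the
#' accession (`NM_x(GENE):c...`) is accepted and discarded with a warning.
#' Syntax errors raise a structured condition of class `hgvs_parse_error`
#' reporting the failing character position and the deepest rule attempted.
#'
#' @param text A single HGVS string (ASCII; the substitution separator is the
#'   ASCII `>`).
#' @return A [sequence_variant()].
#' @examples
#' v <- parse_hgvs("NM_182763.2:c.688+403C>T")
#' v$posedit$pos$start$base    # 688
#' v$posedit$pos$start$offset  # 403
#' @seealso [parse_rule()] to parse fragments with any named production.
#' @export
parse_hgvs <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    hgvs_error("input must be a single string", "hgvs_value_error")
  cur <- .cur_new(text)
  v <- .r_hgvs_variant(cur)
  if (is.null(v) || cur$pos <= cur$n) {
    if (!is.null(v) && cur$pos >= cur$max) { cur$max <- cur$pos; cur$max_rule <- "hgvs_variant" }
    .parse_error(cur)
  }
  v
}

#' Parse a fragment with a named grammar rule
#'
#' Any production of the grammar can be used as an entry point, e.g. the
#' `c_posedit` rule parses `"688+403C>T"` and the `base_offset_position` rule
#' parses `"88-2"`.  The full input must be consumed by the rule.
#'
#' @param rule Name of a production; see [hgvs_rules()].
#' @param text Fragment to parse.
#' @return The model fragment the production builds (a position, interval,
#'   edit, posedit or accession string).
#' @examples
#' parse_rule("c_posedit", "688+403C>T")
#' parse_rule("base_offset_position", "88-2")
#' @export
parse_rule <- function(rule, text) {
  fn <- .hgvs_rules[[rule]]
  if (is.null(fn))
    hgvs_error(sprintf("unknown grammar rule '%s'", rule), "hgvs_unknown_rule_error")
  if (!is.character(text) || length(text) != 1L || is.na(text))
    hgvs_error("input must be a single string", "hgvs_value_error")
  cur <- .cur_new(text)
  val <- fn(cur)
  if (is.null(val) || cur$pos <= cur$n) {
    if (!is.null(val) && cur$pos >= cur$max) { cur$max <- cur$pos; cur$max_rule <- rule }
    .parse_error(cur)
  }
  val
}
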