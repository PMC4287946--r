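#' @keywords internal
"_PACKAGE"

# Positions use the HGVS convention throughout: 1-based, inclusive.  The only
# 0-based/interbase arithmetic in the package lives inside alignment maps.

hgvs_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "hgvs_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.as_int1 <- function(x, what) {
  if (length(x) != 1L || is.na(x)) hgvs_error(sprintf("%s must be a single integer", what), "hgvs_value_error")
  xi <- suppressWarnings(as.integer(x))
  if (is.na(xi) || xi != x) hgvs_error(sprintf("%s must be a single integer", what), "hgvs_value_error")
  xi
}

#' Positions on a sequence
#'
#' Three position kinds cover the HGVS coordinate systems:
#' * `simple_position()` — plain 1-based coordinates, used for genomic (`g.`)
#'   and mitochondrial (`m.`) variants.
#' * `base_offset_position()` — transcript coordinates with an optional
#'   intronic offset, used for `c.`, `n.` and `r.` variants.  `base` is the
#'   exonic anchor; a non-zero `offset` counts bases into the intron from that
#'   anchor (`+` towards 3', `-` towards 5').  The `datum` selects the origin:
#'   `"seq_start"` for `n.` numbering, `"cds_start"` for CDS-relative `c.`
#'   numbering (negative bases are 5' UTR; there is no position 0), and
#'   `"cds_end"` for `*`-positions counted from the first base after the stop
#'   codon.
#' * `aa_position()` — protein residue coordinates carrying the reference
#'   amino acid (stored as its 3-letter code).
#'
#' @param base Integer coordinate (see above for the per-kind constraints).
#' @param offset Integer intronic offset; 0 means exonic.
#' @param datum Coordinate origin for base-offset positions.
#' @param aa Amino-acid code, 1- or 3-letter (`"*"` and `"Ter"` both denote
#'   the translation stop).
#' @return A position object (`simple_position`, `base_offset_position` or
#'   `aa_position`, all inheriting from `hgvs_position`).
#' @examples
#' base_offset_position(688, 403)      # c.688+403
#' base_offset_position(3, datum = "cds_end")  # c.*3
#' aa_position(2, "A")                 # Ala2
#' @export
simple_position <- function(base) {
  base <- .as_int1(base, "base")
  if (base < 1L) hgvs_error("simple positions are 1-based: base must be >= 1", "hgvs_value_error")
  structure(list(base = base), class = c("simple_position", "hgvs_position"))
}

#' @rdname simple_position
#' @export
base_offset_position <- function(base, offset = 0L,
                                 datum = c("cds_start", "seq_start", "cds_end")) {
  datum <- match.arg(datum)
  base <- .as_int1(base, "base")
  offset <- .as_int1(offset, "offset")
  if (datum == "cds_start" && base == 0L)
    hgvs_error("HGVS has no position 0: base must be non-zero for CDS-relative positions", "hgvs_value_error")
  if (datum != "cds_start" && base < 1L)
    hgvs_error(sprintf("base must be >= 1 for datum '%s'", datum), "hgvs_value_error")
  structure(list(base = base, offset = offset, datum = datum),
            class = c("base_offset_position", "hgvs_position"))
}

# amino-acid code tables (incl. Ter for the translation stop)
.aa1 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V","*")
.aa3 <- c("Ala","Arg","Asn","Asp","Cys","Gln","Glu","Gly","His","Ile","Leu","Lys",
          "Met","Phe","Pro","Ser","Thr","Trp","Tyr","Val","Ter")

aa_to3 <- function(aa) {
  if (aa %in% .aa3) return(aa)
  i <- match(aa, .aa1)
  if (is.na(i)) hgvs_error(sprintf("unknown amino-acid code '%s'", aa), "hgvs_value_error")
  .aa3[i]
}

aa_to1 <- function(aa3) {
  i <- match(aa3, .aa3)
  if (is.na(i)) hgvs_error(sprintf("unknown amino-acid code '%s'", aa3), "hgvs_value_error")
  .aa1[i]
}

#' @rdname simple_position
#' @export
aa_position <- function(base, aa) {
  base <- .as_int1(base, "base")
  if (base < 1L) hgvs_error("residue numbers are 1-based: base must be >= 1", "hgvs_value_error")
  structure(list(base = base, aa = aa_to3(aa)),
            class = c("aa_position", "hgvs_position"))
}

#' Compare two positions
#'
#' Total order on each position kind, consistent with left-to-right order on
#' the underlying sequence.  For CDS-relative positions, negative (5' UTR)
#' bases precede positive bases, `*` (3' UTR, `datum = "cds_end"`) positions
#' follow all CDS positions, and within a base smaller intronic offsets come
#' first (so `c.88 < c.88+2 < c.89-2 < c.89`).
#'
#' @param a,b Positions of the same kind (and, for base-offset positions, of
#'   the same numbering family: `seq_start` coordinates are not comparable
#'   with CDS-relative ones).
#' @return `-1L`, `0L` or `1L` for `a < b`, `a == b`, `a > b`.
#' @examples
#' position_order(base_offset_position(-5), base_offset_position(1))   # -1
#' position_order(base_offset_position(88, 2), base_offset_position(89, -2))
#' @export
position_order <- function(a, b) {
  if (!inherits(a, "hgvs_position") || !inherits(b, "hgvs_position") ||
      !.pos_comparable(a, b))
    hgvs_error("positions of different kinds are not comparable", "hgvs_type_error")
  ka <- .pos_key(a)
  kb <- .pos_key(b)
  for (i in seq_along(ka)) {
    if (ka[i] < kb[i]) return(-1L)
    if (ka[i] > kb[i]) return(1L)
  }
  0L
}

.pos_key <- function(p) {
  if (inherits(p, "base_offset_position")) {
    # seq_start and cds_* live on different numbering lines
    rank <- switch(p$datum, seq_start = 0, cds_start = 1, cds_end = 2)
    c(if (p$datum == "seq_start") 0 else 1, rank, p$base, p$offset)
  } else {
    c(0, 0, p$base, 0)
  }
}

.pos_comparable <- function(a, b) {
  if (class(a)[1] != class(b)[1]) return(FALSE)
  if (inherits(a, "base_offset_position")) {
    fam <- function(d) if (d == "seq_start") "n" else "c"
    return(fam(a$datum) == fam(b$datum))
  }
  TRUE
}

#' Position interval
#'
#' An inclusive interval between two positions of the same kind.  By default
#' the constructor enforces `start <= end` (under [position_order()]); the
#' parser builds intervals with `validate = FALSE` so that syntactically valid
#' but inconsistent strings (such as `g.7_5del`) can be reported by
#' [validate_intrinsic()] instead of failing at construction.
#'
#' @param start,end Positions; `end` defaults to `start` (a point interval).
#' @param validate Enforce the ordering invariant at construction.
#' @return An `hgvs_interval` object.
#' @export
hgvs_interval <- function(start, end = start, validate = TRUE) {
  if (!inherits(start, "hgvs_position") || !inherits(end, "hgvs_position"))
    hgvs_error("interval bounds must be positions", "hgvs_type_error")
  if (!.pos_comparable(start, end))
    hgvs_error("interval bounds must be comparable positions of one kind", "hgvs_type_error")
  if (validate && position_order(start, end) > 0L)
    hgvs_error("interval start must be <= end", "hgvs_value_error")
  structure(list(start = start, end = end), class = "hgvs_interval")
}

interval_is_point <- function(iv) identical(iv$start, iv$end)
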