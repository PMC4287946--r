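# Genome-transcript alignment maps.  Internally everything here is 0-based
# half-open (interbase) — gap and intron arithmetic is off-by-one-proof that
# way — and converts to the model's 1-based inclusive convention only at the
# function boundaries.
#
# Block kinds: M (aligned), D (genome-only), I (transcript-only), intron.
# Genomic spans of M/D/intron blocks partition the transcript's genomic
# extent; transcript spans of M/I blocks partition [0, tx_len).

#' Build an alignment map from a transcript record
#'
#' Expands the record's per-exon segment runs into an ordered block table
#' over the transcript's genomic span, inserting intron blocks between
#' consecutive exons.  Transcript coordinates run 5'->3' in transcript
#' orientation; on the minus strand they therefore decrease with genomic
#' position.
#'
#' @param rec A [transcript_record()].
#' @return An `alignment_map`.
#' @export
build_alignment_map <- function(rec) {
  if (!inherits(rec, "transcript_record"))
    hgvs_error("rec must be a transcript_record", "hgvs_type_error")
  rows <- list()
  n <- 0L
  exs <- exons_tx_order(rec)
  for (k in seq_along(exs)) {
    ex <- exs[[k]]
    if (rec$strand == "+") {
      g <- ex$g_start - 1L
      for (seg in ex$segments) {
        if (seg$op == "M") {
          rows[[length(rows) + 1L]] <- list("M", g, g + seg$len, n, n + seg$len)
          g <- g + seg$len; n <- n + seg$len
        } else if (seg$op == "D") {
          rows[[length(rows) + 1L]] <- list("D", g, g + seg$len, n, n)
          g <- g + seg$len
        } else {
          rows[[length(rows) + 1L]] <- list("I", g, g, n, n + seg$len)
          n <- n + seg$len
        }
      }
      if (g != ex$g_end)
        hgvs_error(sprintf("exon %d of %s: segments do not close its genomic span",
                           k, rec$tx_ac), "hgvs_build_error")
    } else {
      g <- ex$g_end
      for (seg in ex$segments) {
        if (seg$op == "M") {
          rows[[length(rows) + 1L]] <- list("M", g - seg$len, g, n, n + seg$len)
          g <- g - seg$len; n <- n + seg$len
        } else if (seg$op == "D") {
          rows[[length(rows) + 1L]] <- list("D", g - seg$len, g, n, n)
          g <- g - seg$len
        } else {
          rows[[length(rows) + 1L]] <- list("I", g, g, n, n + seg$len)
          n <- n + seg$len
        }
      }
      if (g != ex$g_start - 1L)
        hgvs_error(sprintf("exon %d of %s: segments do not close its genomic span",
                           k, rec$tx_ac), "hgvs_build_error")
    }
  }
  # intron blocks between genomically consecutive exons
  gexs <- rec$exons
  for (i in seq_len(length(gexs) - 1L)) {
    rows[[length(rows) + 1L]] <- list("intron", gexs[[i]]$g_end,
                                      gexs[[i + 1L]]$g_start - 1L, NA_integer_, NA_integer_)
  }
  blocks <- data.frame(
    kind = vapply(rows, `[[`, character(1), 1L),
    g_lo = vapply(rows, function(r) as.integer(r[[2]]), integer(1)),
    g_hi = vapply(rows, function(r) as.integer(r[[3]]), integer(1)),
    n_lo = vapply(rows, function(r) as.integer(r[[4]]), integer(1)),
    n_hi = vapply(rows, function(r) as.integer(r[[5]]), integer(1)),
    stringsAsFactors = FALSE
  )
  blocks <- blocks[order(blocks$g_lo, blocks$g_hi), , drop = FALSE]
  structure(list(blocks = blocks, strand = rec$strand, tx_len = n,
                 g_lo = min(blocks$g_lo), g_hi = max(blocks$g_hi),
                 tx_ac = rec$tx_ac, ref_ac = rec$ref_ac),
            class = "alignment_map")
}

# row index of the g-width block containing 1-based genomic base g
.g_row <- function(map, g) {
  b <- map$blocks
  w <- which(b$g_lo < g & g <= b$g_hi)
  if (length(w) != 1L)
    hgvs_error(sprintf("g.%d is outside the transcript's genomic span (%d-%d)",
                       g, map$g_lo + 1L, map$g_hi), "hgvs_range_error")
  w
}

# transcript coordinate (1-based) of the aligned genomic base g; `dir` scans
# outward (-1 genomically left, +1 right) across D/intron blocks if g itself
# is not aligned
.nearest_exonic_n <- function(map, g, dir) {
  b <- map$blocks
  repeat {
    if (g <= map$g_lo || g > map$g_hi)
      hgvs_error("no aligned base in that direction", "hgvs_range_error")
    w <- which(b$g_lo < g & g <= b$g_hi)[1]
    if (!is.na(w) && b$kind[w] == "M") {
      off <- g - 1L - b$g_lo[w]
      return(if (map$strand == "+") b$n_lo[w] + off + 1L else b$n_hi[w] - off)
    }
    g <- if (dir < 0L) b$g_lo[w] else b$g_hi[w] + 1L
  }
}

.g_to_n1 <- function(map, g) {
  w <- .g_row(map, g)
  b <- map$blocks
  kind <- b$kind[w]
  if (kind == "M") {
    off <- g - 1L - b$g_lo[w]
    n <- if (map$strand == "+") b$n_lo[w] + off + 1L else b$n_hi[w] - off
    return(list(base = n, offset = 0L, gap = FALSE))
  }
  if (kind == "D") {
    # position falls in a genome-only gap: clamp to the transcript base
    # immediately 5' (transcript orientation) of the gap
    return(list(base = max(b$n_lo[w], 1L), offset = 0L, gap = TRUE))
  }
  # intron: anchor on the nearer exon boundary; ties go to the boundary that
  # is 5' in transcript orientation
  gL <- b$g_lo[w]          # 1-based last base of the genomically-left exon
  gR <- b$g_hi[w] + 1L     # 1-based first base of the genomically-right exon
  dL <- g - gL
  dR <- gR - g
  if (map$strand == "+") {
    if (dL <= dR) list(base = .nearest_exonic_n(map, gL, -1L), offset = dL, gap = FALSE)
    else list(base = .nearest_exonic_n(map, gR, 1L), offset = -dR, gap = FALSE)
  } else {
    if (dR <= dL) list(base = .nearest_exonic_n(map, gR, 1L), offset = dR, gap = FALSE)
    else list(base = .nearest_exonic_n(map, gL, -1L), offset = -dL, gap = FALSE)
  }
}

.n_to_g1 <- function(map, base, offset = 0L) {
  if (base < 1L || base > map$tx_len)
    hgvs_error(sprintf("n.%d is outside the transcript (length %d)", base, map$tx_len),
               "hgvs_range_error")
  b <- map$blocks
  n0 <- base - 1L
  w <- which(b$n_lo <= n0 & n0 < b$n_hi & b$kind %in% c("M", "I"))
  if (length(w) != 1L)
    hgvs_error(sprintf("no alignment block contains n.%d", base), "hgvs_mapping_error")
  if (b$kind[w] == "I") {
    # transcript-only base: clamp to the genomic position immediately 5'
    # (transcript orientation) of the insertion
    g <- if (map$strand == "+") max(b$g_lo[w], 1L) else b$g_lo[w] + 1L
    res <- list(g = g, gap = TRUE)
  } else {
    off <- n0 - b$n_lo[w]
    g <- if (map$strand == "+") b$g_lo[w] + off + 1L else b$g_hi[w] - off
    res <- list(g = g, gap = FALSE)
  }
  if (offset != 0L) {
    g2 <- if (map$strand == "+") res$g + offset else res$g - offset
    if (g2 <= map$g_lo || g2 > map$g_hi)
      hgvs_error(sprintf("n.%d%+d maps outside the transcript's genomic span", base, offset),
                 "hgvs_range_error")
    res$g <- g2
  }
  res
}

#' Project positions between genomic and transcript coordinates
#'
#' `g_to_n()` assigns each 1-based genomic position its transcript (`n.`)
#' coordinate: exonic aligned bases map exactly (offset 0); intronic bases
#' anchor on the nearest exon boundary with a signed offset (ties at the
#' midpoint of an even-length intron go to the boundary that is 5' in
#' transcript orientation); bases inside a genome-only (`D`) discrepancy are
#' clamped to the transcript base immediately 5' of the gap and flagged
#' (`gap = TRUE`).  `n_to_g()` is the inverse on aligned bases; transcript
#' bases inside a transcript-only (`I`) discrepancy clamp to the genomic
#' position immediately 5' of the insertion, flagged likewise.
#'
#' @param map An [build_alignment_map()] result.
#' @param g Integer vector of genomic positions (1-based).
#' @param base,offset Integer vectors of transcript base coordinates (1-based)
#'   and intronic offsets.
#' @return A data frame: for `g_to_n()` columns `base`, `offset`, `gap`; for
#'   `n_to_g()` columns `g`, `gap`.
#' @export
g_to_n <- function(map, g) {
  g <- as.integer(g)
  out <- lapply(g, function(x) .g_to_n1(map, x))
  data.frame(base = vapply(out, `[[`, integer(1), "base"),
             offset = vapply(out, `[[`, integer(1), "offset"),
             gap = vapply(out, `[[`, logical(1), "gap"))
}

#' @rdname g_to_n
#' @export
n_to_g <- function(map, base, offset = 0L) {
  base <- as.integer(base)
  offset <- rep_len(as.integer(offset), length(base))
  out <- mapply(function(b, o) .n_to_g1(map, b, o), base, offset, SIMPLIFY = FALSE)
  data.frame(g = vapply(out, `[[`, integer(1), "g"),
             gap = vapply(out, `[[`, logical(1), "gap"))
}

#' Convert between transcript (n.) and CDS-relative (c.) positions
#'
#' `n_to_c()` re-expresses a transcript position relative to the CDS: bases
#' 5' of the CDS start become negative (there is no position 0), bases within
#' the CDS count from 1, and bases 3' of the CDS end become `*`-positions
#' (`datum = "cds_end"`).  Intronic offsets pass through unchanged.
#' `c_to_n()` is the exact inverse.
#'
#' @param rec A coding [transcript_record()].
#' @param pos A [base_offset_position()] (`seq_start` datum for `n_to_c`,
#'   CDS-relative for `c_to_n`).
#' @return A [base_offset_position()].
#' @export
n_to_c <- function(rec, pos) {
  if (!rec_is_coding(rec))
    hgvs_error(sprintf("%s is non-coding: c. coordinates are undefined", rec$tx_ac),
               "hgvs_unsupported_error")
  if (!inherits(pos, "base_offset_position") || pos$datum != "seq_start")
    hgvs_error("n_to_c expects a seq_start-datum position", "hgvs_type_error")
  s <- rec$cds_start_n; e <- rec$cds_end_n
  if (pos$base < s) base_offset_position(pos$base - s, pos$offset, "cds_start")
  else if (pos$base <= e) base_offset_position(pos$base - s + 1L, pos$offset, "cds_start")
  else base_offset_position(pos$base - e, pos$offset, "cds_end")
}

#' @rdname n_to_c
#' @export
c_to_n <- function(rec, pos) {
  if (!rec_is_coding(rec))
    hgvs_error(sprintf("%s is non-coding: c. coordinates are undefined", rec$tx_ac),
               "hgvs_unsupported_error")
  if (!inherits(pos, "base_offset_position"))
    hgvs_error("c_to_n expects a base-offset position", "hgvs_type_error")
  s <- rec$cds_start_n; e <- rec$cds_end_n
  n <- switch(pos$datum,
              seq_start = pos$base,
              cds_start = if (pos$base < 0L) pos$base + s else pos$base + s - 1L,
              cds_end = pos$base + e)
  base_offset_position(n, pos$offset, "seq_start")
}
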