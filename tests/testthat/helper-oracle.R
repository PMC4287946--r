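# Independent oracles.  These re-derive expected behaviour through different
# algorithms (per-base expansion, seqinr-based sequence handling) and never
# call the package's mapping internals.

# --- brute-force per-base coordinate table ---------------------------------
# Walks the alignment base by base in transcript orientation, assigning every
# genomic base of the transcript span its transcript coordinate, intronic
# offset and clamp flag.  Returns:
#   $g_tab: data.frame(g, base, offset, gap, exonic)
#   $n_tab: data.frame(n, g, gap)   (one row per transcript base)
oracle_tables <- function(rec) {
  # slots in genomic order: one entry per segment occurrence
  slots <- list()
  for (xi in seq_along(rec$exons)) {
    ex <- rec$exons[[xi]]
    g <- ex$g_start
    for (seg in ex$segments) {
      slots[[length(slots) + 1L]] <-
        list(op = seg$op, len = seg$len,
             g = if (seg$op == "I") NA_integer_ else g)
      if (seg$op != "I") g <- g + seg$len
    }
  }
  minus <- rec$strand == "-"
  order_idx <- if (minus) rev(seq_along(slots)) else seq_along(slots)

  g_all <- integer(0); n_all <- integer(0); gap_all <- logical(0)
  n_tab_n <- integer(0); n_tab_g <- integer(0); n_tab_gap <- logical(0)
  n <- 0L
  last_g <- NA_integer_
  for (si in order_idx) {
    sl <- slots[[si]]
    if (sl$op == "M") {
      gs <- sl$g:(sl$g + sl$len - 1L)
      if (minus) gs <- rev(gs)        # transcript orientation
      for (gb in gs) {
        n <- n + 1L
        g_all <- c(g_all, gb); n_all <- c(n_all, n); gap_all <- c(gap_all, FALSE)
        n_tab_n <- c(n_tab_n, n); n_tab_g <- c(n_tab_g, gb); n_tab_gap <- c(n_tab_gap, FALSE)
        last_g <- gb
      }
    } else if (sl$op == "D") {
      gs <- sl$g:(sl$g + sl$len - 1L)
      if (minus) gs <- rev(gs)
      for (gb in gs) {
        g_all <- c(g_all, gb); n_all <- c(n_all, max(n, 1L)); gap_all <- c(gap_all, TRUE)
      }
    } else {                          # I: transcript-only bases
      for (j in seq_len(sl$len)) {
        n <- n + 1L
        n_tab_n <- c(n_tab_n, n); n_tab_g <- c(n_tab_g, last_g); n_tab_gap <- c(n_tab_gap, TRUE)
      }
    }
  }
  exonic <- data.frame(g = g_all, base = n_all, offset = 0L, gap = gap_all,
                       exonic = TRUE)

  # intron bases: nearest exon boundary, ties to the transcript-5' boundary
  intr <- NULL
  nexon <- length(rec$exons)
  if (nexon > 1L) {
    n_of_g <- stats::setNames(exonic$base, exonic$g)
    for (i in seq_len(nexon - 1L)) {
      gL <- rec$exons[[i]]$g_end
      gR <- rec$exons[[i + 1L]]$g_start
      for (gb in (gL + 1L):(gR - 1L)) {
        dL <- gb - gL; dR <- gR - gb
        if (rec$strand == "+") {
          if (dL <= dR) { b <- n_of_g[[as.character(gL)]]; o <- dL }
          else { b <- n_of_g[[as.character(gR)]]; o <- -dR }
        } else {
          if (dR <= dL) { b <- n_of_g[[as.character(gR)]]; o <- dR }
          else { b <- n_of_g[[as.character(gL)]]; o <- -dL }
        }
        intr <- rbind(intr, data.frame(g = gb, base = b, offset = o, gap = FALSE,
                                       exonic = FALSE))
      }
    }
  }
  g_tab <- rbind(exonic, intr)
  g_tab <- g_tab[order(g_tab$g), , drop = FALSE]
  list(g_tab = g_tab,
       n_tab = data.frame(n = n_tab_n, g = n_tab_g, gap = n_tab_gap))
}

# --- independent fixture reader (seqinr code path) -------------------------
# A second provider implementation over the same on-disk fixture files,
# used to check interface conformance of the primary implementation.
seqinr_provider <- function(dir) {
  ctg <- seqinr::read.fasta(file.path(dir, "contig.fa"), as.string = TRUE, seqonly = FALSE)
  txs <- seqinr::read.fasta(file.path(dir, "transcripts.fa"), as.string = TRUE)
  doc <- jsonlite::fromJSON(file.path(dir, "records.json"), simplifyVector = FALSE)
  seqs <- c(stats::setNames(lapply(ctg, function(s) toupper(as.character(s))), names(ctg)),
            stats::setNames(lapply(txs, function(s) toupper(as.character(s))), names(txs)))
  structure(list(seqs = seqs, records = doc$records), class = "seqinr_provider")
}

get_seq.seqinr_provider <- function(provider, ac, start = 1L, end = NULL) {
  s <- provider$seqs[[ac]]
  if (is.null(s)) stop("unknown accession")
  if (is.null(end)) end <- nchar(s)
  if (start < 1L || end < start || end > nchar(s)) stop("range error")
  substr(s, start, end)
}

find_transcripts.seqinr_provider <- function(provider, ref_ac, g_start, g_end) {
  hits <- Filter(function(r) {
    gs <- min(vapply(r$exons, function(e) e$g_start, integer(1)))
    ge <- max(vapply(r$exons, function(e) e$g_end, integer(1)))
    identical(r$ref_ac, ref_ac) && g_start <= ge && g_end >= gs
  }, provider$records)
  ord <- order(vapply(hits, function(r) paste(r$tx_ac, r$aln_method), character(1)))
  hits[ord]
}

# --- protein translate-and-diff oracle -------------------------------------
# Applies a CDS edit by splicing per-base vectors and translates with seqinr;
# classification mirrors the biological definitions, not the package code.
oracle_protein <- function(tx_seq, cds_start, cds_end, c1, c2, kind, alt = NULL) {
  full <- strsplit(substr(tx_seq, cds_start, nchar(tx_seq)), "")[[1]]
  cds_len <- cds_end - cds_start + 1L
  altv <- if (is.null(alt)) character(0) else strsplit(alt, "")[[1]]
  edited <- switch(kind,
    sub = { x <- full; x[c1] <- altv; x },
    del = full[-(c1:c2)],
    ins = append(full, altv, after = c1),
    delins = append(full[-(c1:c2)], altv, after = c1 - 1L),
    dup = append(full, full[c1:c2], after = c2),
    identity = full)
  dlen <- length(edited) - length(full)

  trans <- function(v, upto = length(v)) {
    v <- v[seq_len(3L * (upto %/% 3L))]
    if (length(v) == 0L) return(character(0))
    aa <- seqinr::translate(tolower(v))
    st <- match("*", aa)
    if (!is.na(st)) aa[seq_len(st)] else aa
  }
  ref_aa <- trans(full, cds_len)
  if (dlen %% 3L == 0L) {
    alt_aa <- trans(edited, cds_len + dlen)
    frameshift <- FALSE
  } else {
    alt_aa <- trans(edited)
    frameshift <- TRUE
  }
  first_diff <- {
    i <- 1L
    while (i <= min(length(ref_aa), length(alt_aa)) && ref_aa[i] == alt_aa[i]) i <- i + 1L
    i
  }
  list(ref_aa = ref_aa, alt_aa = alt_aa, frameshift = frameshift,
       identical = identical(ref_aa, alt_aa), first_diff = first_diff,
       stop_from_first = {
       if (first_diff <= length(alt_aa)) {
         st <- match("*", alt_aa[first_diff:length(alt_aa)])
         if (is.na(st)) NA_integer_ else st
       } else NA_integer_
     })
}

# --- regular-expression decomposition of delins strings --------------------
regex_delins <- function(s) {
  m <- regmatches(s, regexec("^([A-Za-z0-9_.]+):([a-z])\\.([-*0-9_+]+)del([ACGT]*)ins([ACGT]+)$", s))[[1]]
  if (length(m) == 0L) return(NULL)
  list(ac = m[2], type = m[3], pos = m[4],
       ref = if (nzchar(m[5])) m[5] else NULL, alt = m[6])
}
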