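# Random well-formed model objects for property-style tests.  Everything is
# generated through the public constructors, so generated objects are
# canonical: formatting then parsing must reproduce them exactly.

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_seq <- function(n, alpha = c("A", "C", "G", "T")) {
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}

rand_pos_simple <- function() simple_position(sample.int(100000L, 1L))

rand_pos_cds <- function() {
  datum <- sample(c("cds_start", "cds_start", "cds_start", "cds_end"), 1L)
  base <- if (datum == "cds_end") sample.int(500L, 1L)
          else sample(setdiff(-300:500, 0L), 1L)
  offset <- sample(c(0L, 0L, 0L, sample(c(-200:-1, 1:200), 1L)), 1L)
  base_offset_position(base, offset, datum)
}

rand_pos_n <- function() {
  base_offset_position(sample.int(2000L, 1L),
                       sample(c(0L, 0L, 0L, sample(c(-150:-1, 1:150), 1L)), 1L),
                       "seq_start")
}

aa_codes3 <- c("Ala","Arg","Asn","Asp","Cys","Gln","Glu","Gly","His","Ile","Leu",
               "Lys","Met","Phe","Pro","Ser","Thr","Trp","Tyr","Val","Ter")

rand_pos_aa <- function(base = sample.int(5000L, 1L)) {
  aa_position(base, sample(aa_codes3, 1L))
}

# ordered interval from two draws of `gen` (point interval when equal)
rand_interval <- function(gen) {
  a <- gen(); b <- gen()
  if (position_order(a, b) > 0L) hgvs_interval(b, a) else hgvs_interval(a, b)
}

# interval of two adjacent positions, for insertions
rand_ins_interval <- function(kind) {
  if (kind == "simple") {
    b <- sample.int(99999L, 1L)
    hgvs_interval(simple_position(b), simple_position(b + 1L))
  } else {
    datum <- if (kind == "n") "seq_start" else "cds_start"
    b <- if (kind == "n") sample.int(2000L, 1L) else sample(setdiff(-300:500, 0L), 1L)
    if (stats::runif(1) < 0.5) {
      b2 <- if (datum == "cds_start" && b == -1L) 1L else b + 1L
      b2 <- if (b2 == 0L) 1L else b2
      hgvs_interval(base_offset_position(b, 0L, datum),
                    base_offset_position(b2, 0L, datum))
    } else {
      o <- sample(0:100, 1L)
      hgvs_interval(base_offset_position(b, o, datum),
                    base_offset_position(b, o + 1L, datum))
    }
  }
}

rand_nt_edit <- function(kind, alpha = c("A", "C", "G", "T")) {
  switch(kind,
         sub = edit_sub(rand_seq(1L, alpha), rand_seq(1L, alpha)),
         del = edit_del(if (stats::runif(1) < 0.5) rand_seq(sample.int(4L, 1L), alpha)),
         ins = edit_ins(rand_seq(sample.int(5L, 1L), alpha)),
         delins = edit_delins(if (stats::runif(1) < 0.5) rand_seq(sample(2:4, 1L), alpha),
                              rand_seq(sample.int(5L, 1L), alpha)),
         dup = edit_dup(if (stats::runif(1) < 0.5) rand_seq(sample.int(4L, 1L), alpha)),
         identity = edit_identity(if (stats::runif(1) < 0.5) rand_seq(sample.int(3L, 1L), alpha)),
         "repeat" = {
           mn <- sample.int(10L, 1L)
           edit_repeat(rand_seq(sample.int(3L, 1L), alpha), mn,
                       mn + sample(c(0L, 0L, sample.int(5L, 1L)), 1L))
         })
}

rand_accession <- function() {
  paste0(sample(c("NM_", "NC_", "NR_", "ACC", "X"), 1L),
         sample.int(999999L, 1L), ".", sample.int(9L, 1L))
}

nt_edit_kinds <- c("sub", "del", "ins", "delins", "dup", "identity", "repeat")

rand_variant <- function(type = sample(c("g", "m", "c", "n", "r", "p"), 1L)) {
  if (type == "p") return(rand_p_variant())
  alpha <- if (type == "r") c("a", "c", "g", "u") else c("A", "C", "G", "T")
  posgen <- switch(type, g = , m = rand_pos_simple, n = rand_pos_n, rand_pos_cds)
  kind <- sample(nt_edit_kinds, 1L)
  iv <- if (kind == "ins") {
    rand_ins_interval(switch(type, g = , m = "simple", n = "n", "cds"))
  } else if (kind == "sub") {
    hgvs_interval(p <- posgen(), p)
  } else {
    rand_interval(posgen)
  }
  sequence_variant(rand_accession(), type, posedit(iv, rand_nt_edit(kind, alpha)))
}

rand_p_variant <- function() {
  kind <- sample(c("aa_sub", "aa_delins_del", "aa_delins_ins", "aa_delins_sub",
                   "aa_fs", "aa_identity"), 1L)
  inferred <- stats::runif(1) < 0.5
  pe <- switch(kind,
    aa_identity = posedit(NULL, edit_aa_identity(), inferred),
    aa_sub = posedit(hgvs_interval(p <- rand_pos_aa(), p),
                     edit_aa_sub(sample(aa_codes3, 1L)), inferred),
    aa_fs = posedit(hgvs_interval(p <- rand_pos_aa(), p),
                    edit_aa_fs(if (stats::runif(1) < 0.7) sample(setdiff(aa_codes3, "Ter"), 1L),
                               if (stats::runif(1) < 0.5) sample.int(200L, 1L) else NA_integer_),
                    inferred),
    aa_delins_del = posedit(rand_interval(rand_pos_aa), edit_aa_delins(NULL), inferred),
    aa_delins_sub = posedit(rand_interval(rand_pos_aa),
                            edit_aa_delins(sample(aa_codes3, sample.int(4L, 1L), replace = TRUE)),
                            inferred),
    aa_delins_ins = {
      b <- sample.int(4999L, 1L)
      posedit(hgvs_interval(rand_pos_aa(b), rand_pos_aa(b + 1L)),
              edit_aa_delins(sample(aa_codes3, sample.int(4L, 1L), replace = TRUE),
                             ins_only = TRUE), inferred)
    })
  sequence_variant(rand_accession(), "p", pe)
}

# small deterministic provider + fixture shared across test files
toy_provider <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- fixture_provider(toy_locus())
    p
  }
})
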