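test_that("a gapless multi-exon transcript yields the expected block structure", {
  rec <- get_transcript(toy_provider(), "TX1", "CTG1", "splign")
  map <- build_alignment_map(rec)
  expect_identical(map$blocks$kind, c("M", "intron", "M", "intron", "M"))
  rec3 <- get_transcript(toy_provider(), "TX3")
  map3 <- build_alignment_map(rec3)
  expect_identical(sum(map3$blocks$kind %in% c("M", "D", "I")), 5L)  # exon 2 contributes 3
})

test_that("exonic, intronic and gap positions project as specified", {
  p <- toy_provider()
  map <- build_alignment_map(get_transcript(p, "TX1", "CTG1", "splign"))
  expect_identical(g_to_n(map, 150),
                   data.frame(base = 50L, offset = 0L, gap = FALSE))
  expect_identical(g_to_n(map, 250),
                   data.frame(base = 100L, offset = 50L, gap = FALSE))
  expect_identical(g_to_n(map, 251),
                   data.frame(base = 101L, offset = -50L, gap = FALSE))
  expect_identical(n_to_g(map, 50), data.frame(g = 150L, gap = FALSE))
  expect_error(g_to_n(map, 50), class = "hgvs_range_error")
  expect_error(n_to_g(map, 301), class = "hgvs_range_error")

  # genome-only (D) discrepancy: clamp 5' with the gap flag raised
  map3 <- build_alignment_map(get_transcript(p, "TX3"))
  got <- g_to_n(map3, 342)
  expect_identical(got$base, 140L)
  expect_true(got$gap)

  # transcript-only (I) discrepancy: n.41/n.42 clamp to the genomic boundary
  map4 <- build_alignment_map(get_transcript(p, "TX4"))
  got4 <- n_to_g(map4, c(40, 41, 42, 43))
  expect_identical(got4$g, c(140L, 140L, 140L, 141L))
  expect_identical(got4$gap, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("CDS arithmetic is exact and inverse over the whole transcript", {
  rec <- get_transcript(toy_provider(), "TX1", "CTG1", "splign")
  # cds 21..260 on a 300-base transcript
  expect_identical(format(n_to_c(rec, base_offset_position(21, 0, "seq_start"))), "1")
  expect_identical(format(n_to_c(rec, base_offset_position(20, 0, "seq_start"))), "-1")
  expect_identical(format(n_to_c(rec, base_offset_position(50, 0, "seq_start"))), "30")
  expect_identical(format(n_to_c(rec, base_offset_position(263, 0, "seq_start"))), "*3")
  for (n in 1:300) {
    npos <- base_offset_position(n, 0L, "seq_start")
    cpos <- n_to_c(rec, npos)
    expect_identical(c_to_n(rec, cpos), npos)
    # arithmetic oracle: piecewise-linear with no position 0
    s <- rec$cds_start_n; e <- rec$cds_end_n
    want <- if (n < s) n - s else if (n <= e) n - s + 1L else n - e
    expect_identical(cpos$base, want)
    expect_identical(cpos$datum, if (n > e) "cds_end" else "cds_start")
  }
  rec3 <- get_transcript(toy_provider(), "TX3")
  expect_error(n_to_c(rec3, base_offset_position(5, 0, "seq_start")),
               class = "hgvs_unsupported_error")
})

test_that("mapping agrees with the brute-force per-base table on random fixtures", {
  n_fix <- 100L
  for (s in seq_len(n_fix)) {
    nex <- 2L + (s %% 3L)
    cfg <- locus_config(
      n_transcripts = 1L, exons_per_tx = nex,
      exon_len = c(40L, 80L), intron_len = c(20L, 60L), intergenic = c(30L, 60L),
      cds_start_exon = if (s %% 3L == 0L) 2L else 1L,   # CDS start not in exon 1
      strands = if (s %% 2L) "-" else "+",
      indels = list(count = s %% 3L, len = c(1L, 4L), ops = c("D", "I")))
    fx <- generate_locus(cfg, seed = 20000L + s)
    rec <- fx$records[[1]]
    map <- build_alignment_map(rec)
    tab <- oracle_tables(rec)

    got <- g_to_n(map, tab$g_tab$g)
    expect_identical(got$base, tab$g_tab$base)
    expect_identical(got$offset, tab$g_tab$offset)
    expect_identical(got$gap, tab$g_tab$gap)

    inv <- n_to_g(map, tab$n_tab$n)
    expect_identical(inv$g, tab$n_tab$g)
    expect_identical(inv$gap, tab$n_tab$gap)

    # bijectivity on aligned (M) bases
    mb <- tab$g_tab[tab$g_tab$exonic & !tab$g_tab$gap, ]
    expect_identical(n_to_g(map, mb$base)$g, mb$g)
  }
})

test_that("minus-strand mapping mirrors the plus-strand fixture", {
  # same geometry, opposite strands: n coordinates must reflect
  mk <- function(strand) {
    transcript_record("TXS", "G", strand, "CTG",
                      list(list(g_start = 11L, g_end = 40L),
                           list(g_start = 61L, g_end = 100L)))
  }
  mp <- build_alignment_map(mk("+"))
  mm <- build_alignment_map(mk("-"))
  L <- 70L
  for (g in c(11:40, 61:100)) {
    np <- g_to_n(mp, g)$base
    nm <- g_to_n(mm, g)$base
    expect_identical(nm, L - np + 1L)
  }
})

test_that("variant projection composes the table with CDS arithmetic", {
  p <- toy_provider()
  ref <- get_seq(p, "TX1", 50, 50)
  v <- parse_hgvs(sprintf("TX1:c.30%s>T", ref))
  gv <- c_to_g(v, p, aln_method = "splign")
  expect_identical(gv$ac, "CTG1")
  expect_identical(gv$posedit$pos$start$base, 150L)
  expect_identical(gv$posedit$edit$ref, ref)
  # round trip back to the same transcript
  expect_identical(format(g_to_c(gv, "TX1", p, aln_method = "splign")), format(v))

  # intronic source: position carries its offset through to the genome
  iv <- parse_hgvs("TX1:c.80+50A>C")
  gv2 <- suppressWarnings(c_to_g(iv, p, aln_method = "splign"))
  expect_identical(gv2$posedit$pos$start$base, 250L)
})

test_that("minus-strand variants are reverse-complemented on projection", {
  p <- toy_provider()
  ref <- get_seq(p, "TX5", 30, 30)  # c.10 = n.30
  v <- parse_hgvs(sprintf("TX5:c.10%s>G", ref))
  gv <- c_to_g(v, p)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_identical(gv$posedit$edit$ref, unname(comp[ref]))
  expect_identical(gv$posedit$edit$alt, "C")
  expect_identical(format(g_to_c(gv, "TX5", p)), format(v))
  # multi-base edit: endpoints swap so start <= end on the genome
  d <- parse_hgvs("TX5:c.10_12del")
  gd <- c_to_g(d, p)
  expect_lt(gd$posedit$pos$start$base, gd$posedit$pos$end$base)
})

test_that("liftover between transcripts goes through the shared reference", {
  p <- toy_provider()
  ref <- get_seq(p, "TX1", 50, 50)
  v <- parse_hgvs(sprintf("TX1:c.30%s>T", ref))
  lifted <- liftover(v, "TX2", p)
  # brute-force composition: n(TX1) -> g -> n(TX2) -> c(TX2)
  rec1 <- get_transcript(p, "TX1", "CTG1", "splign")
  rec2 <- get_transcript(p, "TX2", "CTG1", "splign")
  g <- n_to_g(build_alignment_map(rec1), c_to_n(rec1, v$posedit$pos$start)$base)$g
  n2 <- g_to_n(build_alignment_map(rec2), g)$base
  want <- n_to_c(rec2, base_offset_position(n2, 0L, "seq_start"))
  expect_identical(lifted$posedit$pos$start$base, want$base)
  expect_identical(lifted$ac, "TX2")
  expect_identical(lifted$posedit$edit, v$posedit$edit)  # plus strand: unchanged

  # identity liftover
  same <- liftover(v, "TX1", p, from_aln = "splign", to_aln = "splign")
  expect_identical(format(same), format(v))
  # unknown target
  expect_error(liftover(v, "TXnope", p), class = "hgvs_liftover_error")
})

test_that("liftover between alignment methods moves boundary-adjacent variants only", {
  p <- toy_provider()
  # interior variant: same representation under splign and blat
  ref <- get_seq(p, "TX1", 50, 50)
  v <- parse_hgvs(sprintf("TX1:c.30%s>T", ref))
  v_blat <- liftover(v, "TX1", p, from_aln = "splign", to_aln = "blat")
  expect_identical(format(v_blat), format(v))
  # boundary-adjacent: splign exon 1 ends at n.100 (g.200); under blat g.200
  # is intronic (its exon 1 ends at g.198), so the representation changes
  refb <- get_seq(p, "TX1", 100, 100)
  vb <- parse_hgvs(sprintf("TX1:c.80%s>A", refb))      # c.80 = n.100
  vb2 <- suppressWarnings(liftover(vb, "TX1", p, from_aln = "splign", to_aln = "blat"))
  expect_false(identical(format(vb2), format(vb)))
  expect_true(vb2$posedit$pos$start$offset != 0L)       # intronic under blat
})

test_that("edits spanning a splice boundary map positionally with a warning", {
  p <- toy_provider()
  v <- parse_hgvs("TX1:c.80_80+2del")   # crosses the exon 1 / intron 1 boundary
  expect_warning(gv <- c_to_g(v, p, aln_method = "splign"), class = "hgvs_splice_warning")
  expect_identical(gv$posedit$pos$start$base, 200L)
  expect_identical(gv$posedit$pos$end$base, 202L)
  # positions inside a D discrepancy surface the clamp as a warning
  gvar <- parse_hgvs("CTG1:g.342A>T")
  gvar$posedit$edit$ref <- get_seq(p, "CTG1", 342, 342)
  expect_warning(g_to_c(gvar, "TX3", p), class = "hgvs_gap_warning")
})

test_that("map_variant dispatches across coordinate systems", {
  p <- toy_provider()
  ref <- get_seq(p, "TX1", 50, 50)
  v <- parse_hgvs(sprintf("TX1:c.30%s>T", ref))
  expect_identical(map_variant(v, "g", p)$type, "g")
  expect_identical(map_variant(v, "p", p)$type, "p")
  expect_identical(map_variant(v, "n", p)$posedit$pos$start$base, 50L)
  expect_identical(format(map_variant(v, "r", p)),
                   sprintf("TX1:r.30%s>u", chartr("ACGT", "acgu", ref)))
  gv <- map_variant(v, "g", p)
  expect_identical(format(map_variant(gv, "c", p, tx_ac = "TX1", aln_method = "splign")),
                   format(v))
  expect_error(map_variant(v, "q", p), class = "hgvs_error")
})
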