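test_that("get_seq slices match the stored sequences exactly", {
  p <- toy_provider()
  fx <- toy_locus()
  first <- substr(fx$contig_seq, 1, 1)
  expect_identical(get_seq(p, "CTG1", 1, 1), first)
  expect_identical(get_seq(p, "CTG1"), fx$contig_seq)
  expect_identical(get_seq(p, "TX1"), fx$tx_seqs$TX1)
  expect_error(get_seq(p, "CTG1", 5, 4), class = "hgvs_range_error")
  expect_error(get_seq(p, "CTG1", 0, 4), class = "hgvs_range_error")
  expect_error(get_seq(p, "CTG1", 1, 10^6), class = "hgvs_range_error")
  expect_error(get_seq(p, "NOPE", 1, 1), class = "hgvs_unknown_accession_error")
})

test_that("transcript lookup distinguishes unknown transcripts from unknown alignments", {
  p <- toy_provider()
  rec <- get_transcript(p, "TX1", "CTG1", "splign")
  expect_s3_class(rec, "transcript_record")
  expect_length(rec$exons, 3L)
  expect_error(get_transcript(p, "TXnope"), class = "hgvs_unknown_transcript_error")
  expect_error(get_transcript(p, "TX1", "CTG1", "nosuch"),
               class = "hgvs_unknown_aln_method_error")
  expect_identical(get_alignment_methods(p, "TX1", "CTG1"), c("blat", "splign"))
  expect_identical(get_protein_accession(p, "TX1"), "PRO_TX1")
  expect_error(get_protein_accession(p, "TX3"), class = "hgvs_unknown_accession_error")
  expect_match(get_data_version(p), "fixture")
})

test_that("find_transcripts returns exactly the overlapping records, in order", {
  p <- toy_provider()
  inside_tx1_exon2 <- find_transcripts(p, "CTG1", 350, 350)
  expect_true("TX1" %in% vapply(inside_tx1_exon2, function(r) r$tx_ac, character(1)))
  expect_identical(find_transcripts(p, "CTG1", 2000, 2100), list())
  expect_error(find_transcripts(p, "NOPE", 1, 10), class = "hgvs_unknown_accession_error")

  # sweep: the union of hits over tiling windows covers every record exactly
  fx <- toy_locus()
  windows <- seq(1, 1500, by = 50)
  seen <- character(0)
  for (w in windows) {
    for (r in find_transcripts(p, "CTG1", w, w + 49)) {
      sp <- c(r$exons[[1]]$g_start, r$exons[[length(r$exons)]]$g_end)
      expect_true(w <= sp[2] && w + 49 >= sp[1])
      seen <- c(seen, paste(r$tx_ac, r$aln_method))
    }
  }
  all_keys <- vapply(fx$records, function(r) paste(r$tx_ac, r$aln_method), character(1))
  expect_setequal(unique(seen), all_keys)
})

test_that("generated fixtures are deterministic and self-consistent", {
  a <- generate_locus(locus_config(), seed = 42)
  b <- generate_locus(locus_config(), seed = 42)
  expect_identical(a, b)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  write_locus(a, d1); write_locus(b, d2)
  for (f in c("contig.fa", "transcripts.fa", "records.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  expect_false(identical(generate_locus(locus_config(), seed = 43), a))
})

test_that("fixture invariants hold across random seeds and feature mixes", {
  for (s in 1:40) {
    nex <- 1L + (s %% 4L)
    cfg <- locus_config(
      n_transcripts = 1L + (s %% 2L), exons_per_tx = nex,
      cds_start_exon = if (nex >= 2L && s %% 3L == 0L) 2L else 1L,
      strands = if (s %% 2L) c("+", "-") else NULL,
      coding = s %% 4L != 1L,
      indels = list(count = s %% 3L, len = c(1L, 4L), ops = c("D", "I")))
    fx <- generate_locus(cfg, seed = 1000L + s)
    expect_true(check_locus_fixture(fx))
    for (rec in fx$records) {
      expect_identical(tx_length(rec), nchar(fx$tx_seqs[[rec$tx_ac]]))
      if (!is.na(rec$cds_start_n))
        expect_identical((rec$cds_end_n - rec$cds_start_n + 1L) %% 3L, 0L)
    }
  }
})

test_that("a D segment shortens and an I segment lengthens the transcript", {
  cfg_d <- locus_config(n_transcripts = 1L, strands = "+",
                        indels = list(count = 1L, len = c(3L, 3L), ops = "D"))
  fx <- generate_locus(cfg_d, seed = 7)
  rec <- fx$records[[1]]
  g_len <- sum(vapply(rec$exons, function(e) e$g_end - e$g_start + 1L, integer(1)))
  expect_identical(nchar(fx$tx_seqs[[rec$tx_ac]]), g_len - 3L)

  cfg_i <- locus_config(n_transcripts = 1L, strands = "+",
                        indels = list(count = 1L, len = c(2L, 2L), ops = "I"))
  fx2 <- generate_locus(cfg_i, seed = 7)
  rec2 <- fx2$records[[1]]
  g_len2 <- sum(vapply(rec2$exons, function(e) e$g_end - e$g_start + 1L, integer(1)))
  expect_identical(nchar(fx2$tx_seqs[[rec2$tx_ac]]), g_len2 + 2L)
})

test_that("minus-strand transcripts store the reverse complement of their exons", {
  cfg <- locus_config(n_transcripts = 1L, strands = "-", indels = list(count = 0L))
  fx <- generate_locus(cfg, seed = 17)
  rec <- fx$records[[1]]
  expect_identical(rec$strand, "-")
  spliced <- paste(vapply(rec$exons, function(e)
    substr(fx$contig_seq, e$g_start, e$g_end), character(1)), collapse = "")
  # independent reverse-complement via Biostrings on the spliced genomic seq
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(spliced)))
  expect_identical(fx$tx_seqs[[rec$tx_ac]], rc)
})

test_that("an independent reader of the fixture files answers identically", {
  fx <- generate_locus(locus_config(n_transcripts = 2L,
                                    indels = list(count = 1L, len = c(1L, 3L),
                                                  ops = c("D", "I"))), seed = 4242)
  dir <- file.path(tempdir(), "fx-conf")
  write_locus(fx, dir)
  p1 <- fixture_provider(read_locus(dir))
  p2 <- seqinr_provider(dir)

  for (ac in c("CTG1", names(fx$tx_seqs))) {
    len <- nchar(get_seq(p1, ac))
    expect_identical(get_seq(p1, ac), get_seq(p2, ac))
    st <- sample.int(len - 5L, 3L)
    for (s in st) expect_identical(get_seq(p1, ac, s, s + 4L), get_seq(p2, ac, s, s + 4L))
  }
  for (w in seq(1, 2500, by = 100)) {
    h1 <- vapply(find_transcripts(p1, "CTG1", w, w + 99L),
                 function(r) paste(r$tx_ac, r$aln_method), character(1))
    h2 <- vapply(find_transcripts(p2, "CTG1", w, w + 99L),
                 function(r) paste(r$tx_ac, r$aln_method), character(1))
    expect_identical(h1, h2)
  }
  # repeated queries return equal results (read-only view)
  expect_identical(get_seq(p1, "TX1", 3, 9), get_seq(p1, "TX1", 3, 9))
})
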