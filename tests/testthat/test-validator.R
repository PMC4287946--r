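test_that("intrinsic validation implements the documented truth table", {
  ok <- function(s) expect_true(report_ok(validate_intrinsic(parse_hgvs(s))), label = s)
  bad <- function(s, code) {
    rep <- validate_intrinsic(parse_hgvs(s))
    expect_identical(rep$level, "error", label = s)
    expect_true(code %in% vapply(rep$findings, `[[`, character(1), "code"),
                label = paste(s, "->", code))
  }
  ok("NM_001197320.1:c.281C>T")
  ok("X:g.5_6insT")
  ok("NM_1.1:c.688_688+1insT")     # exonic/intronic flanking pair
  ok("NM_1.1:c.689-1_689insT")
  ok("X:g.5_7delGTA")
  ok("X:g.5_7del")
  ok("X:g.5dup")
  bad("X:g.7_5del", "start_gt_end")
  bad("X:g.10_10insA", "ins_span")
  bad("X:g.10_12insA", "ins_span")
  bad("X:g.5_7delGT", "ref_length")
  bad("X:g.5delGT", "ref_length")
  bad("NM_1.1:c.688_688+2insT", "ins_span")
})

test_that("the insertion rule accepts exactly interval length one", {
  # exhaustive span sweep: an insertion is valid iff its flanks are adjacent
  for (span in 0:3) {
    v <- sequence_variant("X", "g",
                          posedit(hgvs_interval(simple_position(10L),
                                                simple_position(10L + span),
                                                validate = FALSE),
                                  edit_ins("A")))
    expect_identical(report_ok(validate_intrinsic(v)), span == 1L)
  }
  # and the same table for deletions/identity, where any span is legal
  for (span in 0:3) {
    for (mk in list(edit_del(), edit_identity())) {
      v <- sequence_variant("X", "g",
                            posedit(hgvs_interval(simple_position(10L),
                                                  simple_position(10L + span),
                                                  validate = FALSE), mk))
      expect_true(report_ok(validate_intrinsic(v)))
    }
  }
  # substitutions must be single-base
  v2 <- sequence_variant("X", "g",
                         posedit(hgvs_interval(simple_position(10L), simple_position(11L),
                                               validate = FALSE),
                                 edit_sub("A", "T")))
  expect_false(report_ok(validate_intrinsic(v2)))
})

test_that("alphabet mismatches surface as intrinsic findings on unchecked objects", {
  pe <- posedit(hgvs_interval(base_offset_position(5)), edit_sub("c", "u"))
  v <- sequence_variant("NM_1.1", "c", pe, validate = FALSE)
  rep <- validate_intrinsic(v)
  expect_identical(rep$level, "error")
  expect_true("alphabet" %in% vapply(rep$findings, `[[`, character(1), "code"))
})

test_that("extrinsic validation checks the stated reference against the provider", {
  p <- toy_provider()
  # the worked invalid-reference example: stated A, transcript has C
  ref281 <- get_seq(p, "TX2", 281 + 9, 281 + 9)   # c.281 = n.290 on TX2 (cds 10)
  wrong <- setdiff(c("A", "C", "G", "T"), ref281)[1]
  good <- parse_hgvs(sprintf("TX2:c.281%s>T", ref281))
  bad <- parse_hgvs(sprintf("TX2:c.281%s>T", wrong))
  expect_true(report_ok(validate_variant(good, p)))
  repb <- validate_variant(bad, p)
  expect_identical(repb$level, "error")
  expect_identical(repb$findings[[1]]$code, "ref_mismatch")

  # bounds and unknown accessions are findings, not conditions
  expect_identical(validate_variant(parse_hgvs("TX1:c.5000A>T"), p)$findings[[1]]$code,
                   "out_of_bounds")
  expect_identical(validate_variant(parse_hgvs("NOPE:g.5A>T"), p)$findings[[1]]$code,
                   "unknown_accession")
  expect_identical(validate_variant(parse_hgvs("CTG1:g.999999A>T"), p)$findings[[1]]$code,
                   "out_of_bounds")

  # intronic positions are validated through the genomic projection of the
  # named alignment (splign and blat place this boundary differently)
  gref <- get_seq(p, "CTG1", 250, 250)
  okv <- parse_hgvs(sprintf("TX1:c.80+50%s>%s", gref, setdiff(c("A","C","G","T"), gref)[1]))
  expect_true(report_ok(validate_variant(okv, p, aln_method = "splign")))
  wrongg <- setdiff(c("A", "C", "G", "T"), gref)[1]
  badv <- parse_hgvs(sprintf("TX1:c.80+50%s>A", wrongg))
  expect_identical(validate_variant(badv, p, aln_method = "splign")$findings[[1]]$code,
                   "ref_mismatch")

  # minus strand: the stated base is in transcript orientation
  t5 <- get_seq(p, "TX5", 30, 30)
  expect_true(report_ok(validate_variant(
    parse_hgvs(sprintf("TX5:c.10%s>%s", t5, setdiff(c("A","C","G","T"), t5)[1])), p)))
})

test_that("every provider-derived variant validates; any ref mutation flips it", {
  p <- toy_provider()
  set.seed(2024)
  n <- 1000L
  acs <- c("CTG1", "TX1", "TX2", "TX5")
  for (i in seq_len(n)) {
    ac <- sample(acs, 1L)
    len <- nchar(get_seq(p, ac))
    pos <- sample.int(len - 3L, 1L)
    span <- sample.int(3L, 1L)
    ref <- get_seq(p, ac, pos, pos + span - 1L)
    type <- if (ac == "CTG1") "g" else "n"
    s <- if (span == 1L)
      sprintf("%s:%s.%d%s>%s", ac, type, pos, ref, sample(c("A","C","G","T"), 1L))
    else
      sprintf("%s:%s.%d_%ddel%s", ac, type, pos, pos + span - 1L, ref)
    v <- parse_hgvs(s)
    expect_true(report_ok(validate_variant(v, p)), label = s)

    # mutate one stated ref base to a different base: must flip to error
    j <- sample.int(span, 1L)
    base_j <- substr(ref, j, j)
    mut <- ref
    substr(mut, j, j) <- sample(setdiff(c("A", "C", "G", "T"), base_j), 1L)
    v$posedit$edit$ref <- mut
    rep <- validate_variant(v, p)
    expect_identical(rep$level, "error", label = paste("mutated", s))
  }
})

test_that("protein-level extrinsic validation checks the translated residue", {
  p <- toy_provider()
  aa <- get_seq(p, "PRO_TX1", 5, 5)
  mk <- function(a) sequence_variant("PRO_TX1", "p",
                                     posedit(hgvs_interval(aa_position(5, a)),
                                             edit_aa_sub("Gly")))
  expect_true(report_ok(validate_variant(mk(aa), p)))
  other <- setdiff(c("A", "R", "N", "D"), aa)[1]
  expect_identical(validate_variant(mk(other), p)$findings[[1]]$code, "ref_aa_mismatch")
})

test_that("validation short-circuits: extrinsic is skipped after intrinsic failure", {
  p <- toy_provider()
  v <- parse_hgvs("TX1:c.7_5del")    # intrinsically broken AND unknown span
  rep <- validate_variant(v, p)
  codes <- vapply(rep$findings, `[[`, character(1), "code")
  expect_identical(codes, "start_gt_end")   # no extrinsic findings follow
  # intrinsic validation needs no provider and is pure
  expect_identical(validate_intrinsic(v), validate_intrinsic(v))
})
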