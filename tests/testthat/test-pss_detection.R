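# Frozen expected values in this file were computed with the enumeration
# oracles in helper-oracles.R before being asserted.

make_pair <- function(fl, fr, id = "sv") {
  structure(list(sv_id = id, flank_left = fl, flank_right = fr),
            class = "FlankPair")
}

test_that("extract_flanks honours the inward convention", {
  cfg <- sim_config(seed = 7, n_sv_case = 5, n_sv_control = 0)
  sim <- plant_structural_variants(simulate_locus(cfg), cfg)
  pcfg <- pss_config()
  sv <- sim$svs[1, ]
  tr <- sim$truth[sim$truth$sv_id == sv$id, ]
  pair <- extract_flanks(sv, sim$locus, pcfg)
  expect_equal(nchar(pair$flank_left), 20L)
  expect_equal(nchar(pair$flank_right), 20L)
  expect_true(startsWith(pair$flank_left, tr$motif_seq))
  expect_true(startsWith(pair$flank_right, tr$motif_seq))

  # DEL vs INV with identical breakpoints give identical flanks (inner mode)
  sv_inv <- sv; sv_inv$svtype <- "INV"
  pair2 <- extract_flanks(sv_inv, sim$locus, pcfg)
  expect_identical(pair2$flank_left, pair$flank_left)
  expect_identical(pair2$flank_right, pair$flank_right)

  # breakpoint too close to the contig end is a logged skip, not an error
  sv_edge <- structural_variants("edge", "DEL", 42995L, 42999L)
  expect_message(res <- extract_flanks(sv_edge, sim$locus, pcfg), "skipping")
  expect_null(res)

  # outer mode reads away from the segment
  ocfg <- pss_config(flank_mode = "outer")
  pair3 <- extract_flanks(sv, sim$locus, ocfg)
  expect_identical(
    pair3$flank_left,
    reverse_complement(substr(sim$locus$sequence, sv$left_bp - 19, sv$left_bp)))
})

test_that("best_inverted_alignment finds designed optima", {
  cfg <- pss_config()
  # identical 10-base prefix, tails built to mismatch everywhere
  fl <- paste0("GGGACAGCCA", "AAAAAAAAAA")
  fr <- paste0("GGGACAGCCA", "CCCCCCCCCC")
  aln <- best_inverted_alignment(make_pair(fl, fr), cfg)
  expect_equal(aln$offset_left, 0L)
  expect_equal(aln$offset_right, 0L)
  expect_equal(aln$aligned_len, 10L)
  expect_equal(aln$identity, 1.0)
  expect_true(aln$passed)

  # one substitution inside the 10-mer: identity 9/10
  fr2 <- paste0("GGCACAGCCA", "CCCCCCCCCC")
  aln2 <- best_inverted_alignment(make_pair(fl, fr2), cfg)
  expect_equal(aln2$aligned_len, 10L)
  expect_equal(aln2$identity, 0.9)

  # equal flanks: full-length perfect alignment
  aln3 <- best_inverted_alignment(make_pair(fl, fl), cfg)
  expect_equal(aln3$aligned_len, 20L)
  expect_equal(aln3$identity, 1.0)

  # N never counts as a match
  alnN <- best_inverted_alignment(
    make_pair(strrep("N", 20), strrep("N", 20)), cfg)
  expect_equal(alnN$matches, 0L)
  expect_false(alnN$passed)
})

test_that("best_inverted_alignment equals brute-force enumeration", {
  cfg <- pss_config()
  withr::with_seed(20, {
    for (i in 1:200) {
      fl <- random_flank(); fr <- random_flank()
      got <- best_inverted_alignment(make_pair(fl, fr), cfg)
      want <- oracle_best_alignment(fl, fr, cfg)
      expect_equal(got$identity, want$identity)
      expect_equal(got$aligned_len, want$len)
      expect_equal(got$offset_left, want$ol)
      expect_equal(got$offset_right, want$or)

      # symmetry: swapping flanks swaps offsets, preserves the rest
      sw <- best_inverted_alignment(make_pair(fr, fl), cfg)
      expect_equal(sw$identity, got$identity)
      expect_equal(sw$aligned_len, got$aligned_len)
    }
  })
  # the full-window denominator option divides by flank_window
  wcfg <- pss_config(identity_denominator = "window")
  fl <- paste0("GGGACAGCCA", "AAAAAAAAAA")
  fr <- paste0("GGGACAGCCA", "CCCCCCCCCC")
  alnw <- best_inverted_alignment(make_pair(fl, fr), wcfg)
  expect_equal(alnw$identity, alnw$matches / 20)
})

test_that("repeat filter matches its definition and the scanning oracle", {
  expect_true(has_disqualifying_repeat("AAAAAA"))
  expect_false(has_disqualifying_repeat("AAAAA"))
  expect_true(has_disqualifying_repeat("ACACAC"))
  expect_false(has_disqualifying_repeat("ACACA"))
  expect_false(has_disqualifying_repeat("GGGACAGCCA"))
  expect_true(has_disqualifying_repeat("TTGCATGCATG"))   # GCAT x2 + partial, tract 9
  expect_false(has_disqualifying_repeat("TTGCATGGA"))
  expect_error(has_disqualifying_repeat(""), "empty")

  withr::with_seed(31, {
    for (i in 1:300) {
      s <- random_flank(sample(6:20, 1))
      expect_identical(has_disqualifying_repeat(s), oracle_has_repeat(s),
                       info = s)
      expect_identical(has_disqualifying_repeat(reverse_complement(s)),
                       has_disqualifying_repeat(s), info = s)
    }
  })
})

test_that("control subtraction removes only control-like candidates", {
  cfg <- pss_config()
  cand <- data.frame(
    sv_id = c("a", "a"), side = c("left", "right"),
    sequence = c("TGGCTGTCCCTGGA", "TGGCTGTCCCTGGA"),
    offset_left = 0L, offset_right = 0L, aligned_len = 14L,
    identity = 1, control_hit = FALSE, stringsAsFactors = FALSE)

  expect_identical(subtract_control(cand, list(), cfg)$sv_id, cand$sv_id)

  # a control pair identical to the candidate's own pair removes it:
  # its aligned left-flank equals the candidate inward sequence
  inward <- reverse_complement(cand$sequence[1])
  ctrl_pair <- make_pair(paste0(inward, "AAAAAA"), paste0(inward, "CCCCCC"),
                         id = "ctrl1")
  out <- subtract_control(cand, list(ctrl_pair), cfg)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "removed")$control_id, c("ctrl1", "ctrl1"))

  # a non-passing control pair (no inverted identity) removes nothing
  null_pair <- make_pair(strrep("A", 20), strrep("C", 20), id = "ctrl2")
  expect_equal(nrow(subtract_control(cand, list(null_pair), cfg)), 2L)

  # cohort mode: any passing control pair empties the candidate set
  ccfg <- pss_config(control_mode = "cohort")
  expect_equal(nrow(subtract_control(cand, list(ctrl_pair, null_pair), ccfg)), 0L)

  # never increases the candidate set
  expect_lte(nrow(subtract_control(cand, list(ctrl_pair), cfg)), nrow(cand))
})

test_that("detect_pss recovers planted SVs and reports 3'-anchored sequences", {
  empty_sv <- structural_variants(character(), character(), integer(), integer())
  cfg <- sim_config(seed = 7, n_sv_case = 20, n_sv_control = 20)
  sim <- plant_structural_variants(simulate_locus(cfg), cfg)
  case <- sim$svs[sim$svs$cohort == "case", ]
  ctrl <- sim$svs[sim$svs$cohort == "control", ]

  expect_equal(nrow(detect_pss(empty_sv, ctrl, sim$locus)), 0L)

  cand <- detect_pss(case, ctrl, sim$locus)
  expect_setequal(unique(cand$sv_id), case$id)
  expect_equal(nrow(cand), 2L * nrow(case))
  expect_setequal(unique(cand$side), c("left", "right"))
  # reporting orientation: breakpoint at the 3' terminus -> reverse
  # complement of the planted inward motif is a suffix-anchored match
  for (i in seq_len(nrow(case))) {
    tr <- sim$truth[sim$truth$sv_id == case$id[i], ]
    seqs <- cand$sequence[cand$sv_id == case$id[i]]
    expect_true(all(endsWith(seqs, reverse_complement(tr$motif_seq))))
  }
  # candidate length bookkeeping
  side_off <- ifelse(cand$side == "left", cand$offset_left, cand$offset_right)
  expect_equal(nchar(cand$sequence),
               pmin(cand$aligned_len + side_off, 20L))
})

test_that("inactivation classification follows exon overlap rules", {
  loc <- toy_locus()   # exons [100,160) and [250,300)
  ex <- loc$exons
  sv1 <- structural_variants("d1", "DEL", 90L, 170L)    # spans exon 1
  sv2 <- structural_variants("d2", "DEL", 170L, 240L)   # fully intronic
  sv3 <- structural_variants("i1", "INV", 170L, 240L)   # intronic inversion
  # intronic left breakpoint inside the gene body, segment covers exon 2;
  # an inversion spanning the *whole* gene (both breakpoints outside the
  # body) would leave the gene intact and is not inactivating
  sv4 <- structural_variants("i2", "INV", 170L, 310L)
  sv5 <- structural_variants("t1", "TRA", 120L, 50L, partner_contig = "partner")
  sv6 <- structural_variants("t2", "TRA", 200L, 50L, partner_contig = "partner")
  sv7 <- structural_variants("u1", "DUP", 255L, 400L)   # touches exon 2

  expect_true(classify_inactivating(sv1, ex))
  expect_false(classify_inactivating(sv2, ex))
  expect_false(classify_inactivating(sv3, ex))
  expect_true(classify_inactivating(sv4, ex))
  expect_true(classify_inactivating(sv5, ex))   # anchor inside exon 1
  expect_false(classify_inactivating(sv6, ex))
  expect_true(classify_inactivating(sv7, ex))

  svs <- rbind(sv1, sv2, sv3, sv4, sv5, sv6, sv7)
  s <- summarize_cohort(svs, ex)
  expect_equal(s$total, 7L)
  expect_equal(s$inactivating, 4L)
  # independent interval-overlap tally for the non-TRA calls
  plain <- svs[svs$svtype %in% c("DEL", "DUP"), ]
  oracle <- sum(vapply(seq_len(nrow(plain)), function(i)
    any(ex$start < plain$right_bp[i] & ex$end > plain$left_bp[i]), logical(1)))
  expect_equal(oracle, 2L)

  empty_sv <- structural_variants(character(), character(), integer(), integer())
  e <- summarize_cohort(empty_sv, ex)
  expect_equal(c(e$inactivating, e$total), c(0L, 0L))
})
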