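CONS <- "PSITKVTRVIEGE"

test_that("period estimation recovers the 13-residue / 39-nt period", {
  p <- estimate_period(bio_seq(strrep(CONS, 6)), max_period = 40, seed = 1)
  expect_equal(as.integer(p), 13L)
  set.seed(21)
  unit <- paste(sample(DNA4, 39, replace = TRUE), collapse = "")
  pd <- estimate_period(bio_seq(strrep(unit, 5), alphabet = "DNA"),
                        max_period = 80, seed = 1)
  expect_equal(as.integer(pd), 39L)
})

test_that("random sequences carry no significant period", {
  fp <- 0L
  for (r in 1:50) {
    s <- bio_seq(random_protein(200, seed = 3000 + r))
    p <- estimate_period(s, max_period = 40, n_shuffles = 30, seed = r)
    if (!is.null(p)) fp <- fp + 1L
  }
  # null threshold is the 99th percentile, so false positives must be rare
  expect_lte(fp, 3L)
})

test_that("exact tandems of any unit length return that length", {
  for (L in seq(5, 40, by = 5)) {
    set.seed(400 + L)
    unit <- paste(sample(AA20, L, replace = TRUE), collapse = "")
    s <- bio_seq(strrep(unit, 4))
    p <- estimate_period(s, max_period = min(2L * L, 4L * L - 1L),
                         n_shuffles = 30, seed = 1)
    expect_equal(as.integer(p), L)
    # oracle: exhaustive lag scan peaks at the same fundamental lag
    sc <- oracle_lag_scores(s$residues, 2L * L)
    expect_equal(min(which(sc >= max(sc) * 0.95)), L)
  }
})

test_that("unit segmentation phases on the anchor and drops flanks", {
  s <- bio_seq(paste0("XX", strrep(CONS, 3), "YY"))
  arr <- segment_units(s, 13)
  expect_equal(arr$units, rep(CONS, 3))
  # absent anchor falls back to a self-similar phase, same unit count
  arr2 <- segment_units(s, 13, anchor_residue = "Q")
  expect_equal(length(arr2$units), 3L)
  expect_error(segment_units(bio_seq("PSITKVTRVIEGEPS"), 13),
               "fewer than 2")
  expect_error(segment_units(s, NULL), "absent")
})

test_that("DNA segmentation keeps the reading frame on length deviations", {
  set.seed(42)
  u <- paste(sample(DNA4, 39, replace = TRUE), collapse = "")
  u42 <- paste0(substr(u, 1, 20), "AAA", substr(u, 21, 39))
  tand <- bio_seq(paste0(u, u42, u, u, u), alphabet = "DNA")
  arr <- segment_units(tand, 39, anchor_residue = NULL)
  expect_true(42 %in% nchar(arr$units))
  expect_true(all(nchar(arr$units) %% 3 == 0))
})

test_that("star alignment handles identical units and records deletions", {
  ident <- align_units(plastex:::repeat_array_from_units(rep(CONS, 4)))
  expect_equal(ident$alignment, rep(CONS, 4))
  expect_equal(nrow(ident$edits), 0L)
  # single-residue insertion in one of several units: deletion wins the
  # two-way comparison when it restores full column agreement
  ins <- "PSITKQVTRVIEGE"
  arr <- align_units(plastex:::repeat_array_from_units(
    c(CONS, CONS, ins, CONS)))
  n <- 4
  # oracle: keeping the insertion scores (matches + 1) - (n - 1) gap chars;
  # deleting scores full agreement with no gap column
  score_insert <- (n * nchar(CONS) + 1) - (n - 1)
  score_delete <- n * nchar(CONS)
  expect_true(score_delete > score_insert)
  expect_equal(nrow(arr$edits), 1L)
  expect_equal(arr$edits$residue, "Q")
  expect_equal(arr$alignment, rep(CONS, 4))
  # with only two units the insertion is kept instead
  arr2 <- align_units(plastex:::repeat_array_from_units(c(CONS, ins)))
  expect_equal(nrow(arr2$edits), 0L)
  expect_true(nchar(arr2$alignment[1]) >= nchar(ins))
})

test_that("alignment width is at least the longest unit", {
  for (seed in 1:5) {
    us <- sample_repeat_units(CONS, 6, 0.15, seed = seed)
    set.seed(seed)
    us[2] <- paste0(substr(us[2], 1, 6), "W", substr(us[2], 7, 13))
    arr <- align_units(plastex:::repeat_array_from_units(us))
    # width covers the longest unit net of any recorded deletion
    net_len <- nchar(us) - tabulate(arr$edits$unit, nbins = length(us))
    expect_gte(nchar(arr$alignment[1]), max(net_len))
    expect_equal(length(unique(nchar(arr$alignment))), 1L)
  }
})

test_that("consensus calling is a per-column majority with tie flags", {
  arr <- plastex:::repeat_array_from_units(c("AAG", "AAG", "CAG"))
  prof <- build_consensus(arr)
  expect_equal(prof$consensus, "AAG")
  single <- build_consensus(plastex:::repeat_array_from_units("PSI"))
  expect_equal(single$consensus, "PSI")
  tie <- build_consensus(plastex:::repeat_array_from_units(c("AC", "CA")))
  expect_true(all(tie$ties))
  expect_equal(tie$consensus, "AA")  # lexicographic tie-break
})

test_that("consensus recovery from 45 diverged units is exact", {
  units <- sample_repeat_units(CONS, 45, 0.1, seed = 7)
  prof <- build_consensus(plastex:::repeat_array_from_units(units))
  expect_equal(prof$consensus, CONS)
  expect_equal(prof$n_units, 45L)
})

test_that("per-locus robustness flags require agreement in every locus", {
  units <- c("AAA", "AAA", "ACA", "ACA")
  loci <- factor(c("l1", "l1", "l2", "l2"))
  prof <- build_consensus(plastex:::repeat_array_from_units(units,
                                                            loci = loci))
  expect_true(prof$robust[1])   # A modal in both loci
  expect_false(prof$robust[2])  # A not modal in locus 2
  expect_true(prof$robust[3])
})

test_that("percent identity counts matches over gap-aware columns", {
  r <- percent_identity("EYTKVTKVIEGEP", "SITKVTRVIEGEP")
  expect_equal(r$matches, 10L)
  expect_equal(r$length, 13L)
  expect_equal(r$percent, 77)
  s <- random_protein(30, seed = 2)
  expect_equal(percent_identity(s, s)$percent, 100)
  expect_equal(percent_identity("AAAA", "CCCC")$percent, 0)
  # gap vs residue is a mismatch; both-gap columns are skipped
  r2 <- percent_identity("A-C-", "AAC-")
  expect_equal(r2$matches, 2L)
  expect_equal(r2$length, 3L)
  expect_error(percent_identity("--", "--"), "zero-length")
  expect_error(percent_identity("AA", "AAA"), "equal")
})

test_that("percent identity is symmetric and complements Hamming distance", {
  for (seed in 1:10) {
    a <- random_protein(25, seed = 6000 + seed)
    b <- random_protein(25, seed = 7000 + seed)
    ab <- percent_identity(a, b)
    expect_equal(ab$matches, percent_identity(b, a)$matches)
    hamming <- sum(chars(a) != chars(b))
    expect_equal(ab$matches, 25L - hamming)
  }
})

test_that("consensus rotation and doubling match the printed forms", {
  expect_equal(rotate_consensus(CONS, 1), "SITKVTRVIEGEP")
  expect_equal(rotate_consensus(CONS, 0), CONS)
  for (k in 1:12) {
    expect_equal(rotate_consensus(rotate_consensus(CONS, k), 13 - k), CONS)
  }
  expect_error(rotate_consensus(CONS, 13), "range")
  expect_equal(nchar(doubled_consensus(CONS)), 26L)
  expect_equal(doubled_consensus("A"), "AA")
  expect_error(doubled_consensus(""), "empty")
})

test_that("logo information content matches the closed forms", {
  # invariant column
  lm <- logo_matrix(c("AAAA", "AAAA", "AAAA"))
  expect_equal(unique(lm$ic), log2(20), tolerance = 1e-12)
  # uniform column over 20 residues -> 0 bits
  lm2 <- logo_matrix(AA20)
  expect_equal(unique(lm2$ic), 0, tolerance = 1e-12)
  # two residues at 0.5/0.5
  lm3 <- logo_matrix(c("A", "C"))
  expect_equal(unique(lm3$ic), log2(20) - 1, tolerance = 1e-12)
  # all-gap column: IC 0, gap fraction 1
  lm4 <- logo_matrix(c("A-", "A-"))
  col2 <- lm4[lm4$column == 2, ]
  expect_equal(col2$ic, 0)
  expect_equal(col2$gap_fraction, 1)
  # letter heights are frequency-weighted IC
  expect_equal(lm3$height, lm3$frequency * lm3$ic)
})

test_that("the repeat report annotates the consensus hallmarks", {
  prof <- build_consensus(plastex:::repeat_array_from_units(
    sample_repeat_units(CONS, 20, 0.05, seed = 3)))
  rep <- repeat_report(prof)
  expect_equal(rep$residue, chars(CONS))
  expect_equal(rep$class[1], "other")        # proline anchor
  expect_equal(rep$class[5], "positive")     # lysine
  expect_equal(rep$class[8], "positive")     # arginine
  expect_equal(rep$class[11], "negative")    # glutamate
})
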