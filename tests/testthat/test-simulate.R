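CONS <- "PSITKVTRVIEGE"

test_that("repeat-unit sampling honors the divergence rate", {
  exact <- sample_repeat_units(CONS, 5, 0, seed = 1)
  expect_equal(exact, rep(CONS, 5))
  units <- sample_repeat_units(CONS, 1000, 0.1, seed = 2)
  rate <- mean(vapply(units, function(u) {
    mean(chars(u) != chars(CONS))
  }, numeric(1)))
  se <- sqrt(0.1 * 0.9 / (1000 * 13))
  expect_lt(abs(rate - 0.1), 2 * se + 1e-3)
  expect_error(sample_repeat_units(CONS, 5, 0.1), "seed")
  # reproducibility
  expect_equal(sample_repeat_units(CONS, 10, 0.2, seed = 9),
               sample_repeat_units(CONS, 10, 0.2, seed = 9))
})

test_that("simulated loci satisfy splice and coding invariants", {
  for (sd in 1:3) {
    loc <- make_locus(seed = sd)
    g <- loc$genomic$residues
    exons <- loc$model$exons
    for (i in seq_along(exons)) {
      if (i < length(exons)) {
        expect_equal(substr(g, exons[[i]]$end + 1, exons[[i]]$end + 2),
                     "GT")
      }
      if (i > 1) {
        expect_equal(substr(g, exons[[i]]$start - 1, exons[[i]]$start),
                     "AG")
      }
      h <- validate_exon(exons[[i]], loc$genomic)
      expect_true(h$frame_preserving)
      expect_true(h$stop_free)
      if (i > 1 && i < length(exons)) expect_true(h$overall)
    }
    # spliced translation equals the truth protein, stop-free
    expect_equal(reconstruct_protein(loc$model, loc$genomic)$residues,
                 loc$protein$residues)
    expect_false(grepl("\\*", loc$protein$residues))
  }
})

test_that("locus simulation is byte-reproducible and seed-demanding", {
  a <- make_locus(seed = 77)
  b <- make_locus(seed = 77)
  expect_identical(a$genomic$residues, b$genomic$residues)
  expect_identical(a$protein$residues, b$protein$residues)
  expect_error(locus_spec(), "seed")
})

test_that("a duplication cluster inserts diverged template copies", {
  spec <- locus_spec(duplication_cluster = list(template_exon = 5L,
                                                n_copies = 8L,
                                                divergence = 0.05),
                     seed = 12)
  loc <- simulate_locus(spec)
  labels <- vapply(loc$model$exons, `[[`, "", "label")
  expect_equal(length(loc$model$exons), 16L)
  expect_equal(labels[5:13], c("5", paste0("5", LETTERS[1:8])))
  # copies stay highly similar to the template at the protein level
  prot <- reconstruct_protein(loc$model, loc$genomic)
  expect_equal(prot$residues, loc$protein$residues)
  tmpl_len <- plastex:::exon_length(loc$model$exons[[5]])
  expect_true(all(vapply(6:13, function(i) {
    plastex:::exon_length(loc$model$exons[[i]]) == tmpl_len
  }, logical(1))))
})

test_that("transcript simulation follows inclusion probabilities", {
  loc <- make_locus(seed = 21)
  n_ex <- length(loc$model$exons)
  # all-constitutive: every transcript is the full splice
  sp1 <- splice_spec(rep(1, n_ex), n_transcripts = 5)
  tr1 <- simulate_transcripts(loc$model, loc$genomic, sp1, seed = 3)
  full <- plastex:::splice_transcript(loc$model, loc$genomic)$residues
  for (t in tr1$transcripts) expect_equal(t$residues, full)
  # one cassette exon at 0.5: inclusion estimate within the binomial CI
  probs <- rep(1, n_ex); probs[3] <- 0.5
  sp2 <- splice_spec(probs, n_transcripts = 400)
  tr2 <- simulate_transcripts(loc$model, loc$genomic, sp2, seed = 4)
  est <- mean(tr2$truth$exon_3)
  expect_lt(abs(est - 0.5), 0.07)
  # every skip of a frame-preserving exon is flagged in-frame
  expect_true(all(!tr2$truth$frame_breaking))
  expect_error(splice_spec(c(1, 0.5), constitutive = c(TRUE, TRUE)),
               "constitutive")
})

test_that("skipping a frame-breaking exon is flagged", {
  # exon lengths not all divisible by 3: make exon 3 one codon short plus 1
  spec <- locus_spec(exon_lengths = c(120L, 90L, 76L, 195L, 87L, 90L,
                                      60L, 122L),
                     repeat_exon = list(exon_index = 4L,
                                        unit_consensus = CONS,
                                        n_units = 5L, divergence = 0.1),
                     seed = 31)
  loc <- simulate_locus(spec)
  probs <- rep(1, 8); probs[3] <- 0
  sp <- splice_spec(probs, n_transcripts = 3)
  tr <- simulate_transcripts(loc$model, loc$genomic, sp, seed = 5)
  expect_true(all(tr$truth$frame_breaking))
})

test_that("EST-style truncation clips transcript ends", {
  loc <- make_locus(seed = 22)
  sp <- splice_spec(rep(1, length(loc$model$exons)), n_transcripts = 50,
                    truncation_prob = 1, truncation_len_range = c(10L, 50L))
  tr <- simulate_transcripts(loc$model, loc$genomic, sp, seed = 6)
  full_len <- sum(vapply(loc$model$exons, plastex:::exon_length, 1L))
  lens <- vapply(tr$transcripts, length, 1L)
  expect_true(all(lens < full_len))
  expect_equal(full_len - lens, tr$truth$clip5 + tr$truth$clip3)
})

test_that("two-rate evolution matches its Poisson expectations", {
  tree <- plastex:::with_seed(1, ape::rtree(6))
  tree$edge.length <- tree$edge.length * 0.2
  root <- bio_seq(random_protein(200, seed = 2), id = "root")
  # zero rates leave every leaf identical to the root
  leaves0 <- evolve_two_rate(root, tree, 1:100, 101:200, 0, 0, seed = 3)
  for (l in leaves0) expect_equal(l$residues, root$residues)
  # 3x rate contrast shows up in region-wise p-distances
  ratio <- vapply(1:10, function(sd) {
    lv <- evolve_two_rate(root, tree, 1:100, 101:200, 0.3, 0.9,
                          seed = 100 + sd)
    pa <- mean(vapply(lv, function(l) {
      mean(chars(substr(l$residues, 1, 100)) !=
             chars(substr(root$residues, 1, 100)))
    }, numeric(1)))
    pb <- mean(vapply(lv, function(l) {
      mean(chars(substr(l$residues, 101, 200)) !=
             chars(substr(root$residues, 101, 200)))
    }, numeric(1)))
    pb / pa
  }, numeric(1))
  expect_gt(median(ratio), 2)
  expect_lt(median(ratio), 4.5)
  expect_error(evolve_two_rate(root, tree, 1:50, 51:150, 1, 1, seed = 1),
               "partition")
})

test_that("the synthetic teleost repeat set carries its stated unit counts", {
  loci <- synthetic_teleost_repeat_set(seed = 11)
  expect_equal(names(loci),
               c("Dr_locus1", "Dr_locus2", "Ga_locus1", "Ga_locus2",
                 "Tn_locus2", "Tr_locus2"))
  lens <- vapply(loci, length, 1L)
  counts <- c(6, 13, 7, 5, 8, 6)
  # each region is flank + 13 aa per unit + flank
  expect_equal(unname(lens), counts * 13 + 6)
  expect_identical(vapply(synthetic_teleost_repeat_set(seed = 11),
                          `[[`, "", "residues"),
                   vapply(loci, `[[`, "", "residues"))
})

test_that("decoy proteins are generically repetitive", {
  decoys <- sample_decoy_proteins(6, length = 140, seed = 5)
  expect_equal(length(decoys), 6L)
  expect_true(all(vapply(decoys, length, 1L) == 140))
  # each decoy carries a significant short period
  for (d in decoys[c(1, 2)]) {
    p <- estimate_period(d, max_period = 30, n_shuffles = 30, seed = 1)
    expect_false(is.null(p))
  }
})
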