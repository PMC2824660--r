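test_that("a translated substring is found as a perfect HSP", {
  g <- bio_seq(random_dna(300, seed = 51), alphabet = "DNA", id = "g")
  q <- translate_dna(bio_seq(substr(g$residues, 61, 240),
                             alphabet = "DNA"))
  q$id <- "q"
  hsps <- translated_hsp_search(q, g)
  top <- hsps[1, ]
  expect_equal(top$identity_fraction, 1.0)
  expect_equal(top$strand, "+")
  expect_equal(top$genomic_start, 60)
  expect_equal(top$genomic_end, 240)
  expect_error(translated_hsp_search(bio_seq("MKV"), g), ">= 10 aa")
})

test_that("minus-strand HSP coordinates map back through the reverse strand", {
  g <- bio_seq(random_dna(300, seed = 52), alphabet = "DNA", id = "g")
  rc <- reverse_complement(g)
  q <- translate_dna(bio_seq(substr(rc$residues, 31, 150),
                             alphabet = "DNA"))
  q$id <- "q"
  hsps <- translated_hsp_search(q, g)
  top <- hsps[1, ]
  expect_equal(top$strand, "-")
  # the minus-strand interval maps to [31, 150] on the reverse strand
  # (local alignments may overrun by a residue of chance match)
  expect_lte(abs((300 - top$genomic_end) - 30), 3)
  expect_lte(abs((300 - top$genomic_start) - 150), 3)
  expect_gte(top$identity_fraction, 0.95)
})

test_that("repetitive queries report all overlapping HSPs unmasked", {
  set.seed(53)
  cons_nt <- paste(sample(DNA4, 39, TRUE), collapse = "")
  genomic <- bio_seq(paste0(random_dna(90, seed = 54), strrep(cons_nt, 4),
                            random_dna(90, seed = 55)),
                     alphabet = "DNA", id = "g")
  q3 <- translate_dna(bio_seq(strrep(cons_nt, 3), alphabet = "DNA"))
  q3$id <- "rep_query"
  hsps <- translated_hsp_search(q3, genomic, min_score = 40)
  within <- hsps[hsps$genomic_start >= 80 & hsps$genomic_end <= 260, ]
  expect_gte(nrow(within), 2L)
})

test_that("exon chaining is optimal against the exhaustive subset oracle", {
  mk <- function(gs, ge, qs, qe, score, strand = "+") {
    data.frame(genomic_start = gs, genomic_end = ge, strand = strand,
               frame = 0L, query_start = qs, query_end = qe, score = score,
               identity_fraction = 1)
  }
  # three collinear HSPs chain fully
  h3 <- rbind(mk(0, 90, 1, 30, 100), mk(150, 240, 31, 60, 90),
              mk(300, 390, 61, 90, 80))
  ch <- chain_exons(h3)
  expect_equal(nrow(ch), 3L)
  expect_equal(attr(ch, "chain_score"), 270)
  # reversed genomic order vs query order: best chain is a single HSP
  h2 <- rbind(mk(300, 390, 1, 30, 100), mk(0, 90, 31, 60, 90))
  ch2 <- chain_exons(h2)
  expect_equal(nrow(ch2), 1L)
  # random instances with <= 6 HSPs match the brute-force subset oracle
  for (seed in 1:10) {
    set.seed(9000 + seed)
    n <- sample(3:6, 1)
    gs <- sort(sample(seq(0, 5000, by = 10), n))
    ge <- gs + sample(60:240, n, replace = TRUE)
    qs <- sort(sample(1:200, n))
    qe <- qs + sample(20:80, n, replace = TRUE)
    h <- mk(gs, ge, qs, qe, sample(50:300, n, replace = TRUE))
    ch <- chain_exons(h)
    expect_equal(attr(ch, "chain_score"), oracle_chain_score(h))
  }
  empty <- chain_exons(h3[0, ])
  expect_equal(nrow(empty), 0L)
  expect_match(attr(empty, "diagnostic"), "no HSPs")
})

test_that("boundary refinement recovers simulated truth exactly", {
  loc <- make_locus(seed = 101)
  hsps <- translated_hsp_search(loc$protein, loc$genomic)
  chain <- chain_exons(hsps)
  model <- refine_boundaries(chain, loc$genomic, loc$protein)
  truth <- unlist(lapply(loc$model$exons, function(e) c(e$start, e$end)))
  est <- unlist(lapply(model$exons, function(e) c(e$start, e$end)))
  expect_equal(est, truth)
  expect_equal(reconstruct_protein(model, loc$genomic)$residues,
               loc$protein$residues)
})

test_that("non-canonical donors are flagged unresolved, model still returned", {
  loc <- make_locus(seed = 102)
  g <- loc$genomic$residues
  # remove every GT dinucleotide in a wide window around the first donor,
  # so no canonical site is reachable for that junction
  donor_pos <- loc$model$exons[[1]]$end
  for (p in (donor_pos - 60):(donor_pos + 60)) {
    if (substr(g, p + 1, p + 2) == "GT") substr(g, p + 1, p + 2) <- "GC"
  }
  genomic2 <- bio_seq(g, alphabet = "DNA", id = "mutated")
  hsps <- translated_hsp_search(loc$protein, genomic2)
  chain <- chain_exons(hsps)
  model <- refine_boundaries(chain, genomic2, loc$protein)
  expect_true(attr(model, "unresolved")[1])
  expect_s3_class(model, "gene_model")
})

test_that("single-exon chains pass through unchanged", {
  g <- bio_seq(random_dna(400, seed = 56), alphabet = "DNA", id = "g")
  q <- translate_dna(bio_seq(substr(g$residues, 101, 280),
                             alphabet = "DNA"))
  q$id <- "q"
  chain <- chain_exons(translated_hsp_search(q, g))
  model <- refine_boundaries(chain, g, q)
  expect_equal(length(model$exons), 1L)
  expect_equal(model$exons[[1]]$start, 100)
  expect_equal(model$exons[[1]]$end, 280)
})

test_that("exon hallmarks follow the frame / stop / splice-site rules", {
  # an 87-nt exon with GT..AG flanks and stop-free frame passes all three
  set.seed(57)
  exon_nt <- paste(vapply(1:29, function(i) {
    repeat {
      cod <- paste(sample(DNA4, 3, TRUE), collapse = "")
      if (!cod %in% c("TAA", "TAG", "TGA")) return(cod)
    }
  }, character(1)), collapse = "")
  g <- bio_seq(paste0(random_dna(50, seed = 58), "AG", exon_nt, "GT",
                      random_dna(50, seed = 59)),
               alphabet = "DNA", id = "g")
  exon <- exon_model(52, 52 + 87, label = "21V22", donor = "GT",
                     acceptor = "AG")
  h <- validate_exon(exon, g)
  expect_true(h$frame_preserving)
  expect_true(h$stop_free)
  expect_true(h$splice_canonical)
  expect_true(h$overall)
  # 86-nt variant breaks the frame
  h86 <- validate_exon(exon_model(52, 52 + 86, donor = "GT",
                                  acceptor = "AG"), g)
  expect_false(h86$frame_preserving)
  expect_false(h86$overall)
  # an in-frame TAA breaks stop-freedom
  g_stop <- g
  res <- g_stop$residues
  substr(res, 53, 55) <- "TAA"
  g_stop <- bio_seq(res, alphabet = "DNA", id = "gstop")
  h_stop <- validate_exon(exon, g_stop)
  expect_false(h_stop$stop_free)
  expect_false(h_stop$overall)
  # hallmark overall is exactly the conjunction
  expect_equal(h$overall,
               h$frame_preserving && h$stop_free && h$splice_canonical)
})

test_that("protein reconstruction splices, skips, and detects frameshifts", {
  loc <- make_locus(seed = 103)
  expect_equal(reconstruct_protein(loc$model, loc$genomic)$residues,
               loc$protein$residues)
  # skipping a frame-preserving cassette exon yields a valid shorter protein
  skip <- loc$model
  skipped_len <- plastex:::exon_length(skip$exons[[3]])
  expect_equal(skipped_len %% 3, 0)
  skip$exons <- skip$exons[-3]
  shorter <- reconstruct_protein(skip, loc$genomic)
  expect_equal(nchar(shorter$residues),
               nchar(loc$protein$residues) - skipped_len / 3)
  # removing part of an exon breaks the frame downstream
  bad <- loc$model
  bad$exons[[3]] <- exon_model(bad$exons[[3]]$start,
                               bad$exons[[3]]$end - 1L, "+",
                               bad$exons[[3]]$phase,
                               bad$exons[[3]]$donor,
                               bad$exons[[3]]$acceptor, "broken")
  expect_error(reconstruct_protein(bad, loc$genomic), "divisible by 3")
})

test_that("conservation profiles localize divergence and are symmetric", {
  a <- bio_seq(random_dna(600, seed = 60), alphabet = "DNA", id = "a")
  tr <- conservation_profile(a, a, window = 100, step = 50)
  expect_true(all(tr$percent_identity == 100))
  expect_equal(unique(tr$class), "high")
  # scramble a 100-nt block in the middle
  res <- a$residues
  set.seed(61)
  substr(res, 251, 350) <- paste(sample(DNA4, 100, TRUE), collapse = "")
  b <- bio_seq(res, alphabet = "DNA", id = "b")
  tr2 <- conservation_profile(a, b, window = 100, step = 25)
  low <- tr2[tr2$class == "low", ]
  expect_gt(nrow(low), 0)
  expect_true(any(low$col_start >= 150 & low$col_end <= 450))
  # symmetry under swapping inputs
  tr3 <- conservation_profile(b, a, window = 100, step = 25)
  expect_equal(tr2$percent_identity, tr3$percent_identity)
  expect_error(conservation_profile(a, b, window = 10000), "window")
  peaks <- conservation_peaks(tr2)
  expect_true(all(peaks$class %in% c("high", "low")))
})
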