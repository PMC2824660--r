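UNIF_BG <- setNames(rep(0.05, 20), AA20)

test_that("profile log-odds match the closed form as pseudocounts vanish", {
  p <- build_profile(c("AC", "AC"), background = UNIF_BG,
                     pseudocount = 1e-9)
  expect_equal(unname(p$scores[1, "A"]), log2(20), tolerance = 1e-6)
  expect_equal(unname(p$scores[2, "C"]), log2(20), tolerance = 1e-6)
  expect_equal(nrow(p$scores), 2L)
  # both pseudocount models agree on the observed residues in the limit
  pb <- build_profile(c("AC", "AC"), background = UNIF_BG,
                      pseudocount = 1e-9,
                      pseudocount_model = "background")
  expect_equal(unname(pb$scores[1, "A"]), log2(20), tolerance = 1e-6)
  expect_equal(p$scores[1, "A"], pb$scores[1, "A"], tolerance = 1e-5)
  expect_equal(p$scores[2, "C"], pb$scores[2, "C"], tolerance = 1e-5)
})

test_that("gap-dominated columns are dropped and recorded", {
  rows <- c("A-C", "A-C", "AGC")
  p <- build_profile(rows)
  expect_equal(p$dropped_columns, 2L)
  expect_equal(nrow(p$scores), 2L)
  expect_error(build_profile(character(0)), "empty")
  expect_error(build_profile(c("---", "---")), "gap-dominated")
})

test_that("heavier background pseudocounts shrink scores toward zero", {
  rows <- c("PSITK", "PSITK", "PSITR")
  p_light <- build_profile(rows, pseudocount = 0.1,
                           pseudocount_model = "background")
  p_heavy <- build_profile(rows, pseudocount = 50,
                           pseudocount_model = "background")
  expect_true(all(abs(p_heavy$scores[, AA20]) <=
                    abs(p_light$scores[, AA20]) + 1e-9))
})

test_that("profile scan equals the quadratic DP oracle on short targets", {
  units <- sample_repeat_units("PSITKVTRVIEGE", 3, 0.15, seed = 11)
  p <- build_profile(units)
  sm <- p$scores
  for (seed in 1:8) {
    tgt <- random_protein(50, seed = 8000 + seed)
    hit <- suppressWarnings(
      scan_profile(p, list(bio_seq(tgt, id = "t"))))
    expect_equal(hit$score,
                 oracle_profile_local(sm, tgt, p$gap_open, p$gap_ext),
                 tolerance = 1e-9)
  }
  # and on a target that embeds the doubled consensus
  emb <- paste0(random_protein(20, seed = 1), doubled_consensus("PSITKVTRVIEGE"),
                random_protein(20, seed = 2))
  hit <- suppressWarnings(scan_profile(p, list(bio_seq(emb, id = "e"))))
  expect_equal(hit$score,
               oracle_profile_local(sm, emb, p$gap_open, p$gap_ext),
               tolerance = 1e-9)
  # reported coordinates overlap the embedded repeat region (21..46)
  expect_lte(hit$target_start, 46)
  expect_gte(hit$target_end, 21)
})

test_that("a consensus-bearing target outranks random decoys", {
  units <- sample_repeat_units("PSITKVTRVIEGE", 4, 0.1, seed = 5)
  p <- build_profile(c(paste0(units[1], units[2]),
                       paste0(units[3], units[4])), n_units_in_query = 2)
  set.seed(6)
  target <- bio_seq(paste0(random_protein(100, seed = 61),
                           doubled_consensus("PSITKVTRVIEGE"),
                           random_protein(100, seed = 62)),
                    id = "embedding")
  db <- c(list(target),
          lapply(1:10, function(i) {
            bio_seq(random_protein(226, seed = 70 + i),
                    id = paste0("rand", i))
          }))
  hits <- scan_profile(p, db)
  expect_equal(hits$target_id[1], "embedding")
})

test_that("single-unit profiles carry the duplet warning", {
  units <- sample_repeat_units("PSITKVTRVIEGE", 3, 0.1, seed = 9)
  p1 <- build_profile(units, n_units_in_query = 1)
  expect_warning(h <- scan_profile(p1, list(bio_seq(random_protein(60, 1),
                                                    id = "t"))),
                 "single repeat unit")
  expect_true(isTRUE(attr(h, "duplet_warning")))
})

test_that("calibration yields self-consistent Gumbel E-values", {
  units <- sample_repeat_units("PSITKVTRVIEGE", 3, 0.15, seed = 13)
  p <- build_profile(units)
  expect_error(calibrate_profile(p, null_db_size = 20), ">= 50")
  p <- calibrate_profile(p, null_db_size = 500, seed = 17, null_len = 200)
  # E monotone decreasing in score
  sc <- seq(0, 40, by = 5)
  ev <- profile_evalue(p, sc, db_size = 100)
  expect_true(all(diff(ev) < 0))
  # doubling the database doubles E at fixed score
  expect_equal(profile_evalue(p, 20, 200),
               2 * profile_evalue(p, 20, 100))
  # the median null maximum should sit near E = db_size / 2
  maxima <- plastex:::with_seed(17, vapply(1:500, function(i) {
    res <- paste(sample(AA20, 200, TRUE, prob = p$background),
                 collapse = "")
    suppressWarnings(scan_profile(p, list(bio_seq(res, id = "n"))))$score
  }, numeric(1)))
  e_med <- profile_evalue(p, median(maxima), db_size = 500)
  expect_gt(e_med, 250 * 0.8)
  expect_lt(e_med, 250 * 1.2)
})

test_that("iterative search grows its inclusion set monotonically", {
  cons <- "PSITKVTRVIEGE"
  units <- sample_repeat_units(cons, 4, 0.05, seed = 23)
  seed_aln <- c(paste0(units[1], units[2]), paste0(units[3], units[4]))
  # A is close to the seed; B is reachable only via a profile refined with
  # A's diverged units
  a_units <- sample_repeat_units(cons, 4, 0.25, seed = 24)
  b_units <- vapply(a_units, function(u) {
    plastex:::with_seed(25, plastex:::mutate_protein(u, 0.2))
  }, character(1), USE.NAMES = FALSE)
  mk <- function(us, id, seed) {
    bio_seq(paste0(random_protein(40, seed), paste(us, collapse = ""),
                   random_protein(40, seed + 1)), id = id)
  }
  db <- list(mk(a_units, "A", 300), mk(b_units, "B", 302),
             bio_seq(random_protein(130, seed = 304), id = "decoy"))
  res <- iterate_search(seed_aln, db, inclusion_threshold = 0.05,
                        max_iter = 3, n_units_in_query = 2,
                        calibration_seed = 31)
  for (k in seq_len(res$iterations - 1L)) {
    expect_true(all(res$included[[k]] %in% res$included[[k + 1L]]))
  }
  expect_true("A" %in% res$included[[res$iterations]])
  # an impossible threshold converges immediately on the seed profile
  res0 <- iterate_search(seed_aln, db, inclusion_threshold = 0,
                         max_iter = 3, n_units_in_query = 2)
  expect_equal(res0$iterations, 1L)
  expect_true(res0$converged)
  expect_equal(length(res0$included[[1]]), 0L)
  # the iteration cap is honored
  res_cap <- iterate_search(seed_aln, db, inclusion_threshold = 100,
                            max_iter = 2, n_units_in_query = 2)
  expect_lte(res_cap$iterations, 2L)
  expect_error(iterate_search(character(0), db), "empty")
})

test_that("the duplet rule separates one- and two-unit searches", {
  res <- duplet_rule_experiment(seeds = 1:10)
  expect_true(all(res$two_unit_top))
  expect_gte(sum(!res$one_unit_top), 1L)
})

test_that("profile TSV export is positionally complete", {
  units <- sample_repeat_units("PSITKVTRVIEGE", 3, 0.1, seed = 41)
  p <- build_profile(units)
  path <- tempfile(fileext = ".tsv")
  write_profile_tsv(p, path)
  df <- read.delim(path, check.names = FALSE)
  expect_equal(nrow(df), nrow(p$scores))
  expect_true(all(AA20 %in% names(df)))
})
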