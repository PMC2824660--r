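# Encode a protein string as 1-based indices into c(AA_CHARS, "X").
encode_protein <- function(residues) {
  idx <- match(split_chars(residues), c(AA_CHARS, "X"))
  idx[is.na(idx)] <- 21L
  idx
}

# conditional substitution probabilities P(r | s) implied by BLOSUM62
# (in half-bit units): q(r|s) proportional to bg_r * 2^(S(r,s)/2).
blosum_conditional <- function(background) {
  s <- blosum62_matrix()[AA_CHARS, AA_CHARS]
  q <- background * 2^(s / 2)   # recycles bg over rows (r index)
  sweep(q, 2, colSums(q), "/")  # columns sum to 1 over r
}

#' Build a position-specific log-odds profile from a repeat-unit alignment
#'
#' Column score for residue \code{r} is \code{log2(f_r / b_r)} in bits,
#' with \code{f_r = (count_r + pseudocount * g_r) / (n_nongap +
#' pseudocount)}. The pseudocount vector \code{g} is, by default,
#' substitution-matrix based (each observed residue spreads mass onto its
#' BLOSUM62 neighbours, the classic data-dependent pseudocount), so
#' conservative substitutions in diverged homologs are penalized mildly
#' while radical ones remain negative; \code{pseudocount_model =
#' "background"} falls back to plain background pseudocounts. Columns with
#' gap fraction above 50\% are dropped and recorded. A profile built from
#' fewer than two repeat units carries a warning state: single-unit repeat
#' queries are known to produce spurious hits against generically
#' repetitive proteins, while two concatenated units already make the
#' search specific (the duplet rule).
#'
#' @param alignment Character vector of equal-length gapped protein rows,
#'   or an aligned \code{\link{repeat_array}}.
#' @param background Named length-20 residue frequency vector.
#' @param pseudocount Pseudocount weight (default 2).
#' @param pseudocount_model \code{"blosum"} (default) or
#'   \code{"background"}.
#' @param n_units_in_query Number of repeat units the query represents
#'   (caller metadata; defaults to the number of alignment rows).
#' @return An object of class \code{pssm}.
#' @export
build_profile <- function(alignment, background = UNIPROT_BG,
                          pseudocount = 2,
                          pseudocount_model = c("blosum", "background"),
                          n_units_in_query = NULL) {
  pseudocount_model <- match.arg(pseudocount_model)
  if (inherits(alignment, "repeat_array")) {
    rows <- if (!is.null(alignment$alignment)) alignment$alignment
            else alignment$units
  } else rows <- alignment
  if (!length(rows)) stop_plastex("empty alignment")
  if (length(rows) < 2L) stop_plastex("profile needs >= 2 alignment rows")
  if (length(unique(nchar(rows))) != 1L) {
    stop_plastex("alignment rows differ in length")
  }
  stopifnot(all(AA_CHARS %in% names(background)))
  background <- background[AA_CHARS] / sum(background[AA_CHARS])
  m <- do.call(rbind, strsplit(rows, ""))
  gap_fraction <- colMeans(m == "-")
  keep <- gap_fraction <= 0.5
  if (!any(keep)) stop_plastex("all columns gap-dominated")
  if (is.null(n_units_in_query)) n_units_in_query <- length(rows)
  qcond <- if (pseudocount_model == "blosum") blosum_conditional(background)
           else NULL
  scores <- vapply(which(keep), function(j) {
    col <- m[, j]
    col <- col[col %in% AA_CHARS]
    counts <- as.numeric(table(factor(col, levels = AA_CHARS)))
    fobs <- counts / length(col)
    g <- if (is.null(qcond)) background else as.numeric(qcond %*% fobs)
    f <- (counts + pseudocount * g) / (length(col) + pseudocount)
    log2(f / background)
  }, numeric(20))
  scores <- t(scores)  # positions x residues
  colnames(scores) <- AA_CHARS
  scores <- cbind(scores, X = 0)  # ambiguity scores zero
  structure(list(scores = scores, background = background,
                 pseudocount = pseudocount,
                 n_units_in_query = as.integer(n_units_in_query),
                 dropped_columns = which(!keep),
                 gap_open = 5.5, gap_ext = 0.5,  # bits (11/1 in half-bits)
                 calibration = NULL),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> %d position(s), %d unit(s) in query%s%s\n",
              nrow(x$scores), x$n_units_in_query,
              if (x$n_units_in_query < 2L) " [single-unit warning]" else "",
              if (is.null(x$calibration)) "" else ", calibrated"))
  invisible(x)
}

#' Consensus (argmax) string of a profile
#' @param p A \code{pssm}.
#' @return Character scalar.
#' @export
profile_consensus <- function(p) {
  paste(AA_CHARS[apply(p$scores[, AA_CHARS, drop = FALSE], 1, which.max)],
        collapse = "")
}

#' Scan a protein database with a profile
#'
#' Best local affine-gap alignment (gap open 11, extend 1, half-bit units)
#' of the profile against each target; hits are sorted by score. E-values
#' are attached when the profile is calibrated. If the profile was built
#' from a single repeat unit the result carries a \code{duplet_warning}
#' attribute and a warning is raised: single-unit searches are prone to
#' spurious matches to generically repetitive sequences.
#'
#' @param p A \code{pssm}.
#' @param db List of protein \code{\link{bio_seq}} objects.
#' @return Data frame of hits: \code{target_id}, \code{score} (bits),
#'   \code{evalue} (NA if uncalibrated), \code{target_start},
#'   \code{target_end}, \code{profile_start}, \code{profile_end}
#'   (1-based, inclusive).
#' @export
scan_profile <- function(p, db) {
  stopifnot(inherits(p, "pssm"))
  if (!length(db)) stop_plastex("empty database")
  if (nrow(p$scores) == 0L) stop_plastex("empty profile")
  hits <- lapply(db, function(s) {
    stopifnot(inherits(s, "bio_seq"))
    if (s$alphabet != "PROTEIN") stop_plastex("profile scan needs proteins")
    r <- .pssm_local_scan(p$scores, encode_protein(s$residues),
                          p$gap_open, p$gap_ext)
    data.frame(target_id = s$id, score = r$score,
               target_start = r$t_start, target_end = r$t_end,
               profile_start = r$prof_start, profile_end = r$prof_end)
  })
  out <- do.call(rbind, hits)
  out$evalue <- if (!is.null(p$calibration)) {
    profile_evalue(p, out$score, db_size = length(db))
  } else NA_real_
  out <- out[order(-out$score),
             c("target_id", "score", "evalue", "target_start", "target_end",
               "profile_start", "profile_end")]
  rownames(out) <- NULL
  if (p$n_units_in_query < 2L) {
    attr(out, "duplet_warning") <- TRUE
    warning("profile was built from a single repeat unit; ",
            "hits may be spurious (use >= 2 units)", call. = FALSE)
  }
  out
}

#' Calibrate a profile's score null by Gumbel fitting
#'
#' Scans \code{null_db_size} shuffled/background null sequences, records
#' the per-sequence maximum local score, and fits an extreme-value (Gumbel)
#' location/scale by moments. E-values are then
#' \code{db_size * P(S >= score)} under the fit. Shuffling preserves length
#' and composition per null sequence when templates are supplied; otherwise
#' null sequences are drawn i.i.d. from the background composition.
#'
#' @param p A \code{pssm}.
#' @param null_db_size Number of null sequences (>= 50; smaller fits are
#'   refused as unstable).
#' @param seed RNG seed (recorded in the calibration).
#' @param templates Optional list of protein \code{bio_seq}s to shuffle
#'   (recycled); default draws from the background.
#' @param null_len Null sequence length when drawing from background.
#' @return The profile with \code{calibration} set (location, scale, n,
#'   seed).
#' @export
calibrate_profile <- function(p, null_db_size = 200L, seed = 1L,
                              templates = NULL, null_len = 400L) {
  stopifnot(inherits(p, "pssm"))
  if (null_db_size < 50L) {
    stop_plastex("null_db_size must be >= 50 for a stable fit")
  }
  maxima <- with_seed(seed, {
    vapply(seq_len(null_db_size), function(i) {
      res <- if (is.null(templates)) {
        paste(sample(AA_CHARS, null_len, replace = TRUE,
                     prob = p$background), collapse = "")
      } else {
        tpl <- templates[[((i - 1L) %% length(templates)) + 1L]]
        paste(sample(split_chars(tpl$residues)), collapse = "")
      }
      .pssm_local_scan(p$scores, encode_protein(res), p$gap_open,
                       p$gap_ext)$score
    }, numeric(1))
  })
  beta <- sd(maxima) * sqrt(6) / pi
  mu <- mean(maxima) - 0.5772156649 * beta
  p$calibration <- list(location = mu, scale = beta, n = null_db_size,
                        seed = seed)
  p
}

#' E-value of a score under a calibrated profile
#'
#' @param p Calibrated \code{pssm}.
#' @param score Score(s) in bits.
#' @param db_size Database size the E-value refers to.
#' @return Numeric E-value(s), \code{db_size * P(S >= score)} under the
#'   Gumbel fit.
#' @export
profile_evalue <- function(p, score, db_size) {
  if (is.null(p$calibration)) stop_plastex("profile is not calibrated")
  z <- (score - p$calibration$location) / p$calibration$scale
  db_size * (-expm1(-exp(-z)))
}

#' Iterative profile search with hit inclusion
#'
#' Scan, include hit regions at or below the E-value threshold, realign the
#' included regions to the profile consensus, rebuild, and repeat until the
#' included set stops changing or \code{max_iter} is reached. The included
#' set is monotone non-decreasing across iterations. Full per-iteration hit
#' tables are returned for audit: the absence of false positives below a
#' threshold is something to inspect in that record, not a guarantee.
#'
#' @param seed_alignment Character vector of gapped protein rows (the seed
#'   repeat alignment).
#' @param db List of protein \code{\link{bio_seq}}s.
#' @param inclusion_threshold E-value inclusion cutoff (default 1.8).
#' @param max_iter Maximum iterations (>= 1, default 3).
#' @param n_units_in_query Units represented by the seed alignment.
#' @param calibration_seed Seed for per-iteration calibration.
#' @param null_db_size Null size for calibration.
#' @return List with \code{profile} (final), \code{hits} (list of per-
#'   iteration hit data frames), \code{included} (list of per-iteration
#'   included target-id vectors), \code{iterations}, \code{converged}.
#' @export
iterate_search <- function(seed_alignment, db, inclusion_threshold = 1.8,
                           max_iter = 3L, n_units_in_query = NULL,
                           calibration_seed = 1L, null_db_size = 100L) {
  if (!length(seed_alignment)) stop_plastex("empty seed alignment")
  stopifnot(max_iter >= 1L)
  prof <- build_profile(seed_alignment, n_units_in_query = n_units_in_query)
  # project seed rows onto the profile's kept columns so rebuilt alignments
  # stay rectangular
  base_rows <- vapply(seed_alignment, function(r) {
    ch <- split_chars(r)
    if (length(prof$dropped_columns)) ch <- ch[-prof$dropped_columns]
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  included_ids <- character(0)
  included_rows <- character(0)
  hits_per_iter <- list()
  included_per_iter <- list()
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    prof <- calibrate_profile(prof, null_db_size = null_db_size,
                              seed = calibration_seed + iter)
    hits <- suppressWarnings(scan_profile(prof, db))
    hits_per_iter[[iter]] <- hits
    ok <- !is.na(hits$evalue) & hits$evalue <= inclusion_threshold &
      hits$score > 0
    new_ids <- union(included_ids, hits$target_id[ok])
    included_per_iter[[iter]] <- new_ids
    if (setequal(new_ids, included_ids) || iter >= max_iter) {
      converged <- setequal(new_ids, included_ids)
      included_ids <- new_ids
      break
    }
    included_ids <- new_ids
    # realign included hit regions to the profile consensus and rebuild
    cons <- profile_consensus(prof)
    regions <- lapply(which(ok), function(k) {
      s <- db[[match(hits$target_id[k], vapply(db, `[[`, "", "id"))]]
      substr(s$residues, hits$target_start[k], hits$target_end[k])
    })
    new_rows <- vapply(regions, function(r) {
      pa <- align_to_consensus(r, cons, "PROTEIN")
      patt <- split_chars(pa$pattern); subj <- split_chars(pa$subject)
      paste(patt[subj != "-"], collapse = "")  # project onto profile columns
    }, character(1))
    included_rows <- union(included_rows, new_rows)
    prof <- build_profile(c(base_rows, included_rows),
                          n_units_in_query = n_units_in_query)
  }
  list(profile = prof, hits = hits_per_iter,
       included = included_per_iter, iterations = iter,
       converged = converged)
}

#' Serialize a profile as TSV (position x residue scores)
#'
#' @param p A \code{pssm}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_profile_tsv <- function(p, path) {
  df <- data.frame(position = seq_len(nrow(p$scores)),
                   p$scores[, AA_CHARS, drop = FALSE], check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
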