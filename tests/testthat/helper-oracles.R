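# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (no Rcpp kernels, no shared helpers).

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
DNA4 <- c("A", "C", "G", "T")

random_protein <- function(n, seed) {
  set.seed(seed)
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(DNA4, n, replace = TRUE), collapse = "")
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# exhaustive lag scan: fraction of self-matches at every lag
oracle_lag_scores <- function(s, max_lag) {
  x <- chars(s)
  L <- length(x)
  vapply(seq_len(max_lag), function(p) {
    mean(x[seq_len(L - p)] == x[(p + 1):L])
  }, numeric(1))
}

# brute-force windowed dot matrix cell
oracle_window_score <- function(a, b, i, j, w, score_fun) {
  xa <- chars(a); xb <- chars(b)
  sum(vapply(0:(w - 1), function(k) score_fun(xa[i + k], xb[j + k]),
             numeric(1)))
}

blosum62_oracle <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env(); utils::data("BLOSUM62", package = "Biostrings",
                                  envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# independent quadratic local profile-alignment DP (score only), affine gaps
oracle_profile_local <- function(score_mat, target, gap_open, gap_ext) {
  tc <- chars(target)
  n <- nrow(score_mat); m <- length(tc)
  NEG <- -1e30
  M <- matrix(NEG, n + 1, m + 1); Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- score_mat[i - 1, tc[j - 1]]
      M[i, j] <- s + max(0, M[i - 1, j - 1], Ix[i - 1, j - 1],
                         Iy[i - 1, j - 1])
      Ix[i, j] <- max(M[i - 1, j] - gap_open, Ix[i - 1, j] - gap_ext)
      Iy[i, j] <- max(M[i, j - 1] - gap_open, Iy[i, j - 1] - gap_ext)
      best <- max(best, M[i, j], Ix[i, j], Iy[i, j])
    }
  }
  best
}

# exhaustive best-chain score over all ordered HSP subsets (<= 6 HSPs),
# mirroring the chain rules: overlap-penalized scores, relaxed gap floor
oracle_chain_score <- function(hsps, max_intron = 50000, min_intron = 30,
                               max_overlap_frac = 1.0) {
  n <- nrow(hsps)
  span <- hsps$query_end - hsps$query_start + 1
  best <- 0
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    for (strand in unique(hsps$strand[idx])) {
      sel <- idx[hsps$strand[idx] == strand]
      h <- hsps[sel, , drop = FALSE]
      sp <- span[sel]
      ord <- if (strand == "+") order(h$genomic_start) else
        order(-h$genomic_start)
      h <- h[ord, , drop = FALSE]
      sp <- sp[ord]
      ok <- TRUE
      total <- h$score[1]
      if (nrow(h) > 1) {
        for (k in 2:nrow(h)) {
          q_overlap <- max(0, h$query_end[k - 1] - h$query_start[k] + 1)
          gap <- if (strand == "+") {
            h$genomic_start[k] - h$genomic_end[k - 1]
          } else h$genomic_start[k - 1] - h$genomic_end[k]
          prog <- if (strand == "+") {
            h$genomic_start[k] > h$genomic_start[k - 1] &&
              h$genomic_end[k] > h$genomic_end[k - 1]
          } else {
            h$genomic_start[k] < h$genomic_start[k - 1] &&
              h$genomic_end[k] < h$genomic_end[k - 1]
          }
          if (q_overlap > max_overlap_frac * sp[k] ||
              gap < min_intron - 3 * q_overlap || gap > max_intron ||
              !prog || h$query_end[k] <= h$query_end[k - 1]) {
            ok <- FALSE
            break
          }
          dens <- min(h$score[k - 1] / sp[k - 1], h$score[k] / sp[k])
          total <- total + h$score[k] - q_overlap * dens
        }
      }
      if (ok) best <- max(best, total)
    }
  }
  best
}

# closed-form three-taxon NJ branch lengths
oracle_nj3 <- function(dab, dac, dbc) {
  c(a = (dab + dac - dbc) / 2, b = (dab + dbc - dac) / 2,
    c = (dac + dbc - dab) / 2)
}

# additive distance matrix from a random binary tree
additive_matrix <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[tree$tip.label, tree$tip.label]
}

make_locus <- function(seed, ...) simulate_locus(locus_spec(seed = seed, ...))
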