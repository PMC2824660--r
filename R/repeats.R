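#' Estimate the fundamental period of a tandem repeat
#'
#' Scores every lag \code{p} by the fraction of positions \code{i} with
#' \code{seq[i] == seq[i+p]} (ambiguity characters \code{N}/\code{X} never
#' match) and returns the smallest lag whose score is within \code{tol} of
#' the maximum — tolerance meaning the relative \code{tol} or twice the
#' binomial standard error of the best score, whichever is larger — which
#' suppresses multiples of the fundamental period. The
#' best score must exceed a null threshold obtained from residue-shuffled
#' copies of the input (99th percentile of the per-shuffle maximum by
#' default), otherwise \code{NULL} is returned: random sequences carry no
#' period.
#'
#' @param seq A \code{\link{bio_seq}}.
#' @param max_period Largest lag to scan; the sequence must be longer than
#'   this.
#' @param tol Relative tolerance for the smallest-lag rule (default 0.05).
#' @param n_shuffles Number of residue shuffles for the null (default 100).
#' @param null_quantile Quantile of the null maxima used as the significance
#'   threshold (default 0.99).
#' @param seed Optional seed for the shuffle null.
#' @return Integer period with attributes \code{score} and
#'   \code{null_threshold}, or \code{NULL} if no significant period.
#' @export
#' @examples
#' estimate_period(bio_seq(strrep("PSITKVTRVIEGE", 6)), max_period = 40)
estimate_period <- function(seq, max_period = 40L, tol = 0.05,
                            n_shuffles = 100L, null_quantile = 0.99,
                            seed = NULL) {
  stopifnot(inherits(seq, "bio_seq"))
  x <- split_chars(seq$residues)
  L <- length(x)
  if (L <= max_period) {
    stop_plastex("sequence too short (", L, ") for max_period ", max_period)
  }
  ambig <- if (seq$alphabet == "DNA") "N" else c("X", "*")
  lag_profile <- function(chars) {
    vapply(seq_len(max_period), function(p) {
      a <- chars[seq_len(L - p)]
      b <- chars[(p + 1L):L]
      mean(a == b & !(a %in% ambig))
    }, numeric(1))
  }
  scores <- lag_profile(x)
  best <- max(scores)
  null_max <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    max(lag_profile(sample(x)))
  }, numeric(1)))
  thr <- as.numeric(quantile(null_max, null_quantile))
  if (best <= thr) return(NULL)
  # smallest lag within tolerance of the maximum wins, so multiples of the
  # fundamental period are suppressed; the tolerance includes a binomial
  # noise allowance for the identity estimate at the best lag
  p_best <- which.max(scores)
  se_best <- sqrt(best * (1 - best) / (L - p_best))
  slack <- max(best * tol, 2 * se_best)
  candidates <- which(scores >= best - slack & scores > thr)
  period <- as.integer(min(candidates))
  structure(period, score = scores[period], null_threshold = thr)
}

#' Segment a sequence into tandem repeat units
#'
#' Cuts an ordered, non-overlapping series of repeat units of approximately
#' \code{period} residues. The starting phase is chosen so that as many
#' units as possible begin with the anchor residue (proline by default, a
#' preference, not a requirement); if the anchor is absent the phase with
#' maximal self-similarity among stacked units is used. Unit lengths may
#' deviate from the period by up to \code{length_tol} residues, resolved
#' greedily by look-ahead identity against the first unit; for DNA the
#' deviation is constrained to multiples of 3 so segmentation keeps the
#' reading frame intact.
#'
#' @param seq A \code{\link{bio_seq}} containing the repeat region.
#' @param period Repeat period (residues), e.g. from
#'   \code{\link{estimate_period}}.
#' @param anchor_residue Single residue used to phase unit starts
#'   (default \code{"P"}); set \code{NULL} to disable.
#' @param length_tol Maximum per-unit length deviation (default 2; DNA uses
#'   3 and steps of 3).
#' @return An object of class \code{repeat_array}.
#' @export
segment_units <- function(seq, period, anchor_residue = "P",
                          length_tol = 2L) {
  stopifnot(inherits(seq, "bio_seq"))
  if (is.null(period)) stop_plastex("period is absent")
  p <- as.integer(period)
  x <- split_chars(seq$residues)
  L <- length(x)
  if (L < 2L * p) stop_plastex("fewer than 2 complete units available")
  is_dna <- seq$alphabet == "DNA"
  deltas <- if (is_dna) c(0L, -3L, 3L) else c(0L, -1L, 1L, -2L, 2L)
  deltas <- deltas[abs(deltas) <= (if (is_dna) 3L else length_tol)]

  grid_units <- function(k) {
    starts <- seq(k, L - p, by = p)
    vapply(starts, function(s) paste(x[(s + 1L):(s + p)], collapse = ""),
           character(1))
  }
  ident <- function(a, b) {
    n <- min(length(a), length(b))
    if (n == 0L) return(NA_real_)
    mean(a[seq_len(n)] == b[seq_len(n)])
  }
  min_tail <- p - (if (is_dna) 3L else length_tol)
  # greedy cut from a fixed phase: unit lengths p + delta, the next cut
  # chosen by the unit's own identity to the reference combined with a
  # look-ahead at the following window
  greedy_from <- function(phase) {
    ref <- x[(phase + 1L):(phase + p)]
    s <- phase
    units <- character(0); starts <- integer(0); idents <- numeric(0)
    while (L - s >= min_tail) {
      cand <- vapply(deltas, function(d) {
        Lc <- p + d
        if (s + Lc > L) return(NA_real_)
        own <- ident(x[(s + 1L):(s + Lc)], ref)
        nxt_from <- s + Lc
        avail <- L - nxt_from
        look <- if (avail >= max(3L, p %/% 2L)) {
          ident(x[(nxt_from + 1L):min(nxt_from + p, L)], ref)
        } else own
        0.5 * own + 0.5 * look
      }, numeric(1))
      if (all(is.na(cand))) break
      d <- deltas[which.max(cand)]
      Lc <- p + d
      units <- c(units, paste(x[(s + 1L):(s + Lc)], collapse = ""))
      starts <- c(starts, s)
      idents <- c(idents, ident(x[(s + 1L):(s + Lc)], ref))
      s <- s + Lc
    }
    list(units = units, starts = starts,
         score = if (length(idents)) mean(idents) else -Inf)
  }
  phases <- 0:(p - 1L)
  phase <- NULL
  if (!is.null(anchor_residue)) {
    counts <- vapply(phases, function(k) {
      sum(substr(grid_units(k), 1L, 1L) == anchor_residue)
    }, integer(1))
    if (max(counts) > 0L) phase <- phases[which.max(counts)]
  }
  if (is.null(phase)) {
    # fall back to the phase whose greedy segmentation is most
    # self-consistent
    fits <- lapply(phases, greedy_from)
    phase <- phases[which.max(vapply(fits, `[[`, numeric(1), "score"))]
    fit <- fits[[phase + 1L]]
  } else {
    fit <- greedy_from(phase)
  }
  units <- fit$units
  starts <- fit$starts
  if (length(units) < 2L) stop_plastex("fewer than 2 complete units found")
  structure(list(source_id = seq$id, units = units, starts = starts,
                 period = p, anchor_residue = anchor_residue,
                 alphabet = seq$alphabet, alignment = NULL,
                 edits = data.frame(unit = integer(0), position = integer(0),
                                    residue = character(0)),
                 loci = NULL),
            class = "repeat_array")
}

#' @export
print.repeat_array <- function(x, ...) {
  cat(sprintf("<repeat_array> %s: %d unit(s), period %d (%s)\n", x$source_id,
              length(x$units), x$period, x$alphabet))
  if (!is.null(x$alignment)) {
    cat(sprintf("  aligned, %d column(s), %d recorded edit(s)\n",
                nchar(x$alignment[1]), nrow(x$edits)))
  }
  invisible(x)
}

# Build a repeat_array directly from pre-cut units (used when units come
# from multiple loci or external sources).
repeat_array_from_units <- function(units, source_id = "units",
                                    alphabet = "PROTEIN", period = NULL,
                                    loci = NULL) {
  if (is.null(period)) period <- as.integer(round(mean(nchar(units))))
  structure(list(source_id = source_id, units = units, starts = NULL,
                 period = period, anchor_residue = NULL, alphabet = alphabet,
                 alignment = NULL,
                 edits = data.frame(unit = integer(0), position = integer(0),
                                    residue = character(0)),
                 loci = loci),
            class = "repeat_array")
}

# Global alignment of a unit against the consensus; returns equal-length
# gapped strings (pattern, subject).
align_to_consensus <- function(unit, cons, alphabet) {
  if (alphabet == "PROTEIN") {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(unit), Biostrings::AAString(cons),
      type = "global", substitutionMatrix = blosum62_matrix(),
      gapOpening = 10, gapExtension = 0.5)
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                    baseOnly = FALSE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(unit), Biostrings::DNAString(cons),
      type = "global", substitutionMatrix = mat,
      gapOpening = 10, gapExtension = 0.5)
  }
  list(pattern = as.character(Biostrings::alignedPattern(pa)),
       subject = as.character(Biostrings::alignedSubject(pa)))
}

# Majority residue per column of equal-length strings; gaps excluded from
# the vote (ties broken lexicographically).
stack_majority <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  paste(apply(m, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return("-")
    tb <- table(col)
    names(tb)[which.max(tb)]  # which.max takes first => lexicographic tie
  }), collapse = "")
}

#' Align repeat units by iterated star alignment against their consensus
#'
#' Each unit is globally aligned against the current consensus; the pairwise
#' alignments are merged into one rectangular alignment, the consensus is
#' recalled, and the procedure is iterated (twice by default). A unit
#' carrying a single-residue insertion that no other unit shares may instead
#' have that one residue deleted when this yields higher summed column
#' agreement (gap characters penalized) than opening a gap column in every
#' other row; every such edit is recorded in \code{edits}. At most one
#' deletion per unit is permitted.
#'
#' @param arr A \code{\link{repeat_array}} with at least 2 units.
#' @param iterations Number of align-recall rounds (default 2).
#' @return The \code{repeat_array} with \code{alignment} and \code{edits}
#'   filled.
#' @export
align_units <- function(arr, iterations = 2L) {
  stopifnot(inherits(arr, "repeat_array"))
  units <- arr$units
  if (length(units) < 2L) stop_plastex("need >= 2 units to align")
  n <- length(units)
  edits <- arr$edits
  work <- units

  # initial consensus: majority over the modal-length units, ungapped stack
  modal_len <- as.integer(names(which.max(table(nchar(work)))))
  cons <- stack_majority(work[nchar(work) == modal_len])

  for (iter in seq_len(iterations)) {
    pas <- lapply(work, align_to_consensus, cons = cons,
                  alphabet = arr$alphabet)
    # identify single-residue insertions (gap in consensus row) unique to
    # one unit and decide insertion-vs-deletion by the agreement score:
    # keeping the insertion adds a column with 1 match and n-1 gaps
    # (delta = 2 - n); deleting the residue costs nothing (delta = 0).
    if (n > 2L) {
      ins_slot <- function(pa) {
        subj <- split_chars(pa$subject)
        runs <- rle(subj == "-")
        if (sum(runs$values & runs$lengths == 1L) == 1L &&
            sum(runs$lengths[runs$values]) == 1L) {
          which(subj == "-")
        } else NA_integer_
      }
      slots <- vapply(pas, ins_slot, integer(1))
      for (i in which(!is.na(slots))) {
        if (i %in% edits$unit) next
        # unique to this unit?
        same <- vapply(pas[-i], function(pa) {
          any(split_chars(pa$subject) == "-")
        }, logical(1))
        if (any(same)) next
        patt <- split_chars(pas[[i]]$pattern)
        col <- slots[i]
        pos_in_unit <- sum(patt[seq_len(col)] != "-")
        residue <- patt[col]
        work[i] <- paste0(substr(work[i], 1L, pos_in_unit - 1L),
                          substr(work[i], pos_in_unit + 1L, nchar(work[i])))
        edits <- rbind(edits, data.frame(unit = i, position = pos_in_unit,
                                         residue = residue))
        pas[[i]] <- align_to_consensus(work[i], cons, arr$alphabet)
      }
    }
    rows <- merge_star(pas, nchar(cons))
    cons <- gsub("-", "", stack_majority(rows), fixed = TRUE)
  }
  arr$alignment <- rows
  arr$edits <- edits
  arr
}

# Merge pairwise (unit vs consensus) alignments into one rectangular
# alignment over a common consensus coordinate system.
merge_star <- function(pas, cons_len) {
  n <- length(pas)
  # per unit: residue aligned to each consensus position ("-" if deletion),
  # plus insertion strings keyed by the consensus position they follow
  # (0 = before the first).
  aligned <- matrix("-", n, cons_len)
  inserts <- vector("list", n)
  for (i in seq_len(n)) {
    patt <- split_chars(pas[[i]]$pattern)
    subj <- split_chars(pas[[i]]$subject)
    ins <- list()
    cpos <- 0L
    for (k in seq_along(subj)) {
      if (subj[k] == "-") {
        key <- as.character(cpos)
        ins[[key]] <- paste0(if (is.null(ins[[key]])) "" else ins[[key]],
                             patt[k])
      } else {
        cpos <- cpos + 1L
        aligned[i, cpos] <- patt[k]
      }
    }
    inserts[[i]] <- ins
  }
  max_ins <- integer(cons_len + 1L)
  for (i in seq_len(n)) {
    for (key in names(inserts[[i]])) {
      k <- as.integer(key) + 1L
      max_ins[k] <- max(max_ins[k], nchar(inserts[[i]][[key]]))
    }
  }
  vapply(seq_len(n), function(i) {
    parts <- character(0)
    for (cpos in 0:cons_len) {
      w <- max_ins[cpos + 1L]
      if (w > 0L) {
        s <- inserts[[i]][[as.character(cpos)]]
        if (is.null(s)) s <- ""
        parts <- c(parts, paste0(s, strrep("-", w - nchar(s))))
      }
      if (cpos < cons_len) parts <- c(parts, aligned[i, cpos + 1L])
    }
    paste(parts, collapse = "")
  }, character(1))
}

#' Call a consensus profile from an aligned repeat array
#'
#' Per-column majority residue over non-gap characters, with lexicographic
#' tie-breaking (flagged). Columns where more than half the rows are gapped
#' are insertion columns and are excluded from the consensus string (but
#' retained in the frequency matrix). When the array carries locus labels, a
#' per-column robustness flag records whether the same residue is modal in
#' every locus-specific sub-alignment.
#'
#' @param arr An aligned \code{\link{repeat_array}} (see
#'   \code{\link{align_units}}), or one whose units all have equal length.
#' @param loci Optional factor of locus labels, one per unit (defaults to
#'   \code{arr$loci}).
#' @return An object of class \code{consensus_profile} with fields
#'   \code{consensus}, \code{column_frequencies}, \code{information_content},
#'   \code{gap_fraction}, \code{n_units}, \code{robust}, \code{ties}.
#' @export
build_consensus <- function(arr, loci = NULL) {
  stopifnot(inherits(arr, "repeat_array"))
  rows <- arr$alignment
  if (is.null(rows)) {
    if (length(unique(nchar(arr$units))) != 1L) {
      stop_plastex("units differ in length; run align_units() first")
    }
    rows <- arr$units
  }
  if (!length(rows)) stop_plastex("empty alignment")
  if (is.null(loci)) loci <- arr$loci
  m <- do.call(rbind, strsplit(rows, ""))
  n <- nrow(m)
  alpha_chars <- if (arr$alphabet == "DNA") DNA_CHARS[1:4] else AA_CHARS
  nc <- ncol(m)
  freqs <- matrix(0, length(alpha_chars), nc,
                  dimnames = list(alpha_chars, NULL))
  gap_fraction <- numeric(nc)
  cons_chars <- character(nc)
  ties <- logical(nc)
  robust <- rep(NA, nc)
  for (j in seq_len(nc)) {
    col <- m[, j]
    gap_fraction[j] <- mean(col == "-")
    res <- col[col != "-" & col %in% alpha_chars]
    if (length(res)) {
      tb <- table(factor(res, levels = alpha_chars))
      freqs[, j] <- as.numeric(tb) / length(res)
      mx <- max(tb)
      winners <- names(tb)[tb == mx]
      cons_chars[j] <- sort(winners)[1]
      ties[j] <- length(winners) > 1L
      if (!is.null(loci)) {
        robust[j] <- all(vapply(split(col, loci), function(sub) {
          sub <- sub[sub != "-"]
          if (!length(sub)) return(FALSE)
          tb2 <- table(sub)
          cons_chars[j] %in% names(tb2)[tb2 == max(tb2)]
        }, logical(1)))
      }
    } else {
      cons_chars[j] <- "-"
    }
  }
  keep <- gap_fraction <= 0.5 & cons_chars != "-"
  ic <- column_information(freqs, gap_fraction, length(alpha_chars))
  structure(list(consensus = paste(cons_chars[keep], collapse = ""),
                 consensus_columns = which(keep),
                 column_frequencies = freqs,
                 information_content = ic,
                 gap_fraction = gap_fraction,
                 n_units = n, robust = robust, ties = ties,
                 alphabet = arr$alphabet),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("<consensus_profile> %d units, %d column(s)\n  consensus: %s\n",
              x$n_units, length(x$gap_fraction), x$consensus))
  invisible(x)
}

column_information <- function(freqs, gap_fraction, alphabet_size) {
  apply(rbind(freqs, gap_fraction), 2, function(col) {
    gf <- col[length(col)]
    f <- col[-length(col)]
    if (gf >= 1) return(0)
    f <- f[f > 0]
    log2(alphabet_size) + sum(f * log2(f))
  })
}

#' Percent identity between two equal-length (possibly gapped) strings
#'
#' Matches are identical non-gap column pairs; columns where both strings
#' have a gap are skipped; a gap opposite a residue counts as a mismatch.
#' The percentage is rounded half-up to an integer, so 10/13 prints as 77.
#'
#' @param a,b Character scalars of equal length.
#' @param ambig Characters that never count as matches (default \code{"X"},
#'   the protein ambiguity code; pass \code{"N"} for DNA comparisons).
#' @return List with \code{matches}, \code{length} (columns with at least
#'   one non-gap), and \code{percent}.
#' @export
#' @examples
#' percent_identity("EYTKVTKVIEGEP", "SITKVTRVIEGEP")  # 10 / 13 -> 77
percent_identity <- function(a, b, ambig = "X") {
  ca <- split_chars(a); cb <- split_chars(b)
  if (length(ca) != length(cb)) {
    stop_plastex("sequences must have equal (aligned) length")
  }
  both_gap <- ca == "-" & cb == "-"
  ca <- ca[!both_gap]; cb <- cb[!both_gap]
  if (!length(ca)) stop_plastex("zero-length comparison")
  matches <- sum(ca == cb & ca != "-" & !(ca %in% ambig))
  len <- length(ca)
  list(matches = matches, length = len,
       percent = floor(matches / len * 100 + 0.5))
}

#' Cyclic rotation of a consensus string
#'
#' @param c Consensus string.
#' @param new_start 0-based index of the residue that becomes position 1.
#' @return The rotated string.
#' @export
#' @examples
#' rotate_consensus("PSITKVTRVIEGE", 1)  # "SITKVTRVIEGEP"
rotate_consensus <- function(c, new_start) {
  n <- nchar(c)
  if (new_start < 0 || new_start >= n) stop_plastex("index out of range")
  if (new_start == 0) return(c)
  paste0(substr(c, new_start + 1L, n), substr(c, 1L, new_start))
}

#' Side-by-side duplication of a consensus
#'
#' Concatenates the consensus with itself, the standard query construction
#' for repeat-homology searches (a 13-residue unit becomes a 26-residue
#' query).
#'
#' @param c Non-empty consensus string.
#' @return \code{c} concatenated with itself.
#' @export
doubled_consensus <- function(c) {
  if (!nzchar(c)) stop_plastex("empty consensus")
  paste0(c, c)
}

#' Sequence-logo matrix: per-column frequencies and information content
#'
#' Information content per column is \code{log2(A) + sum(f * log2(f))} over
#' non-gap residues (A = alphabet size), deliberately without small-sample
#' correction. Letter heights are \code{f * IC}. All-gap columns have
#' undefined IC, reported as 0 with gap fraction 1.
#'
#' @param alignment A \code{\link{repeat_array}} with alignment filled, a
#'   \code{consensus_profile}, or a character vector of equal-length gapped
#'   rows.
#' @param alphabet \code{"PROTEIN"} or \code{"DNA"} (ignored when it can be
#'   taken from the object).
#' @return Data frame with one row per (column, residue) pair:
#'   \code{column}, \code{residue}, \code{frequency}, \code{ic} (column
#'   information content, bits), \code{height}, plus per-column
#'   \code{gap_fraction}.
#' @export
logo_matrix <- function(alignment, alphabet = "PROTEIN") {
  if (inherits(alignment, "repeat_array")) {
    prof <- build_consensus(alignment)
  } else if (inherits(alignment, "consensus_profile")) {
    prof <- alignment
  } else {
    arr <- repeat_array_from_units(alignment, alphabet = alphabet)
    arr$alignment <- alignment
    prof <- build_consensus(arr)
  }
  freqs <- prof$column_frequencies
  ic <- prof$information_content
  nc <- ncol(freqs)
  out <- do.call(rbind, lapply(seq_len(nc), function(j) {
    nz <- which(freqs[, j] > 0)
    if (!length(nz)) {
      return(data.frame(column = j, residue = "-", frequency = 0,
                        ic = 0, height = 0,
                        gap_fraction = prof$gap_fraction[j]))
    }
    data.frame(column = j, residue = rownames(freqs)[nz],
               frequency = freqs[nz, j], ic = ic[j],
               height = freqs[nz, j] * ic[j],
               gap_fraction = prof$gap_fraction[j])
  }))
  rownames(out) <- NULL
  out
}

#' Descriptive report of repeat consensus characteristics
#'
#' Summarizes, per consensus position, the modal residue, its frequency,
#' information content, and simple physicochemical annotation (hydrophobic,
#' positively/negatively charged), the descriptive counterpart of the
#' repeat's hallmark pattern (anchor proline, hydrophobic core interspersed
#' with basic residues, acidic tail). These are reported, never enforced.
#'
#' @param profile A \code{consensus_profile}.
#' @return Data frame, one row per consensus position.
#' @export
repeat_report <- function(profile) {
  stopifnot(inherits(profile, "consensus_profile"))
  cols <- profile$consensus_columns
  chars <- split_chars(profile$consensus)
  hydrophobic <- c("A", "V", "L", "I", "M", "F", "W", "C", "T")
  positive <- c("K", "R", "H")
  negative <- c("D", "E")
  data.frame(
    position = seq_along(cols),
    residue = chars,
    frequency = vapply(seq_along(cols), function(i) {
      profile$column_frequencies[chars[i], cols[i]]
    }, numeric(1)),
    ic_bits = profile$information_content[cols],
    class = vapply(chars, function(ch) {
      if (ch %in% positive) "positive"
      else if (ch %in% negative) "negative"
      else if (ch %in% hydrophobic) "hydrophobic"
      else "other"
    }, character(1)),
    row.names = NULL
  )
}

#' Write an aligned repeat array as aligned FASTA
#'
#' @param arr An aligned \code{\link{repeat_array}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_repeat_alignment <- function(arr, path) {
  stopifnot(inherits(arr, "repeat_array"), !is.null(arr$alignment))
  ids <- sprintf("%s_unit%02d", arr$source_id, seq_along(arr$alignment))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(arr$alignment)) {
    writeLines(c(paste0(">", ids[i]), arr$alignment[i]), con)
  }
  invisible(path)
}
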