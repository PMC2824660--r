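# Map local-alignment amino-acid coordinates (1-based, inclusive) in a
# translated frame back to 0-based half-open genomic coordinates.
aa_to_genomic <- function(aa_start, aa_end, frame, strand, glen) {
  g1 <- frame + 3L * (aa_start - 1L)
  g2 <- frame + 3L * aa_end
  if (strand == "+") c(g1, g2) else c(glen - g2, glen - g1)
}

# Decompose a local pairwise alignment into gap-bounded HSP segments:
# splitting at any gap run longer than `max_gap` columns (intron-scale
# jumps), rescoring each segment with the same affine penalties, and
# reporting 1-based aa coordinates in pattern (query) and subject (target).
split_hsp_segments <- function(pa, subst, min_score, max_gap = 5L,
                               gap_open = 11, gap_ext = 1) {
  patt <- split_chars(as.character(Biostrings::alignedPattern(pa)))
  subj <- split_chars(as.character(Biostrings::alignedSubject(pa)))
  q0 <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  t0 <- Biostrings::start(Biostrings::subject(pa)) - 1L
  is_gap <- patt == "-" | subj == "-"
  r <- rle(is_gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # segment boundaries: long gap runs split; short gaps stay internal
  cutpoints <- which(r$values & r$lengths > max_gap)
  seg_bounds <- list()
  seg_start <- 1L
  for (k in cutpoints) {
    seg_bounds[[length(seg_bounds) + 1L]] <- c(seg_start, starts[k] - 1L)
    seg_start <- ends[k] + 1L
  }
  seg_bounds[[length(seg_bounds) + 1L]] <- c(seg_start, length(patt))
  qpos <- cumsum(patt != "-")
  tpos <- cumsum(subj != "-")
  rows <- lapply(seg_bounds, function(b) {
    if (b[1] > b[2]) return(NULL)
    idx <- b[1]:b[2]
    # trim flanking gap columns
    nong <- idx[!is_gap[idx]]
    if (!length(nong)) return(NULL)
    idx <- nong[1]:nong[length(nong)]
    # per-column scores: substitution for paired columns; gap columns pay
    # the extension, plus the open cost on the first column of each run
    colscore <- function(ix) {
      pc <- patt[ix]; sc <- subj[ix]
      gapped <- pc == "-" | sc == "-"
      v <- numeric(length(ix))
      v[!gapped] <- subst[cbind(pc[!gapped], sc[!gapped])]
      v[gapped] <- -gap_ext
      opens <- gapped & !c(FALSE, gapped[-length(gapped)])
      v[opens] <- v[opens] - gap_open
      v
    }
    # trim to the maximal-scoring contiguous sub-block: segments produced
    # by splitting a masked re-search are not guaranteed locally maximal
    # and can carry net-negative junk flanks
    v <- colscore(idx)
    best <- 0; best_i <- 1L; best_j <- 0L
    cur <- 0; cur_i <- 1L
    for (k in seq_along(v)) {
      if (cur <= 0) { cur <- 0; cur_i <- k }
      cur <- cur + v[k]
      if (cur > best) { best <- cur; best_i <- cur_i; best_j <- k }
    }
    if (best_j < best_i) return(NULL)
    idx <- idx[best_i:best_j]
    nong2 <- idx[!is_gap[idx]]
    if (!length(nong2)) return(NULL)
    idx <- nong2[1]:nong2[length(nong2)]
    pc <- patt[idx]; sc <- subj[idx]
    paired <- pc != "-" & sc != "-"
    score <- sum(colscore(idx))
    if (score < min_score) return(NULL)
    data.frame(q_start = q0 + qpos[idx[1]], q_end = q0 + qpos[idx[length(idx)]],
               t_start = t0 + tpos[idx[1]], t_end = t0 + tpos[idx[length(idx)]],
               score = score,
               identity = mean(pc[paired] == sc[paired]))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(q_start = integer(0), q_end = integer(0),
                      t_start = integer(0), t_end = integer(0),
                      score = numeric(0), identity = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Translated local-alignment search of a protein query against genomic DNA
#'
#' Smith-Waterman local alignments (BLOSUM62, affine gaps, gap open 11 /
#' extend 1) of the query against all six translated frames. No
#' low-complexity masking is applied and the score threshold is permissive
#' by default, so repetitive queries report all their overlapping HSPs.
#' Multiple HSPs per frame are found by iteratively masking previous hit
#' regions.
#'
#' @param query Protein \code{\link{bio_seq}}, at least 10 residues.
#' @param genomic DNA \code{\link{bio_seq}}, at least 30 nt.
#' @param min_score Minimum HSP alignment score (default 40, deliberately
#'   low).
#' @param max_hsps_per_frame Safety cap on HSPs reported per frame.
#' @return Data frame of HSPs: \code{genomic_start}, \code{genomic_end}
#'   (0-based half-open), \code{strand}, \code{frame}, \code{query_start},
#'   \code{query_end} (1-based aa), \code{score},
#'   \code{identity_fraction}.
#' @export
translated_hsp_search <- function(query, genomic, min_score = 40,
                                  max_hsps_per_frame = 50L) {
  stopifnot(inherits(query, "bio_seq"), inherits(genomic, "bio_seq"))
  if (query$alphabet != "PROTEIN") stop_plastex("query must be protein")
  if (nchar(query$residues) < 10L) stop_plastex("query must be >= 10 aa")
  if (nchar(genomic$residues) < 30L) stop_plastex("genomic must be >= 30 nt")
  subst <- blosum62_matrix()
  glen <- nchar(genomic$residues)
  q <- Biostrings::AAString(gsub("[*]", "X", query$residues))
  frames <- translate_six_frames(genomic)
  out <- list()
  for (k in seq_along(frames)) {
    strand <- if (k <= 3L) "+" else "-"
    frame <- (k - 1L) %% 3L
    target <- gsub("[*]", "X", frames[[k]]$residues)
    for (rep in seq_len(max_hsps_per_frame)) {
      pa <- Biostrings::pairwiseAlignment(
        q, Biostrings::AAString(target), type = "local",
        substitutionMatrix = subst, gapOpening = 11, gapExtension = 1)
      if (Biostrings::score(pa) < min_score) break
      segs <- split_hsp_segments(pa, subst, min_score = min_score)
      if (!nrow(segs)) break
      for (s in seq_len(nrow(segs))) {
        g <- aa_to_genomic(segs$t_start[s], segs$t_end[s], frame, strand,
                           glen)
        out[[length(out) + 1L]] <- data.frame(
          genomic_start = g[1], genomic_end = g[2], strand = strand,
          frame = frame, query_start = segs$q_start[s],
          query_end = segs$q_end[s], score = segs$score[s],
          identity_fraction = segs$identity[s])
      }
      # mask the whole matched span and look for further HSPs
      ts <- Biostrings::start(Biostrings::subject(pa))
      te <- Biostrings::end(Biostrings::subject(pa))
      substr(target, ts, te) <- strrep("X", te - ts + 1L)
    }
  }
  if (!length(out)) {
    return(data.frame(genomic_start = integer(0), genomic_end = integer(0),
                      strand = character(0), frame = integer(0),
                      query_start = integer(0), query_end = integer(0),
                      score = numeric(0), identity_fraction = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$score), ]
  rownames(res) <- NULL
  res
}

#' Chain HSPs into a candidate ordered exon chain
#'
#' Weighted dynamic program over HSPs collinear in both query and genome on
#' one strand, with genomic gaps between consecutive HSPs constrained to
#' plausible intron lengths. Because local alignments overrun exon ends
#' into introns by chance matches, consecutive HSPs may overlap in the
#' query: the overlap is penalized at the lower score density of the two
#' HSPs (standard overlap-penalized chaining; the overrun causing the
#' overlap is low-density junk) up to \code{max_overlap_frac} of the
#' incoming HSP's span, and the genomic-gap floor is relaxed by three
#' nucleotides per overlapping residue. HSPs violating
#' collinearity are left out of the chain. The highest-scoring chain over
#' both strands is returned, in transcript order.
#'
#' @param hsps HSP data frame from \code{\link{translated_hsp_search}}.
#' @param max_intron Maximum intron length (default 50000; the genomic
#'   footprint of a typical multi-exon locus motivates the ceiling).
#' @param min_intron Minimum intron length (default 30).
#' @param max_overlap_frac Maximum query-span overlap between linked
#'   HSPs, as a fraction of the incoming HSP's span (default 1.0, i.e. only the requirement of at least one fresh query residue).
#' @return Data frame: the chained HSPs in transcript order, with
#'   attribute \code{chain_score}; zero rows (with a \code{diagnostic}
#'   attribute) when no valid chain exists.
#' @export
chain_exons <- function(hsps, max_intron = 50000L, min_intron = 30L,
                        max_overlap_frac = 1.0) {
  if (!nrow(hsps)) {
    out <- hsps
    attr(out, "diagnostic") <- "no HSPs to chain"
    return(out)
  }
  best_overall <- NULL
  best_score <- -Inf
  for (strand in unique(hsps$strand)) {
    h <- hsps[hsps$strand == strand, , drop = FALSE]
    # transcript order: ascending genomic for +, descending for -
    ord <- if (strand == "+") order(h$genomic_start, h$genomic_end)
           else order(-h$genomic_start, -h$genomic_end)
    h <- h[ord, , drop = FALSE]
    n <- nrow(h)
    dp <- h$score
    prev <- rep(NA_integer_, n)
    # sloppy HSP ends can overrun into introns on both sides, so the
    # apparent genomic gap may undershoot the true intron length (and even
    # go negative); boundary refinement restores the real splice sites
    span <- h$query_end - h$query_start + 1L
    for (j in seq_len(n)) {
      for (i in seq_len(j - 1L)) {
        if (h$query_end[j] <= h$query_end[i]) next
        q_overlap <- max(0L, h$query_end[i] - h$query_start[j] + 1L)
        if (q_overlap > max_overlap_frac * span[j]) next
        gap <- if (strand == "+") h$genomic_start[j] - h$genomic_end[i]
               else h$genomic_start[i] - h$genomic_end[j]
        if (gap < min_intron - 3L * q_overlap || gap > max_intron) next
        if (strand == "+") {
          if (h$genomic_start[j] <= h$genomic_start[i] ||
              h$genomic_end[j] <= h$genomic_end[i]) next
        } else {
          if (h$genomic_start[j] >= h$genomic_start[i] ||
              h$genomic_end[j] >= h$genomic_end[i]) next
        }
        dens <- min(h$score[i] / span[i], h$score[j] / span[j])
        penalty <- q_overlap * dens
        cand <- dp[i] + h$score[j] - penalty
        if (cand > dp[j]) { dp[j] <- cand; prev[j] <- i }
      }
    }
    jbest <- which.max(dp)
    if (dp[jbest] > best_score) {
      idx <- jbest
      while (!is.na(prev[idx[1]])) idx <- c(prev[idx[1]], idx)
      best_overall <- h[idx, , drop = FALSE]
      best_score <- dp[jbest]
    }
  }
  rownames(best_overall) <- NULL
  attr(best_overall, "chain_score") <- best_score
  best_overall
}

# Translate nucleotides (frame 0) to an AA string with stops as X.
nt_to_aa <- function(nt) {
  if (nchar(nt) < 3L) return("")
  gsub("[*]", "X",
       as.character(translate_dna(bio_seq(nt, alphabet = "DNA"))$residues))
}

#' Refine exon boundaries to canonical GT-AG splice sites
#'
#' For each junction between chained HSPs, donor and acceptor positions are
#' searched within \code{window} nt of the HSP ends; only canonical sites
#' (intron starting \code{GT}, ending \code{AG}) are eligible — GC-AG and
#' AT-AC variants are rejected. Among eligible pairs, the one maximizing
#' the local alignment score of the translated junction against the query
#' wins, with reading-frame continuity carried across exons
#' (\code{phase[i+1] = (phase[i] + length[i]) mod 3}). A junction with no
#' GT-AG-compatible boundary in the window is flagged unresolved and keeps
#' its HSP-derived boundaries.
#'
#' @param chain Chained HSPs (one strand) from \code{\link{chain_exons}}.
#' @param genomic DNA \code{\link{bio_seq}}.
#' @param query Protein \code{\link{bio_seq}} used for junction scoring.
#' @param window Search half-width in nt around each HSP end (default 15).
#' @param min_intron Minimum intron length (default 30).
#' @return A \code{\link{gene_model}} with exon labels \code{"1"},
#'   \code{"2"}, ... and an \code{unresolved} attribute (logical per
#'   junction).
#' @export
refine_boundaries <- function(chain, genomic, query, window = 15L,
                              min_intron = 30L) {
  if (!nrow(chain)) stop_plastex("empty chain")
  strand <- chain$strand[1]
  glen <- nchar(genomic$residues)
  if (strand == "-") {
    rc <- reverse_complement(genomic)
    flipped <- chain
    flipped$genomic_start <- glen - chain$genomic_end
    flipped$genomic_end <- glen - chain$genomic_start
    flipped$strand <- "+"
    flipped <- flipped[order(flipped$genomic_start), , drop = FALSE]
    model <- refine_boundaries(flipped, rc, query, window, min_intron)
    exons <- lapply(rev(model$exons), function(e) {
      exon_model(glen - e$end, glen - e$start, "-", e$phase, e$donor,
                 e$acceptor, e$label)
    })
    out <- gene_model(genomic$id, exons, "-",
                      coding_complete = model$coding_complete,
                      contig_length = glen, validate = FALSE)
    attr(out, "unresolved") <- attr(model, "unresolved")
    return(out)
  }
  res <- genomic$residues
  subst <- blosum62_matrix()
  qaa <- Biostrings::AAString(gsub("[*]", "X", query$residues))
  n <- nrow(chain)
  starts <- chain$genomic_start
  ends <- chain$genomic_end
  unresolved <- logical(max(n - 1L, 0L))
  cum_len <- 0L
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      d0 <- ends[i]; a0 <- starts[i + 1L]
      # widen the search when the HSPs' query spans overlap: local
      # alignments overrun exon ends by chance intron matches, and the
      # overlap measures that overrun
      q_overlap <- max(0L, chain$query_end[i] - chain$query_start[i + 1L] + 1L)
      win <- window + 3L * q_overlap
      dn <- max(starts[i] + 3L, d0 - win):min(glen - 2L, d0 + win)
      donors <- dn[substring(res, dn + 1L, dn + 2L) == "GT"]
      an <- max(2L, a0 - win):min(ends[i + 1L] - 3L, a0 + win)
      acceptors <- an[substring(res, an - 1L, an) == "AG"]
      if (!length(donors) || !length(acceptors)) {
        unresolved[i] <- TRUE
        cum_len <- cum_len + (ends[i] - starts[i])
        next
      }
      grid <- expand.grid(d = donors, a = acceptors)
      grid <- grid[grid$a - grid$d >= min_intron, , drop = FALSE]
      if (!nrow(grid)) {
        unresolved[i] <- TRUE
        cum_len <- cum_len + (ends[i] - starts[i])
        next
      }
      sc <- vapply(seq_len(nrow(grid)), function(k) {
        d <- grid$d[k]; a <- grid$a[k]
        len_i <- d - starts[i]
        # tail starting on a codon boundary of the running CDS
        tail_len <- min(36L, len_i)
        tail_len <- tail_len - (cum_len + len_i - tail_len) %% 3L
        if (tail_len < 3L) tail_len <- tail_len + 3L
        tail_nt <- substr(res, d - tail_len + 1L, d)
        head_nt <- substr(res, a + 1L, min(a + 36L, ends[i + 1L]))
        pep <- nt_to_aa(paste0(tail_nt, head_nt))
        if (nchar(pep) < 2L) return(-Inf)
        Biostrings::score(Biostrings::pairwiseAlignment(
          Biostrings::AAString(pep), qaa, type = "local",
          substitutionMatrix = subst, gapOpening = 11, gapExtension = 1))
      }, numeric(1))
      drift <- abs(grid$d - d0) + abs(grid$a - a0)
      pick <- order(-sc, drift)[1]
      ends[i] <- grid$d[pick]
      starts[i + 1L] <- grid$a[pick]
      cum_len <- cum_len + (ends[i] - starts[i])
    }
  }
  exons <- lapply(seq_len(n), function(i) {
    fl <- exon_flanks(genomic, starts[i], ends[i], "+")
    exon_model(starts[i], ends[i], "+",
               phase = if (i == 1L) 0L else
                 (sum(ends[seq_len(i - 1L)] - starts[seq_len(i - 1L)])) %% 3L,
               donor = if (i < n) fl$donor else "",
               acceptor = if (i > 1L) fl$acceptor else "",
               label = as.character(i))
  })
  total <- sum(ends - starts)
  out <- gene_model(genomic$id, exons, "+",
                    coding_complete = total %% 3L == 0L,
                    contig_length = glen, validate = FALSE)
  attr(out, "unresolved") <- unresolved
  out
}

#' Hallmark validation of a single exon
#'
#' The three basic hallmarks of a functional cassette exon:
#' \code{frame_preserving} (length divisible by 3, so the exon can be
#' skipped without a frameshift), \code{stop_free} (no stop codon in the
#' exon's phase-consistent reading), and \code{splice_canonical} (intronic
#' flanks \code{GT}...\code{AG}). \code{overall} is their conjunction.
#'
#' @param exon An \code{\link{exon_model}}.
#' @param genomic DNA \code{\link{bio_seq}} (used for flanks not already
#'   stored on the exon and for the exon sequence).
#' @return List of class \code{hallmark_report} with the three booleans
#'   and \code{overall}.
#' @export
validate_exon <- function(exon, genomic) {
  stopifnot(inherits(exon, "exon_model"), inherits(genomic, "bio_seq"))
  len <- exon_length(exon)
  frame_preserving <- len %% 3L == 0L
  res <- if (exon$strand == "+") genomic$residues
         else reverse_complement(genomic)$residues
  glen <- nchar(genomic$residues)
  s <- if (exon$strand == "+") exon$start else glen - exon$end
  exon_nt <- substr(res, s + 1L, s + len)
  offset <- (3L - exon$phase) %% 3L
  stop_free <- TRUE
  if (nchar(exon_nt) - offset >= 3L) {
    aa <- translate_dna(bio_seq(exon_nt, alphabet = "DNA"), frame = offset)
    stop_free <- !grepl("*", aa$residues, fixed = TRUE)
  }
  donor <- exon$donor; acceptor <- exon$acceptor
  if (!nzchar(donor) || !nzchar(acceptor)) {
    fl <- exon_flanks(genomic, exon$start, exon$end, exon$strand)
    if (!nzchar(donor)) donor <- fl$donor
    if (!nzchar(acceptor)) acceptor <- fl$acceptor
  }
  splice_canonical <- identical(donor, "GT") && identical(acceptor, "AG")
  structure(list(frame_preserving = frame_preserving, stop_free = stop_free,
                 splice_canonical = splice_canonical,
                 overall = frame_preserving && stop_free && splice_canonical),
            class = "hallmark_report")
}

#' @export
print.hallmark_report <- function(x, ...) {
  cat(sprintf(
    "<hallmark_report> frame %s | stop-free %s | GT-AG %s -> overall %s\n",
    x$frame_preserving, x$stop_free, x$splice_canonical, x$overall))
  invisible(x)
}

#' Hallmark report for every exon of a model
#'
#' @param model A \code{\link{gene_model}}.
#' @param genomic DNA \code{\link{bio_seq}}.
#' @return Data frame, one row per exon.
#' @export
validate_model <- function(model, genomic) {
  rows <- lapply(model$exons, function(e) {
    h <- validate_exon(e, genomic)
    data.frame(label = e$label, start = e$start, end = e$end,
               length = exon_length(e),
               frame_preserving = h$frame_preserving,
               stop_free = h$stop_free,
               splice_canonical = h$splice_canonical, overall = h$overall)
  })
  do.call(rbind, rows)
}

#' Reconstruct the protein encoded by a gene model
#'
#' Exons are spliced in transcript order and translated in phase. An
#' internal stop codon or a total length not divisible by 3 is an error.
#'
#' @param model Coding-complete \code{\link{gene_model}}.
#' @param genomic DNA \code{\link{bio_seq}}.
#' @return Protein \code{\link{bio_seq}}.
#' @export
reconstruct_protein <- function(model, genomic) {
  cds <- splice_transcript(model, genomic)
  if (nchar(cds$residues) %% 3L != 0L) {
    stop_plastex("spliced CDS length ", nchar(cds$residues),
                 " is not divisible by 3 (frameshift)")
  }
  aa <- translate_dna(cds)
  res <- aa$residues
  if (substr(res, nchar(res), nchar(res)) == "*") {
    res <- substr(res, 1L, nchar(res) - 1L)
  }
  if (grepl("*", res, fixed = TRUE)) {
    stop_plastex("internal stop codon in spliced translation")
  }
  bio_seq(res, id = paste0(model$contig_id, "_protein"),
          alphabet = "PROTEIN")
}

#' Windowed conservation profile of two genomic sequences
#'
#' Global pairwise alignment (affine gaps), then percent identity per
#' sliding window of alignment columns (a gap opposite a residue counts as
#' a mismatch). Window intervals are classified against a conservation
#' threshold, 75\% by default. The input order of the two sequences does
#' not affect the values.
#'
#' @param genomicA,genomicB DNA \code{\link{bio_seq}}s.
#' @param window Window size in alignment columns (default 100).
#' @param step Step between windows (default 25).
#' @param threshold Peak classification threshold in percent (default 75).
#' @return Object of class \code{conservation_track}: data frame of windows
#'   (\code{col_start}, \code{col_end}, \code{percent_identity},
#'   \code{class}) with the threshold and alignment length as attributes.
#' @export
conservation_profile <- function(genomicA, genomicB, window = 100L,
                                 step = 25L, threshold = 75) {
  stopifnot(inherits(genomicA, "bio_seq"), inherits(genomicB, "bio_seq"))
  # canonical input order => symmetric output
  if (genomicA$residues > genomicB$residues) {
    tmp <- genomicA; genomicA <- genomicB; genomicB <- tmp
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(genomicA$residues),
    Biostrings::DNAString(genomicB$residues), type = "global",
    substitutionMatrix = mat, gapOpening = 6, gapExtension = 0.5)
  ra <- split_chars(as.character(Biostrings::alignedPattern(pa)))
  rb <- split_chars(as.character(Biostrings::alignedSubject(pa)))
  L <- length(ra)
  if (window > L) stop_plastex("window larger than alignment length ", L)
  match_col <- ra == rb & ra != "-" & ra != "N"
  starts <- seq(1L, L - window + 1L, by = step)
  pid <- vapply(starts, function(s) {
    100 * mean(match_col[s:(s + window - 1L)])
  }, numeric(1))
  df <- data.frame(col_start = starts, col_end = starts + window - 1L,
                   percent_identity = pid,
                   class = ifelse(pid > threshold, "high", "low"))
  structure(df, class = c("conservation_track", "data.frame"),
            window = window, step = step, threshold = threshold,
            alignment_length = L)
}

#' Intervals of a conservation track by class
#'
#' @param track A \code{conservation_track}.
#' @return Data frame of maximal runs of same-class windows:
#'   \code{col_start}, \code{col_end}, \code{class}, \code{mean_identity}.
#' @export
conservation_peaks <- function(track) {
  cls <- track$class
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(col_start = track$col_start[starts],
             col_end = track$col_end[ends], class = r$values,
             mean_identity = vapply(seq_along(starts), function(k) {
               mean(track$percent_identity[starts[k]:ends[k]])
             }, numeric(1)))
}
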