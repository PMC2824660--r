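#' Dot-matrix plot configuration
#'
#' Window scores are raw sums over the aligned window (no gaps inside a
#' window), matching the integer arithmetic of classic dot-matrix tools:
#' DNA defaults to +5/match, -4/mismatch with window 50; proteins use a
#' substitution matrix (BLOSUM62) with window 5. Grey-map bounds control
#' rendering only: scores at or below \code{greymap_top} map to the black
#' end, scores at or above \code{greymap_bottom} to the white end (white =
#' highest similarity), linear in between.
#'
#' @param window Sliding window size (>= 1, must fit both sequences).
#' @param match_score,mismatch_score DNA per-position scores.
#' @param matrix_name Protein substitution matrix name (only
#'   \code{"BLOSUM62"} is shipped).
#' @param greymap_top,greymap_bottom Display bounds (top < bottom); the
#'   classic settings are 0/35 for DNA repeat displays and 0/245 for
#'   protein plots at full dynamic range.
#' @param color_scale Optional ordered palette applied after grey mapping
#'   (default the white-yellow-orange-red-black continuum, white = highest).
#' @return An object of class \code{dotplot_config}.
#' @export
dotplot_config <- function(window = 50L, match_score = 5, mismatch_score = -4,
                           matrix_name = "BLOSUM62", greymap_top = 0,
                           greymap_bottom = 245, color_scale = NULL) {
  if (window < 1L) stop_plastex("window must be >= 1")
  if (greymap_top >= greymap_bottom) {
    stop_plastex("greymap_top must be < greymap_bottom")
  }
  structure(list(window = as.integer(window), match_score = match_score,
                 mismatch_score = mismatch_score, matrix_name = matrix_name,
                 greymap_top = greymap_top, greymap_bottom = greymap_bottom,
                 color_scale = color_scale),
            class = "dotplot_config")
}

#' Compute a windowed dot matrix between two sequences
#'
#' Cell \code{[i, j]} is the summed pairwise score of the length-\code{w}
#' windows starting at position \code{i} of \code{a} and \code{j} of
#' \code{b}. Windows are computed only where they lie fully inside both
#' sequences (no padding), which avoids edge artifacts in diagonal
#' detection. Self plots (\code{a} = \code{b}) are symmetric.
#'
#' @param a,b \code{\link{bio_seq}} objects with matching alphabets.
#' @param cfg A \code{\link{dotplot_config}}.
#' @return An object of class \code{dot_matrix} with the score matrix in
#'   \code{values} (rows index windows of \code{a}).
#' @export
compute_dot_matrix <- function(a, b, cfg = dotplot_config()) {
  stopifnot(inherits(a, "bio_seq"), inherits(b, "bio_seq"),
            inherits(cfg, "dotplot_config"))
  if (a$alphabet != b$alphabet) stop_plastex("alphabet mismatch")
  w <- cfg$window
  na <- nchar(a$residues); nb <- nchar(b$residues)
  if (w > min(na, nb)) stop_plastex("window larger than a sequence")
  xa <- split_chars(a$residues); xb <- split_chars(b$residues)
  if (a$alphabet == "DNA") {
    ambig <- xa == "N"
    score_pair <- function(ia, ib) {
      m <- (xa[ia] == xb[ib]) & xa[ia] != "N"
      ifelse(m, cfg$match_score, cfg$mismatch_score)
    }
  } else {
    subst <- blosum62_matrix()
    fa <- match(xa, rownames(subst)); fb <- match(xb, rownames(subst))
    fa[is.na(fa)] <- which(rownames(subst) == "X")
    fb[is.na(fb)] <- which(rownames(subst) == "X")
    score_pair <- function(ia, ib) subst[cbind(fa[ia], fb[ib])]
  }
  nr <- na - w + 1L; nc <- nb - w + 1L
  values <- matrix(NA_real_, nr, nc)
  # fill by diagonal: positions (i, i + d); window sums via cumsum
  for (d in (-(na - 1L)):(nb - 1L)) {
    ia <- max(1L, 1L - d):min(na, nb - d)
    if (length(ia) < w) next
    ib <- ia + d
    s <- score_pair(ia, ib)
    cs <- cumsum(s)
    wins <- cs[w:length(s)] - c(0, cs)[seq_len(length(s) - w + 1L)]
    ri <- ia[seq_along(wins)]
    ci <- ib[seq_along(wins)]
    keep <- ri <= nr & ci <= nc
    values[cbind(ri[keep], ci[keep])] <- wins[keep]
  }
  structure(list(seqA_id = a$id, seqB_id = b$id, values = values,
                 config = cfg, alphabet = a$alphabet,
                 a = a$residues, b = b$residues),
            class = "dot_matrix")
}

#' @export
print.dot_matrix <- function(x, ...) {
  cat(sprintf("<dot_matrix> %s (%d) x %s (%d), window %d\n", x$seqA_id,
              nrow(x$values), x$seqB_id, ncol(x$values), x$config$window))
  invisible(x)
}

#' Detect diagonal similarity runs in a dot matrix
#'
#' Forward runs are maximal stretches of consecutive cells along a diagonal
#' whose window score meets \code{min_mean_score}; a run must span at least
#' \code{min_len} residues (cells + window - 1). Reverse (anti-diagonal)
#' runs on DNA are found by computing the matrix of \code{a} against the
#' reverse complement of \code{b} internally and mapping coordinates back;
#' requesting reverse detection on proteins is a configuration error
#' (reverse-complement similarity has no meaning for proteins). Runs are
#' sorted by mean score, descending.
#'
#' @param m A \code{dot_matrix}.
#' @param min_len Minimum residue span (default 2x window).
#' @param min_mean_score Minimum per-window score (default 60\% of the
#'   window maximum for DNA; 60\% of window times the matrix diagonal mean
#'   for proteins).
#' @param orientation \code{"forward"}, \code{"reverse"}, or \code{"both"}.
#' @return Data frame of runs: \code{orientation}, \code{start_A},
#'   \code{start_B} (0-based window starts), \code{length} (residues),
#'   \code{mean_score}, \code{offset} (\code{start_B - start_A} forward,
#'   \code{start_B + start_A} reverse).
#' @export
detect_diagonals <- function(m, min_len = NULL, min_mean_score = NULL,
                             orientation = c("both", "forward", "reverse")) {
  stopifnot(inherits(m, "dot_matrix"))
  orientation <- match.arg(orientation)
  w <- m$config$window
  if (is.null(min_len)) min_len <- 2L * w
  if (is.null(min_mean_score)) {
    per_pos <- if (m$alphabet == "DNA") m$config$match_score else {
      subst <- blosum62_matrix()
      mean(diag(subst[AA_CHARS, AA_CHARS]))
    }
    min_mean_score <- 0.6 * w * per_pos
  }
  runs_forward <- function(values) {
    nr <- nrow(values); nc <- ncol(values)
    out <- list()
    for (d in (-(nr - 1L)):(nc - 1L)) {
      ia <- max(1L, 1L - d):min(nr, nc - d)
      if (!length(ia)) next
      v <- values[cbind(ia, ia + d)]
      ok <- !is.na(v) & v >= min_mean_score
      r <- rle(ok)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        span <- r$lengths[k] + w - 1L
        if (span < min_len) next
        idx <- starts[k]:ends[k]
        out[[length(out) + 1L]] <- data.frame(
          start_A = ia[starts[k]] - 1L, start_B = ia[starts[k]] + d - 1L,
          length = span, mean_score = mean(v[idx]))
      }
    }
    if (!length(out)) {
      return(data.frame(start_A = integer(0), start_B = integer(0),
                        length = integer(0), mean_score = numeric(0)))
    }
    do.call(rbind, out)
  }
  res <- list()
  if (orientation %in% c("both", "forward")) {
    fw <- runs_forward(m$values)
    if (nrow(fw)) {
      fw$orientation <- "forward"
      fw$offset <- fw$start_B - fw$start_A
      res[[length(res) + 1L]] <- fw
    }
  }
  if (orientation %in% c("both", "reverse")) {
    if (m$alphabet != "DNA") {
      if (orientation == "reverse") {
        stop_plastex("reverse-complement detection is DNA-only")
      }
    } else {
      b_rc <- reverse_complement(bio_seq(m$b, id = m$seqB_id))
      m_rc <- compute_dot_matrix(bio_seq(m$a, id = m$seqA_id), b_rc, m$config)
      rv <- runs_forward(m_rc$values)
      if (nrow(rv)) {
        nb <- nchar(m$b)
        # window [s, s+w) in revcomp(b) covers original b window
        # [nb - s - span, nb - s) for the whole run; report the original-b
        # start of the run's first window.
        rv$start_B <- nb - rv$start_B - rv$length
        rv$orientation <- "reverse"
        rv$offset <- rv$start_B + rv$start_A
        res[[length(res) + 1L]] <- rv
      }
    }
  }
  if (!length(res)) {
    return(data.frame(orientation = character(0), start_A = integer(0),
                      start_B = integer(0), length = integer(0),
                      mean_score = numeric(0), offset = integer(0)))
  }
  out <- do.call(rbind, res)
  out <- out[order(-out$mean_score), c("orientation", "start_A", "start_B",
                                       "length", "mean_score", "offset")]
  rownames(out) <- NULL
  out
}

#' Render a dot matrix to a grey or colored image grid
#'
#' Scores at or below \code{greymap_top} map to the black end (0), scores
#' at or above \code{greymap_bottom} to the white end (1), linear in
#' between, so increasing a cell score never darkens its pixel. When a
#' color scale is set (default white-yellow-orange-red-black, white =
#' highest similarity), the grey level selects a color along that
#' continuum.
#'
#' @param m A \code{dot_matrix}.
#' @param color Apply the 5-color continuum instead of grey.
#' @return Matrix of hex colors (class \code{dot_image}), same shape as the
#'   score matrix; draw it with \code{\link{plot.dot_image}} or write it
#'   with \code{\link{write_dotplot_png}}.
#' @export
render <- function(m, color = FALSE) {
  stopifnot(inherits(m, "dot_matrix"))
  top <- m$config$greymap_top; bottom <- m$config$greymap_bottom
  g <- (m$values - top) / (bottom - top)
  g[g < 0] <- 0; g[g > 1] <- 1
  g[is.na(g)] <- 0
  if (color) {
    pal <- m$config$color_scale
    if (is.null(pal)) pal <- c("black", "red", "orange", "yellow", "white")
    ramp <- grDevices::colorRamp(pal)
    cols <- grDevices::rgb(ramp(as.vector(g)), maxColorValue = 255)
  } else {
    cols <- grDevices::gray(as.vector(g))
  }
  structure(matrix(cols, nrow(g), ncol(g)), class = "dot_image",
            seqA_id = m$seqA_id, seqB_id = m$seqB_id)
}

#' @export
plot.dot_image <- function(x, ...) {
  op <- graphics::par(mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(0, ncol(x)), ylim = c(nrow(x), 0),
                 xlab = "", ylab = "", asp = 1,
                 main = paste(attr(x, "seqA_id"), "vs", attr(x, "seqB_id")),
                 ...)
  graphics::rasterImage(grDevices::as.raster(unclass(x)), 0, nrow(x),
                        ncol(x), 0, interpolate = FALSE)
  invisible(x)
}

#' Write a rendered dot plot as PNG
#'
#' @param m A \code{dot_matrix}.
#' @param path Output PNG path.
#' @param color Use the color continuum.
#' @return Invisibly, \code{path}.
#' @export
write_dotplot_png <- function(m, path, color = FALSE) {
  img <- render(m, color = color)
  grDevices::png(path, width = max(ncol(img), 64L), height = max(nrow(img), 64L))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(unclass(img)), 0, 0, 1, 1,
                        interpolate = FALSE)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}

#' Export a dot matrix as TSV
#'
#' @param m A \code{dot_matrix}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_dot_matrix_tsv <- function(m, path) {
  write.table(m$values, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
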