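#' Construct a multiple alignment object
#'
#' @param rows Character vector of equal-length gapped sequences.
#' @param ids Sequence identifiers (defaults to names of \code{rows}).
#' @param alphabet \code{"PROTEIN"} or \code{"DNA"}.
#' @return Object of class \code{multiple_alignment}.
#' @export
multiple_alignment <- function(rows, ids = names(rows),
                               alphabet = "PROTEIN") {
  stopifnot(length(rows) >= 2L)
  if (length(unique(nchar(rows))) != 1L) {
    stop_plastex("alignment rows differ in length")
  }
  if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
  structure(list(ids = ids, rows = unname(rows), alphabet = alphabet),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<multiple_alignment> %d sequence(s), %d column(s) (%s)\n",
              length(x$rows), nchar(x$rows[1]), x$alphabet))
  invisible(x)
}

aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows, ""))
  rownames(m) <- aln$ids
  m
}

# substitution matrix + gap parameters per alphabet, shared by the
# progressive aligner
msa_params <- function(alphabet) {
  if (alphabet == "PROTEIN") {
    list(subst = blosum62_matrix(), gap_open = 10, gap_ext = 0.5)
  } else {
    chars <- c(DNA_CHARS[1:4], "N")
    s <- matrix(-4, 5, 5, dimnames = list(chars, chars))
    diag(s) <- 5
    s["N", ] <- 0; s[, "N"] <- 0
    list(subst = s, gap_open = 10, gap_ext = 1)
  }
}

# residue frequency matrix (alphabet x columns) of a block of gapped rows
profile_freqs <- function(rows, chars) {
  m <- do.call(rbind, strsplit(rows, ""))
  n <- nrow(m)
  vapply(seq_len(ncol(m)), function(j) {
    tab <- table(factor(m[, j], levels = chars))
    as.numeric(tab) / n
  }, numeric(length(chars)))
}

# merge two aligned blocks with a profile-profile global alignment
merge_blocks <- function(rows_a, rows_b, prm) {
  chars <- rownames(prm$subst)
  fa <- profile_freqs(rows_a, chars)
  fb <- profile_freqs(rows_b, chars)
  if (is.null(dim(fa))) fa <- matrix(fa, ncol = 1)
  if (is.null(dim(fb))) fb <- matrix(fb, ncol = 1)
  cell <- t(fa) %*% prm$subst %*% fb
  al <- .profile_global_align(cell, prm$gap_open, prm$gap_ext)
  expand <- function(rows, path) {
    m <- do.call(rbind, strsplit(rows, ""))
    out <- matrix("-", nrow(m), length(path))
    nz <- path != 0L
    out[, nz] <- m[, path[nz], drop = FALSE]
    apply(out, 1, paste, collapse = "")
  }
  c(expand(rows_a, al$path_a), expand(rows_b, al$path_b))
}

#' Progressive multiple sequence alignment
#'
#' The classic progressive scheme: all pairwise global alignments give a
#' p-distance matrix, a neighbor-joining guide tree orders the merges, and
#' profile-profile alignments (affine gaps; BLOSUM62 for protein, +5/-4
#' for DNA) assemble the final alignment. Deterministic given the input;
#' no randomness is involved.
#'
#' @param seqs List of \code{\link{bio_seq}}s (>= 2, one alphabet).
#' @return A \code{\link{multiple_alignment}} whose rows, once ungapped,
#'   reproduce the inputs.
#' @export
progressive_msa <- function(seqs) {
  stopifnot(length(seqs) >= 2L)
  alphabet <- unique(vapply(seqs, `[[`, "", "alphabet"))
  if (length(alphabet) != 1L) stop_plastex("mixed alphabets")
  ids <- vapply(seqs, `[[`, "", "id")
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  prm <- msa_params(alphabet)
  n <- length(seqs)
  if (n == 2L) {
    rows <- merge_blocks(seqs[[1]]$residues, seqs[[2]]$residues, prm)
    return(multiple_alignment(rows, ids, alphabet))
  }
  # pairwise p-distances from global alignments
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      rows <- merge_blocks(seqs[[i]]$residues, seqs[[j]]$residues, prm)
      a <- split_chars(rows[1]); b <- split_chars(rows[2])
      use <- a != "-" & b != "-"
      d[i, j] <- d[j, i] <- if (any(use)) mean(a[use] != b[use]) else 1
    }
  }
  guide <- ape::nj(stats::as.dist(d))
  guide <- ape::root(guide, outgroup = guide$tip.label[1],
                     resolve.root = TRUE)
  # post-order merge following the guide tree
  merge_node <- function(node) {
    if (node <= n) {
      i <- match(guide$tip.label[node], ids)
      return(list(rows = seqs[[i]]$residues, ids = ids[i]))
    }
    children <- guide$edge[guide$edge[, 1] == node, 2]
    blocks <- lapply(children, merge_node)
    acc <- blocks[[1]]
    for (k in seq_along(blocks)[-1]) {
      rows <- merge_blocks(acc$rows, blocks[[k]]$rows, prm)
      acc <- list(rows = rows, ids = c(acc$ids, blocks[[k]]$ids))
    }
    acc
  }
  root <- n + 1L
  res <- merge_node(root)
  ord <- match(ids, res$ids)
  multiple_alignment(res$rows[ord], ids, alphabet)
}

#' p-distance matrix from a multiple alignment
#'
#' With complete deletion (the default, matching tree construction with
#' gapped positions excluded) every column containing a gap in any row is
#' removed before distances are computed; with pairwise deletion each pair
#' uses the columns where both rows are ungapped.
#'
#' @param aln A \code{\link{multiple_alignment}}.
#' @param deletion \code{"complete"} or \code{"pairwise"}.
#' @return Symmetric matrix of p-distances (zero diagonal, entries in
#'   [0, 1]).
#' @export
pdistance_matrix <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  stopifnot(inherits(aln, "multiple_alignment"))
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop_plastex("need >= 2 rows")
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  if (deletion == "complete") {
    keep <- colSums(m == "-") == 0L
    if (!any(keep)) stop_plastex("no ungapped columns for distances")
    mm <- m[, keep, drop = FALSE]
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- mean(mm[i, ] != mm[j, ])
      }
    }
  } else {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        use <- m[i, ] != "-" & m[j, ] != "-"
        if (!any(use)) {
          stop_plastex("no usable columns for pair ", aln$ids[i], "/",
                       aln$ids[j])
        }
        d[i, j] <- d[j, i] <- mean(m[i, use] != m[j, use])
      }
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration (via \pkg{ape}); additive matrices
#' are recovered exactly. Negative branch-length estimates, which NJ can
#' produce, are clamped to zero with a warning and flagged in the
#' \code{n_clamped} attribute; zero-length internal edges are collapsed,
#' so an all-zero matrix yields a star tree.
#'
#' @param d Symmetric distance matrix (>= 3 taxa) or \code{dist}.
#' @return An \pkg{ape} \code{phylo} tree (unrooted).
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3L) stop_plastex("neighbor joining needs >= 3 taxa")
  tree <- ape::nj(stats::as.dist(d))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    warning(sum(neg), " negative NJ branch length(s) clamped to 0",
            call. = FALSE)
    tree$edge.length[neg] <- 0
  }
  tree <- ape::di2multi(tree, tol = 1e-12)
  attr(tree, "n_clamped") <- sum(neg)
  tree
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Columns are resampled with replacement \code{n_replicates} times; the
#' support of each internal edge of the point-estimate tree is the
#' percentage of replicate trees containing the same bipartition. The
#' resampling depends only on the seed and the column count, so supports
#' are invariant to taxon input order.
#'
#' @param aln A \code{\link{multiple_alignment}}.
#' @param n_replicates Number of bootstrap replicates (1000 is the
#'   conventional choice; tests use fewer).
#' @param seed RNG seed (recorded on the result).
#' @param deletion Passed to \code{\link{pdistance_matrix}}.
#' @return The point-estimate \code{phylo} tree with \code{node.label}
#'   set to supports (percent; root label empty) and attributes
#'   \code{support}, \code{seed}, \code{n_replicates}.
#' @export
bootstrap_support <- function(aln, n_replicates = 1000L, seed = 1L,
                              deletion = "complete") {
  stopifnot(n_replicates >= 1L)
  m <- aln_matrix(aln)
  nc <- ncol(m)
  usable <- sum(colSums(m == "-") == 0L)
  if (usable < 2L) stop_plastex("fewer than 2 usable columns")
  point <- nj_tree(pdistance_matrix(aln, deletion))
  boot <- with_seed(seed, lapply(seq_len(n_replicates), function(r) {
    idx <- sample.int(nc, nc, replace = TRUE)
    rep_aln <- multiple_alignment(apply(m[, idx, drop = FALSE], 1, paste,
                                        collapse = ""),
                                  ids = aln$ids, alphabet = aln$alphabet)
    tryCatch(nj_tree(pdistance_matrix(rep_aln, deletion)),
             error = function(e) NULL)
  }))
  boot <- Filter(Negate(is.null), boot)
  counts <- suppressWarnings(
    ape::prop.clades(point, boot, rooted = FALSE))
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_replicates)
  point$node.label <- as.character(support)
  attr(point, "support") <- support
  attr(point, "seed") <- seed
  attr(point, "n_replicates") <- n_replicates
  point
}

subset_alignment <- function(aln, columns) {
  m <- aln_matrix(aln)
  multiple_alignment(apply(m[, columns, drop = FALSE], 1, paste,
                           collapse = ""),
                     ids = aln$ids, alphabet = aln$alphabet)
}

#' Region-wise branch-length comparison
#'
#' Builds one NJ tree per disjoint column region (complete-deletion
#' p-distances), and reports per-leaf terminal branch lengths and
#' midpoint-rooted root-to-tip distances with their B:A ratios, plus the
#' Robinson-Foulds distance between the two topologies. This is the
#' instrument for contrasting a conserved region with a fast-evolving one:
#' equal rates give ratios near 1, a region evolving k times faster gives
#' terminal-branch ratios near k.
#'
#' @param aln A \code{\link{multiple_alignment}}.
#' @param region_A_columns,region_B_columns Disjoint column index vectors.
#' @return List with \code{tree_A}, \code{tree_B}, \code{leaf_stats}
#'   (data frame: id, terminal_A, terminal_B, terminal_ratio, rtt_A,
#'   rtt_B, rtt_ratio), and \code{rf_distance}.
#' @export
region_branch_compare <- function(aln, region_A_columns, region_B_columns) {
  if (length(intersect(region_A_columns, region_B_columns))) {
    stop_plastex("regions must be disjoint")
  }
  aln_a <- subset_alignment(aln, region_A_columns)
  aln_b <- subset_alignment(aln, region_B_columns)
  tree_a <- nj_tree(pdistance_matrix(aln_a))
  tree_b <- nj_tree(pdistance_matrix(aln_b))
  term_len <- function(tree) {
    idx <- match(seq_along(tree$tip.label), tree$edge[, 2])
    setNames(tree$edge.length[idx], tree$tip.label)
  }
  rtt <- function(tree) {
    rooted <- phangorn::midpoint(tree)
    depths <- ape::node.depth.edgelength(rooted)
    setNames(depths[seq_along(rooted$tip.label)], rooted$tip.label)
  }
  ta <- term_len(tree_a)[aln$ids]; tb <- term_len(tree_b)[aln$ids]
  ra <- rtt(tree_a)[aln$ids]; rb <- rtt(tree_b)[aln$ids]
  leaf_stats <- data.frame(
    id = aln$ids, terminal_A = ta, terminal_B = tb,
    terminal_ratio = tb / ta, rtt_A = ra, rtt_B = rb, rtt_ratio = rb / ra,
    row.names = NULL)
  rf <- tryCatch(phangorn::RF.dist(tree_a, tree_b), error = function(e) NA)
  list(tree_A = tree_a, tree_B = tree_b, leaf_stats = leaf_stats,
       rf_distance = rf)
}

#' Count gapped columns in a range of an alignment
#'
#' @param aln A \code{\link{multiple_alignment}}.
#' @param column_range Integer vector of columns (default all).
#' @return Number of columns in the range containing at least one gap.
#' @export
count_gapped_columns <- function(aln, column_range = NULL) {
  m <- aln_matrix(aln)
  if (is.null(column_range)) column_range <- seq_len(ncol(m))
  if (any(column_range < 1L | column_range > ncol(m))) {
    stop_plastex("column range outside alignment")
  }
  sum(colSums(m[, column_range, drop = FALSE] == "-") > 0L)
}

#' Write a multiple alignment as aligned FASTA
#'
#' @param aln A \code{\link{multiple_alignment}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_alignment_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$rows)) {
    writeLines(c(paste0(">", aln$ids[i]), aln$rows[i]), con)
  }
  invisible(path)
}

#' Read an aligned FASTA file as a multiple alignment
#'
#' @param path File path.
#' @param alphabet \code{"PROTEIN"} or \code{"DNA"}.
#' @return A \code{\link{multiple_alignment}}.
#' @export
read_alignment_fasta <- function(path, alphabet = "PROTEIN") {
  set <- Biostrings::readBStringSet(path)
  multiple_alignment(as.character(set), ids = sub("\\s.*$", "", names(set)),
                     alphabet = alphabet)
}

#' Write a tree as Newick with supports as internal node labels
#'
#' @param tree An \pkg{ape} \code{phylo}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
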