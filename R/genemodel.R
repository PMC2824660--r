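#' Construct an exon model
#'
#' Genomic coordinates are 0-based half-open throughout the package;
#' conversion to 1-based inclusive happens only at the GFF3 boundary.
#' Splice flanks (\code{donor}, \code{acceptor}) are the first/last two
#' intronic bases adjacent to the exon, read on the coding strand, so the
#' canonical GT-AG rule reads identically for both strands.
#'
#' @param start,end 0-based half-open genomic coordinates.
#' @param strand \code{"+"} or \code{"-"}.
#' @param phase Reading-frame phase at the exon start (0, 1, or 2).
#' @param donor,acceptor Two-letter intronic flank dinucleotides on the
#'   coding strand; empty for the last/first exon respectively.
#' @param label Free-text exon label (e.g. \code{"17"}, \code{"18=19"},
#'   \code{"21V22"}, \code{"19A"}).
#' @return An object of class \code{exon_model}.
#' @export
exon_model <- function(start, end, strand = "+", phase = 0L,
                       donor = "", acceptor = "", label = "") {
  start <- as.integer(start); end <- as.integer(end)
  if (!(start >= 0L && start < end)) {
    stop_plastex("exon '", label, "': need 0 <= start < end")
  }
  if (end - start < 3L) stop_plastex("exon '", label, "': length must be >= 3")
  stopifnot(strand %in% c("+", "-"), phase %in% 0:2)
  structure(list(start = start, end = end, strand = strand,
                 phase = as.integer(phase), donor = toupper(donor),
                 acceptor = toupper(acceptor), label = as.character(label)),
            class = "exon_model")
}

exon_length <- function(e) e$end - e$start

#' Construct a gene model
#'
#' An ordered list of exons (5' to 3' in transcript order) on one contig and
#' strand. Exons must be non-overlapping and ordered along the genome
#' consistently with the strand; when \code{coding_complete} the summed exon
#' length must be divisible by 3.
#'
#' @param contig_id Contig/scaffold name.
#' @param exons List of \code{\link{exon_model}}, transcript order.
#' @param strand \code{"+"} or \code{"-"}.
#' @param coding_complete Flag the model as a complete coding sequence.
#' @param contig_length Optional contig length for bounds checking.
#' @param validate Check flank-presence invariants for internal exons.
#' @return An object of class \code{gene_model}.
#' @export
gene_model <- function(contig_id, exons, strand = "+",
                       coding_complete = FALSE, contig_length = NULL,
                       validate = TRUE) {
  stopifnot(length(exons) >= 1L, strand %in% c("+", "-"))
  starts <- vapply(exons, `[[`, integer(1), "start")
  ends <- vapply(exons, `[[`, integer(1), "end")
  ord_ok <- if (strand == "+") all(diff(starts) > 0) else all(diff(starts) < 0)
  if (length(exons) > 1L) {
    if (!ord_ok) stop_plastex("exons not in transcript order for strand ", strand)
    gen_ord <- order(starts)
    s <- starts[gen_ord]; e <- ends[gen_ord]
    if (any(s[-1] < e[-length(e)])) stop_plastex("exons overlap")
  }
  if (!is.null(contig_length) && max(ends) > contig_length) {
    stop_plastex("exon coordinates exceed contig length ", contig_length)
  }
  total <- sum(ends - starts)
  if (coding_complete && total %% 3L != 0L) {
    stop_plastex("coding-complete model has total exon length ", total,
                 ", not divisible by 3")
  }
  if (validate && length(exons) > 1L) {
    n <- length(exons)
    donors <- vapply(exons, `[[`, character(1), "donor")
    accs <- vapply(exons, `[[`, character(1), "acceptor")
    if (any(!nzchar(donors[-n]))) stop_plastex("internal exon missing donor flank")
    if (any(!nzchar(accs[-1]))) stop_plastex("internal exon missing acceptor flank")
  }
  structure(list(contig_id = contig_id, exons = exons, strand = strand,
                 coding_complete = coding_complete,
                 contig_length = contig_length),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s strand %s, %d exon(s)%s\n", x$contig_id,
              x$strand, length(x$exons),
              if (x$coding_complete) ", coding-complete" else ""))
  for (e in x$exons) {
    cat(sprintf("  exon %-6s [%d, %d) phase %d  %s..%s\n", e$label, e$start,
                e$end, e$phase,
                if (nzchar(e$acceptor)) e$acceptor else "--",
                if (nzchar(e$donor)) e$donor else "--"))
  }
  invisible(x)
}

# Intronic flank dinucleotides of exon [start, end) on the coding strand.
# For the minus strand this is computed via the reverse-complement identity
# so the GT-AG rule is strand-agnostic by construction.
exon_flanks <- function(genomic, start, end, strand = "+") {
  res <- genomic$residues
  n <- nchar(res)
  if (strand == "-") {
    rc <- reverse_complement(genomic)
    return(exon_flanks(rc, n - end, n - start, "+"))
  }
  donor <- if (end + 2L <= n) substr(res, end + 1L, end + 2L) else ""
  acceptor <- if (start >= 2L) substr(res, start - 1L, start) else ""
  list(donor = donor, acceptor = acceptor)
}

# Spliced transcript sequence (coding strand) of a gene model.
splice_transcript <- function(model, genomic) {
  res <- if (model$strand == "+") genomic$residues
         else reverse_complement(genomic)$residues
  n <- nchar(genomic$residues)
  parts <- vapply(model$exons, function(e) {
    if (model$strand == "+") substr(res, e$start + 1L, e$end)
    else substr(res, n - e$end + 1L, n - e$start)
  }, character(1))
  bio_seq(paste(parts, collapse = ""), id = paste0(model$contig_id, "_mRNA"),
          alphabet = "DNA")
}

#' Write a gene model as GFF3 or BED12
#'
#' GFF3 uses 1-based inclusive coordinates (one \code{gene} row and one
#' \code{CDS} row per exon, labels and splice flanks carried in attributes);
#' BED12 uses 0-based half-open coordinates with one line per gene and exon
#' labels joined into the name field.
#'
#' @param model A \code{\link{gene_model}}.
#' @param path Output path.
#' @param format \code{"gff3"} or \code{"bed12"}.
#' @return Invisibly, \code{path}.
#' @export
write_annotations <- function(model, path, format = c("gff3", "bed12")) {
  format <- match.arg(format)
  exons <- model$exons
  starts <- vapply(exons, `[[`, integer(1), "start")
  ends <- vapply(exons, `[[`, integer(1), "end")
  if (!is.null(model$contig_length) && max(ends) > model$contig_length) {
    stop_plastex("exon coordinates exceed contig length")
  }
  gid <- paste0(model$contig_id, ".gene")
  if (format == "gff3") {
    lines <- c("##gff-version 3",
               paste(model$contig_id, "plastex", "gene", min(starts) + 1L,
                     max(ends), ".", model$strand, ".",
                     paste0("ID=", gid), sep = "\t"))
    for (i in seq_along(exons)) {
      e <- exons[[i]]
      attrs <- sprintf("ID=%s.cds%d;Parent=%s;exon_label=%s;donor=%s;acceptor=%s",
                       gid, i, gid, e$label, e$donor, e$acceptor)
      lines <- c(lines, paste(model$contig_id, "plastex", "CDS", e$start + 1L,
                              e$end, ".", e$strand, e$phase, attrs, sep = "\t"))
    }
    writeLines(lines, path)
  } else {
    gen_ord <- order(starts)
    block_sizes <- (ends - starts)[gen_ord]
    block_starts <- starts[gen_ord] - min(starts)
    labels <- vapply(exons, `[[`, character(1), "label")[gen_ord]
    name <- paste0(gid, "|", paste(labels, collapse = ","))
    line <- paste(model$contig_id, min(starts), max(ends), name, 0L,
                  model$strand, min(starts), max(ends), "0", length(exons),
                  paste0(paste(block_sizes, collapse = ","), ","),
                  paste0(paste(block_starts, collapse = ","), ","), sep = "\t")
    writeLines(line, path)
  }
  invisible(path)
}

#' Read a gene model back from GFF3
#'
#' Counterpart of \code{\link{write_annotations}}: reads the \code{CDS} rows
#' via \pkg{rtracklayer} and reconstitutes the \code{\link{gene_model}},
#' recovering transcript order from the strand.
#'
#' @param path GFF3 file path.
#' @param coding_complete Passed through to \code{\link{gene_model}}.
#' @return A \code{\link{gene_model}}.
#' @export
read_gff3 <- function(path, coding_complete = FALSE) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0L) stop_plastex("no CDS rows in ", path)
  strand <- as.character(BiocGenerics::strand(cds))[1]
  starts <- BiocGenerics::start(cds) - 1L
  ends <- BiocGenerics::end(cds)
  phase <- as.integer(as.character(cds$phase))
  if (all(is.na(phase))) phase <- rep(0L, length(cds))
  meta <- as.data.frame(S4Vectors::mcols(cds))
  get_col <- function(nm) if (nm %in% names(meta)) as.character(meta[[nm]]) else
    rep("", length(cds))
  labels <- get_col("exon_label"); donors <- get_col("donor")
  accs <- get_col("acceptor")
  donors[is.na(donors)] <- ""; accs[is.na(accs)] <- ""; labels[is.na(labels)] <- ""
  ord <- if (strand == "+") order(starts) else order(-starts)
  exons <- lapply(ord, function(i) {
    exon_model(starts[i], ends[i], strand, phase[i], donors[i], accs[i],
               labels[i])
  })
  gene_model(as.character(GenomeInfoDb::seqnames(cds))[1], exons, strand,
             coding_complete = coding_complete, validate = FALSE)
}
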