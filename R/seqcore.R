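#' Construct a biological sequence
#'
#' The basic sequence container used throughout the package: a named DNA or
#' protein sequence with an explicit alphabet tag. Residues are uppercased
#' and validated against the IUPAC character set for the alphabet (DNA:
#' \code{ACGTN}; protein: the 20 standard amino acids plus \code{X} and the
#' stop symbol \code{*}). Ambiguity characters (\code{N}, \code{X}) score as
#' mismatch/zero in every downstream computation.
#'
#' @param residues Character scalar, the sequence.
#' @param id Sequence identifier.
#' @param alphabet \code{"DNA"}, \code{"PROTEIN"}, or \code{NULL} to
#'   auto-detect (>= 90\% \code{ACGTN} characters is called DNA).
#' @param description Free-text description (FASTA header remainder).
#' @return An object of class \code{bio_seq}.
#' @export
#' @examples
#' bio_seq("ACGT", id = "x")
#' bio_seq("PSITKVTRVIEGE", id = "consensus")
bio_seq <- function(residues, id = "seq", alphabet = NULL, description = "") {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) < 1L) stop_plastex("sequence '", id, "' is empty")
  if (is.null(alphabet)) alphabet <- detect_alphabet(residues)
  alphabet <- match.arg(alphabet, c("DNA", "PROTEIN"))
  chars <- unique(split_chars(residues))
  allowed <- if (alphabet == "DNA") DNA_CHARS else AA_CHARS_EXT
  bad <- setdiff(chars, allowed)
  if (length(bad)) {
    stop_plastex("sequence '", id, "': invalid ", alphabet, " character(s): ",
                 paste(bad, collapse = ", "))
  }
  structure(list(id = id, alphabet = alphabet, residues = residues,
                 description = description),
            class = "bio_seq")
}

#' @export
print.bio_seq <- function(x, ...) {
  res <- x$residues
  shown <- if (nchar(res) > 60) paste0(substr(res, 1, 57), "...") else res
  cat(sprintf("<bio_seq %s> %s (%d %s)\n  %s\n", x$alphabet, x$id,
              nchar(res), if (x$alphabet == "DNA") "nt" else "aa", shown))
  invisible(x)
}

#' @export
as.character.bio_seq <- function(x, ...) x$residues

#' @export
length.bio_seq <- function(x) nchar(x$residues)

#' Guess the alphabet of a raw sequence string
#'
#' @param residues Character scalar.
#' @return \code{"DNA"} if at least 90\% of characters are \code{ACGTN},
#'   otherwise \code{"PROTEIN"}.
#' @export
detect_alphabet <- function(residues) {
  chars <- split_chars(toupper(residues))
  if (mean(chars %in% DNA_CHARS) >= 0.9) "DNA" else "PROTEIN"
}

#' Read a multi-record FASTA file
#'
#' Thin wrapper around \code{Biostrings} FASTA input that returns package
#' \code{\link{bio_seq}} objects with per-record alphabet auto-detection.
#' A light structural pre-scan reports malformed headers and empty records
#' with their line numbers.
#'
#' @param path File path.
#' @param alphabet Optional fixed alphabet for all records; default
#'   auto-detect per record.
#' @return List of \code{bio_seq}.
#' @export
read_fasta <- function(path, alphabet = NULL) {
  if (!file.exists(path)) stop_plastex("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  in_record <- FALSE
  have_residues <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^>", ln)) {
      if (in_record && !have_residues) {
        stop_plastex("FASTA parse error at line ", i - 1L, ": empty record")
      }
      if (nchar(trimws(sub("^>", "", ln))) == 0L) {
        stop_plastex("FASTA parse error at line ", i, ": malformed header")
      }
      in_record <- TRUE
      have_residues <- FALSE
    } else if (nchar(trimws(ln)) > 0L) {
      if (!in_record) {
        stop_plastex("FASTA parse error at line ", i,
                     ": sequence data before first header")
      }
      have_residues <- TRUE
    }
  }
  if (!in_record) stop_plastex("FASTA parse error: no records in ", path)
  if (!have_residues) {
    stop_plastex("FASTA parse error at line ", length(lines), ": empty record")
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  lapply(seq_along(set), function(i) {
    bio_seq(as.character(set[[i]]), id = ids[[i]], alphabet = alphabet,
            description = descs[[i]])
  })
}

#' Write sequences to FASTA
#'
#' @param seqs A \code{bio_seq} or list of them.
#' @param path Output path.
#' @param width Line wrap width (default 60).
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "bio_seq")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    hdr <- if (nzchar(s$description)) paste(s$id, s$description) else s$id
    writeLines(paste0(">", hdr), con)
    n <- nchar(s$residues)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s$residues, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Reverse complement of a DNA sequence
#'
#' @param seq A DNA \code{bio_seq}.
#' @return The reverse-complemented \code{bio_seq} (\code{N} maps to
#'   \code{N}).
#' @export
#' @examples
#' as.character(reverse_complement(bio_seq("AAACCC")))  # "GGGTTT"
reverse_complement <- function(seq) {
  stopifnot(inherits(seq, "bio_seq"))
  if (seq$alphabet != "DNA") {
    stop_plastex("reverse_complement requires a DNA sequence")
  }
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq$residues)))
  bio_seq(rc, id = seq$id, alphabet = "DNA", description = seq$description)
}

#' Translate DNA in a given frame
#'
#' Standard genetic code; the trailing partial codon is dropped and stop
#' codons are retained as \code{*} in the output. Codons containing \code{N}
#' translate to \code{X} unless the ambiguity is synonymous-resolvable.
#'
#' @param seq A DNA \code{bio_seq}.
#' @param frame Frame offset 0, 1, or 2.
#' @return A protein \code{bio_seq}.
#' @export
#' @examples
#' as.character(translate_dna(bio_seq("ATGAAA")))  # "MK"
translate_dna <- function(seq, frame = 0L) {
  stopifnot(inherits(seq, "bio_seq"))
  if (seq$alphabet != "DNA") stop_plastex("translate_dna requires DNA input")
  stopifnot(frame %in% 0:2)
  n <- nchar(seq$residues)
  usable <- n - frame
  n_codons <- usable %/% 3L
  if (n_codons < 1L) {
    stop_plastex("sequence too short to translate in frame ", frame)
  }
  sub <- substr(seq$residues, frame + 1L, frame + 3L * n_codons)
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(sub), if.fuzzy.codon = "solve")))
  bio_seq(aa, id = paste0(seq$id, "_frame", frame), alphabet = "PROTEIN",
          description = seq$description)
}

#' Translate all six reading frames
#'
#' @param seq A DNA \code{bio_seq}.
#' @return A list of six protein \code{bio_seq}s named \code{+0,+1,+2,-0,-1,-2};
#'   minus frames are translations of the reverse complement.
#' @export
translate_six_frames <- function(seq) {
  rc <- reverse_complement(seq)
  out <- c(lapply(0:2, function(f) translate_dna(seq, f)),
           lapply(0:2, function(f) translate_dna(rc, f)))
  names(out) <- c("+0", "+1", "+2", "-0", "-1", "-2")
  out
}
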