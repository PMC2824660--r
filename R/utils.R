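#' @useDynLib plastex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rbinom rpois runif setNames sd cophenetic
#' @importFrom utils head tail write.table read.table
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

DNA_CHARS <- c("A", "C", "G", "T", "N")
AA_CHARS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_CHARS_EXT <- c(AA_CHARS, "X", "*")

# Average residue composition of a large protein database (UniProt-style),
# used as the default profile background. Renormalized over the 20 residues.
UNIPROT_BG <- c(
  A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137,
  Q = 0.0393, E = 0.0674, G = 0.0708, H = 0.0227, I = 0.0593,
  L = 0.0965, K = 0.0582, M = 0.0241, F = 0.0386, P = 0.0472,
  S = 0.0660, T = 0.0535, W = 0.0110, Y = 0.0292, V = 0.0687
)
UNIPROT_BG <- UNIPROT_BG / sum(UNIPROT_BG)

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# BLOSUM62 restricted to the 20 standard residues plus X (scored 0 against
# everything, the package-wide treatment of ambiguity characters).
# Cached after the first load.
.plastex_cache <- new.env(parent = emptyenv())
blosum62_matrix <- function() {
  if (is.null(.plastex_cache$blosum62)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    m <- env$BLOSUM62[AA_CHARS, AA_CHARS]
    full <- matrix(0L, 21L, 21L,
                   dimnames = list(c(AA_CHARS, "X"), c(AA_CHARS, "X")))
    full[AA_CHARS, AA_CHARS] <- m
    .plastex_cache$blosum62 <- full
  }
  .plastex_cache$blosum62
}

stop_plastex <- function(...) stop(..., call. = FALSE)
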