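DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of character sequences
#'
#' Vectorized reverse complement over plain character vectors (uppercase
#' A/C/G/T/N). Wraps \code{Biostrings::reverseComplement}.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAGG"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical k-mer (lexicographic minimum of sequence and reverse complement)
#'
#' Strand-equivalent k-mers are merged throughout the pipeline onto the
#' lexicographically smaller of the pair; reverse-complement palindromes map
#' to themselves.
#'
#' @param x character vector over A/C/G/T.
#' @return character vector of canonical sequences.
#' @export
#' @examples
#' canonicalize("GT")          # "AC"
#' canonicalize("CCAATATTGG") # palindromic: unchanged
canonicalize <- function(x) {
  if (length(x) == 0L) return(character(0))
  if (any(grepl("[^ACGT]", x))) {
    stop("canonicalize() requires sequences over {A,C,G,T}")
  }
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

is_palindromic <- function(x) x == revcomp(x)

# integer base codes 1..4 (A,C,G,T); N and anything else -> NA
dna_index_matrix <- function(x) {
  if (length(x) == 0L) return(matrix(integer(0), nrow = 0, ncol = 0))
  m <- as.matrix(Biostrings::DNAStringSet(x))
  matrix(match(m, DNA_BASES), nrow = nrow(m))
}

# all k-mers over ACGT in lexicographic order (use only for small k)
all_kmers <- function(k) {
  stopifnot(k >= 1, k <= 10)
  Biostrings::mkAllStrings(DNA_BASES, k)
}

# number of canonical k-mer classes: palindromes exist only for even k
n_canonical_kmers <- function(k) {
  n_pal <- if (k %% 2L == 0L) 4^(k / 2) else 0
  (4^k - n_pal) / 2 + n_pal
}

check_dna <- function(x, allow_n = TRUE, what = "sequence") {
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- grep(pat, x)
  if (length(bad)) {
    stop(sprintf("%s %d contains letters outside the allowed DNA alphabet",
                 what, bad[1]))
  }
  invisible(TRUE)
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

iupac_code <- function(bases) {
  bases <- sort(unique(bases))
  for (code in names(IUPAC_SETS)) {
    if (identical(sort(IUPAC_SETS[[code]]), bases)) return(code)
  }
  "N"
}

# does IUPAC letter a denote a subset of the bases letter b denotes?
iupac_subset <- function(a, b) {
  all(IUPAC_SETS[[a]] %in% IUPAC_SETS[[b]])
}
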