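#' A-tract detection
#'
#' An A-tract is a run of at least \code{min_len} consecutive A·T base pairs
#' without an intervening TpA step, i.e. a substring of the form A^n T^m with
#' n + m >= min_len (pure A- or pure T-runs qualify). Returns the leftmost
#' longest qualifying interval.
#'
#' @param seq a single sequence over A/C/G/T.
#' @param min_len minimum tract length (default 4).
#' @return list with \code{has_a_tract} and, when found, \code{start} and
#'   \code{end} (1-based inclusive).
#' @export
#' @examples
#' has_a_tract("AAATTT")  # TRUE
#' has_a_tract("ATATAT")  # FALSE: every A.T pair is broken by a TpA step
has_a_tract <- function(seq, min_len = 4) {
  check_dna(seq, allow_n = FALSE, what = "sequence")
  m <- gregexpr("A*T*", seq)[[1]]
  len <- attr(m, "match.length")
  ok <- len >= min_len
  if (!any(ok)) return(list(has_a_tract = FALSE, start = NA, end = NA))
  best <- which(ok)[which.max(len[ok])]
  # leftmost longest: which.max returns the first maximum
  list(has_a_tract = TRUE, start = as.integer(m[best]),
       end = as.integer(m[best] + len[best] - 1L))
}

#' Enumerate the SRF-type CArG-boxes
#'
#' All distinct canonical 10-mers matching CC(A/T)6GG — 36 modulo reverse
#' complement — sorted lexicographically and annotated with A-tract status
#' (which is strand invariant: the reverse complement of A^nT^m is A^mT^n).
#'
#' @param min_len A-tract minimum length (default 4).
#' @return data.frame: kmer (canonical), center (the W6 core), has_a_tract.
#' @export
enumerate_srf_cargboxes <- function(min_len = 4) {
  centers <- Biostrings::mkAllStrings(c("A", "T"), 6)
  boxes <- unique(canonicalize(paste0("CC", centers, "GG")))
  boxes <- sort(boxes)
  data.frame(kmer = boxes,
             center = substr(boxes, 3, 8),
             has_a_tract = vapply(boxes, function(b)
               has_a_tract(b, min_len)$has_a_tract, logical(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' CArG-box affinity table (A-tract enrichment analysis)
#'
#' Joins the 36 canonical SRF-type CArG-boxes with their relative affinities
#' and counts, sorted by decreasing affinity (ties broken lexicographically).
#' CArG-boxes absent from the affinity table get affinity 0 and a missing
#' flag.
#'
#' @param aff an \code{\link{affinity_table}} with k = 10.
#' @return data.frame: rank, kmer, center, has_a_tract, affinity, count,
#'   missing.
#' @export
atract_affinity_table <- function(aff) {
  if (aff$k != 10) stop("CArG-box analysis requires k = 10")
  boxes <- enumerate_srf_cargboxes()
  idx <- match(boxes$kmer, aff$table$kmer)
  out <- data.frame(boxes,
                    affinity = ifelse(is.na(idx), 0,
                                      aff$table$affinity[idx]),
                    count = ifelse(is.na(idx), 0L, aff$table$count[idx]),
                    missing = is.na(idx),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$affinity, out$kmer), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", "kmer", "center", "has_a_tract", "affinity", "count",
          "missing")]
}

#' Top-affinity k-mer report
#'
#' The \code{n} highest-affinity k-mers of a run (the bar-chart table), with
#' CArG-box annotation; deterministic given the affinity table (ties broken
#' lexicographically).
#'
#' @param aff an \code{\link{affinity_table}}.
#' @param n number of k-mers to report (default 21).
#' @return data.frame: rank, kmer, affinity, count, is_srf_cargbox,
#'   has_a_tract.
#' @export
top_affinity_report <- function(aff, n = 21) {
  tab <- aff$table[order(-aff$table$affinity, aff$table$kmer), ]
  tab <- head(tab, n)
  srf <- grepl("^CC[AT]{6}GG$", tab$kmer) |
    grepl("^CC[AT]{6}GG$", revcomp(tab$kmer))
  data.frame(rank = seq_len(nrow(tab)), kmer = tab$kmer,
             affinity = tab$affinity, count = tab$count,
             is_srf_cargbox = srf,
             has_a_tract = vapply(tab$kmer, function(b)
               has_a_tract(b)$has_a_tract, logical(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
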