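#' Relative k-mer affinities from one selection round
#'
#' For each observed canonical k-mer, the raw enrichment is
#' \code{(observed / expected)^(1/r)} — observed sliding-window counts in
#' round r against expected counts under the R0 background model — and
#' affinities are the raw enrichments normalized so the strongest k-mer
#' scores exactly 1. K-mers observed fewer than \code{count_floor} times are
#' kept but flagged low-confidence.
#'
#' @param pool_r a \code{\link{read_pool}} from round r >= 1.
#' @param bg a \code{\link{markov_background}} fitted on R0.
#' @param k k-mer length.
#' @param r selection round used in the enrichment exponent; defaults to the
#'   pool's \code{round_index}.
#' @param merge_revcomp merge strand-equivalent k-mers (default TRUE).
#' @param count_floor low-confidence flag threshold (default 5); k-mers are
#'   also flagged when fewer than \code{count_floor} distinct read sequences
#'   support them — at finite library size, selection duplicates whole
#'   probes, and a large count carried by one or two duplicated reads says
#'   more about sampling than about binding.
#' @return an object of class \code{affinity_table}: list with \code{k},
#'   \code{round}, \code{provenance} and \code{table} (data.frame: kmer,
#'   count, distinct, expected, raw, affinity, low_confidence; sorted by
#'   decreasing affinity, ties broken lexicographically).
#' @export
estimate_affinities <- function(pool_r, bg, k, r = pool_r$round_index,
                                merge_revcomp = TRUE, count_floor = 5) {
  if (r < 1) stop("affinities require a selection round r >= 1")
  ct <- count_kmers(pool_r, k, merge_revcomp = merge_revcomp)
  tab <- ct$table
  exp_ct <- expected_kmer_counts(bg, k, length(pool_r$sequences),
                                 read_length(pool_r),
                                 merge_revcomp = merge_revcomp,
                                 kmers = tab$kmer)$expected
  raw <- (tab$count / exp_ct)^(1 / r)
  tab <- data.frame(kmer = tab$kmer, count = tab$count,
                    distinct = tab$distinct, expected = exp_ct,
                    raw = raw, affinity = raw / max(raw),
                    low_confidence = tab$count < count_floor |
                      tab$distinct < count_floor |
                      tab$max_single > 0.5 * tab$count,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$affinity, tab$kmer), ]
  rownames(tab) <- NULL
  structure(list(k = as.integer(k), round = as.integer(r),
                 provenance = sprintf("R%d", r),
                 merge_revcomp = merge_revcomp, table = tab),
            class = "affinity_table")
}

#' @export
print.affinity_table <- function(x, ...) {
  cat(sprintf("Relative %d-mer affinities (%s): %d k-mers, max = %g\n",
              x$k, x$provenance, nrow(x$table), max(x$table$affinity)))
  print(head(x$table), ...)
  invisible(x)
}

#' Look up affinities in either orientation
#'
#' Queries are canonicalized, so a k-mer and its reverse complement return
#' the same value. Absent k-mers return NA.
#'
#' @param aff an \code{\link{affinity_table}}.
#' @param kmers character vector of query k-mers.
#' @return numeric vector of affinities.
#' @export
affinity_of <- function(aff, kmers) {
  key <- if (aff$merge_revcomp) canonicalize(kmers) else kmers
  aff$table$affinity[match(key, aff$table$kmer)]
}

# exact local linear regression (tricube weights) evaluated at x0
.local_linear_at <- function(x, y, x0, span) {
  n <- length(x)
  q <- max(2L, ceiling(span * n))
  d <- abs(x - x0)
  h <- sort(d, partial = min(q, n))[min(q, n)]
  if (h <= 0) {
    w <- as.numeric(d == 0)
  } else {
    w <- pmax(0, 1 - (d / h)^3)^3
  }
  sw <- sum(w)
  xm <- sum(w * x) / sw
  ym <- sum(w * y) / sw
  sxx <- sum(w * (x - xm)^2)
  if (sxx < 1e-12) return(ym)
  beta <- sum(w * (x - xm) * (y - ym)) / sxx
  ym + beta * (x0 - xm)
}

# local linear fit at every x; exact when n <= n_exact, otherwise exact fits
# at quantile anchors with linear interpolation in between
.local_linear_fit <- function(x, y, span = 0.5, n_exact = 2000L,
                              n_anchors = 256L) {
  n <- length(x)
  if (n <= n_exact) {
    return(vapply(x, function(x0) .local_linear_at(x, y, x0, span),
                  numeric(1)))
  }
  anchors <- unique(quantile(x, probs = seq(0, 1, length.out = n_anchors),
                             names = FALSE, type = 7))
  fa <- vapply(anchors, function(x0) .local_linear_at(x, y, x0, span),
               numeric(1))
  stats::approx(anchors, fa, xout = x, rule = 2)$y
}

#' Integrate round-1 and round-2 affinity estimates by local regression
#'
#' Locally-weighted linear regression (tricube weights, degree 1) of
#' \code{log(affinity R2)} on \code{log(affinity R1)} over the shared k-mers:
#' the R1 estimate has low bias, the R2 estimate low variance, and the local
#' regression trades the two off on the multiplicative (log) scale. The
#' combined estimate is the back-transformed fit, renormalized to maximum 1.
#'
#' @param aff_r1,aff_r2 \code{\link{affinity_table}}s of the same k.
#' @param span local-regression span (fraction of points per neighborhood).
#' @return an \code{\link{affinity_table}} with provenance "loess".
#' @export
loess_combine <- function(aff_r1, aff_r2, span = 0.5) {
  if (aff_r1$k != aff_r2$k) stop("affinity tables must use the same k")
  shared <- intersect(aff_r1$table$kmer, aff_r2$table$kmer)
  if (length(shared) < 10) stop("need at least 10 shared k-mers")
  a1 <- aff_r1$table[match(shared, aff_r1$table$kmer), ]
  a2 <- aff_r2$table[match(shared, aff_r2$table$kmer), ]
  x <- log(a1$affinity)
  y <- log(a2$affinity)
  fit <- .local_linear_fit(x, y, span = span)
  comb <- exp(fit)
  comb <- comb / max(comb)
  tab <- data.frame(kmer = shared, count = a2$count, distinct = a2$distinct,
                    expected = a2$expected, raw = comb, affinity = comb,
                    low_confidence = a1$low_confidence | a2$low_confidence,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$affinity, tab$kmer), ]
  rownames(tab) <- NULL
  structure(list(k = aff_r1$k, round = aff_r2$round, provenance = "loess",
                 merge_revcomp = aff_r1$merge_revcomp, table = tab),
            class = "affinity_table")
}
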