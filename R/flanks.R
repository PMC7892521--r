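# regex for an IUPAC pattern
.iupac_regex <- function(pattern) {
  paste(vapply(strsplit(pattern, "")[[1]], function(ch) {
    b <- IUPAC_SETS[[ch]]
    if (length(b) == 1) b else paste0("[", paste(b, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Guided flank extraction and orientation around a core motif
#'
#' Extracts every read window of length \code{flank + core + flank} whose
#' central positions match the core pattern (default the SRF-type CArG-box
#' CC(A/T)6GG) on either strand. Because the core pattern is closed under
#' reverse complement, every extracted window is two-fold orientation
#' ambiguous; the residual ambiguity is resolved by a two-orientation mixture
#' EM over all columns of the window, and the oriented set's PWM is returned
#' (flank preferences are read from the outer columns).
#'
#' @param pool a \code{\link{read_pool}}.
#' @param core IUPAC core pattern (default "CCWWWWWWGG").
#' @param flank flank width on each side (default 4).
#' @param seed seed for the EM initialization.
#' @param max_iter,tol EM stopping rule.
#' @param weighting how read multiplicity enters the column statistics:
#'   \code{"log"} (default) weights each distinct read by log2(1 + copies) —
#'   enrichment counts as evidence, but a single duplicated probe cannot
#'   dominate the flank columns at desk scale; \code{"raw"} uses copy
#'   numbers; \code{"unique"} counts each distinct read once.
#' @return list with \code{sequences} (oriented windows), \code{weights}
#'   (per-window weights under the chosen scheme), \code{pwm}
#'   (\code{flank + core + flank} columns), \code{posterior} (probability
#'   that each window was kept in its as-extracted orientation) and
#'   \code{n_matches} (number of distinct matching windows).
#' @export
flank_extract_orient <- function(pool, core = "CCWWWWWWGG", flank = 4,
                                 seed = 1, max_iter = 200, tol = 1e-8,
                                 weighting = c("log", "raw", "unique")) {
  weighting <- match.arg(weighting)
  L <- read_length(pool)
  k <- nchar(core)
  width <- k + 2L * flank
  if (L < width) stop("reads are shorter than flank + core + flank")
  core_re <- paste0("^", .iupac_regex(core), "$")
  mult <- table(pool$sequences)
  seqs <- names(mult)
  rw <- switch(weighting,
               log = log2(1 + as.numeric(mult)),
               raw = as.numeric(mult),
               unique = rep(1, length(mult)))
  wins <- character(0)
  wts <- numeric(0)
  for (s in seq_len(L - width + 1L)) {
    win <- substr(seqs, s, s + width - 1L)
    centre <- substr(win, flank + 1L, flank + k)
    hit <- grepl(core_re, centre) & !grepl("N", win, fixed = TRUE)
    if (any(hit)) {
      wins <- c(wins, win[hit])
      wts <- c(wts, rw[hit])
    }
  }
  if (!length(wins)) stop("no window matches the core pattern")
  M <- dna_index_matrix(wins)
  n <- nrow(M)
  set.seed(seed)
  z <- runif(n)  # probability of the as-extracted orientation
  Mrc <- (5L - M)[, width:1, drop = FALSE]
  theta <- NULL
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    cnt <- matrix(0, 4, width)
    for (j in seq_len(width)) {
      cnt[, j] <- .wtab4(M[, j], wts * z) + .wtab4(Mrc[, j], wts * (1 - z))
    }
    theta <- sweep(cnt + 0.5, 2, colSums(cnt + 0.5), "/")
    lth <- log(theta)
    sf <- numeric(n); sr <- numeric(n)
    for (j in seq_len(width)) {
      sf <- sf + lth[M[, j] + (j - 1L) * 4L]
      sr <- sr + lth[Mrc[, j] + (j - 1L) * 4L]
    }
    mx <- pmax(sf, sr)
    ll <- sum(wts * (mx + log(0.5 * exp(sf - mx) + 0.5 * exp(sr - mx))))
    z <- 1 / (1 + exp(sr - sf))
    if (it > 1 && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  oriented <- ifelse(z >= 0.5, wins, revcomp(wins))
  p <- pwm(theta, pseudocount = 0.5)
  # deterministic global orientation: lexicographically smaller consensus
  rc <- pwm_revcomp(p)
  if (iupac_consensus(rc) < iupac_consensus(p)) {
    p <- rc
    oriented <- revcomp(oriented)
    z <- 1 - z
    attr(p, "orientation") <- "reverse_complemented"
  }
  list(sequences = oriented, weights = wts, pwm = p, posterior = z,
       n_matches = n)
}

#' Positional distribution of k-mers along the reads, with CArG classification
#'
#' Counts exact forward-strand matches of each k-mer at every read offset
#' (1-based), and labels each k-mer \code{complete} (matches CC(A/T)6GG),
#' \code{incomplete} (matches (A/T)2 N6 (A/T)2 but is not complete) or
#' \code{other}. Incomplete CArG-boxes that piggyback on the adapter's
#' terminal CT show up as histogram mass at offsets 1-2.
#'
#' @param pool a \code{\link{read_pool}}.
#' @param kmer_list character vector of k-mers (one common length).
#' @param complete_pattern,incomplete_pattern IUPAC patterns for the classes.
#' @return list with \code{histogram} (k-mer x offset count matrix) and
#'   \code{classes} (data.frame: kmer, class).
#' @export
position_bias <- function(pool, kmer_list,
                          complete_pattern = "CCWWWWWWGG",
                          incomplete_pattern = "WWNNNNNNWW") {
  L <- read_length(pool)
  k <- nchar(kmer_list[1])
  if (k > L) stop("k-mer length exceeds the read length")
  offs <- seq_len(L - k + 1L)
  H <- matrix(0L, nrow = length(kmer_list), ncol = length(offs),
              dimnames = list(kmer_list, offs))
  for (s in offs) {
    win <- substr(pool$sequences, s, s + k - 1L)
    tab <- table(win[win %in% kmer_list])
    if (length(tab)) H[names(tab), s] <- as.integer(tab)
  }
  comp_re <- paste0("^", .iupac_regex(complete_pattern), "$")
  inc_re <- paste0("^", .iupac_regex(incomplete_pattern), "$")
  cls <- ifelse(grepl(comp_re, kmer_list), "complete",
                ifelse(grepl(inc_re, kmer_list), "incomplete", "other"))
  list(histogram = H,
       classes = data.frame(kmer = kmer_list, class = cls,
                            stringsAsFactors = FALSE))
}
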