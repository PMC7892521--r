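#' Sliding-window k-mer counts of a read pool
#'
#' Counts every k-wide window of every read; windows containing N are
#' skipped. With \code{merge_revcomp} (the default, matching the convention
#' that counts comprise occurrences of a sequence and its reverse
#' complement), each window is counted once onto its canonical key.
#'
#' @param pool a \code{\link{read_pool}}.
#' @param k k-mer length (<= read length).
#' @param merge_revcomp merge strand-equivalent k-mers onto canonical keys.
#' @return an object of class \code{kmer_counts}: list with \code{k},
#'   \code{merge_revcomp}, \code{total_windows} and \code{table}
#'   (data.frame: kmer, count, distinct — the number of distinct read
#'   sequences contributing to the count — and max_single — the largest
#'   contribution of any one read sequence; both are duplication diagnostics
#'   at finite library size; sorted by decreasing count then kmer).
#' @export
count_kmers <- function(pool, k, merge_revcomp = TRUE) {
  L <- read_length(pool)
  if (k > L) stop("k exceeds the read length")
  seqv <- NULL  # data.table NSE
  du <- data.table::data.table(seqv = pool$sequences)[, list(m = .N),
                                                      by = seqv]
  useqs <- du$seqv
  mult <- du$m
  win <- vector("list", L - k + 1L)
  wm <- vector("list", L - k + 1L)
  for (s in seq_len(L - k + 1L)) {
    win[[s]] <- substr(useqs, s, s + k - 1L)
    wm[[s]] <- mult
  }
  win <- unlist(win, use.names = FALSE)
  wm <- unlist(wm, use.names = FALSE)
  if (any(grepl("N", win, fixed = TRUE))) {
    ok <- !grepl("N", win, fixed = TRUE)
    win <- win[ok]
    wm <- wm[ok]
  }
  kmer <- NULL; count <- NULL; m <- NULL  # data.table NSE
  distinct <- NULL; max_single <- NULL
  dt <- data.table::data.table(kmer = win, m = wm)[
    , list(count = sum(m), distinct = .N, max_single = max(m)), by = kmer]
  if (merge_revcomp) {
    dt[, kmer := canonicalize(kmer)]
    dt <- dt[, list(count = sum(count), distinct = sum(distinct),
                    max_single = max(max_single)), by = kmer]
  }
  data.table::setorder(dt, -count, kmer)
  structure(list(k = as.integer(k), merge_revcomp = merge_revcomp,
                 total_windows = sum(dt$count),
                 table = as.data.frame(dt)),
            class = "kmer_counts")
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat(sprintf("%d-mer counts over %d windows (%s), %d distinct keys\n",
              x$k, x$total_windows,
              if (x$merge_revcomp) "canonical" else "forward strand",
              nrow(x$table)))
  print(head(x$table), ...)
  invisible(x)
}

# plug-in KL (bits) of a sequence set's k-mer distribution vs the background
.plugin_kl <- function(seqs, bg, k, merge_revcomp, round_index = 1L) {
  ct <- count_kmers(read_pool(seqs, round_index), k,
                    merge_revcomp = merge_revcomp)
  tab <- ct$table
  N <- ct$total_windows
  p0 <- kmer_probability(bg, tab$kmer)
  if (merge_revcomp) {
    rc <- revcomp(tab$kmer)
    pal <- tab$kmer == rc
    p0 <- p0 + ifelse(pal, 0, kmer_probability(bg, rc))
  }
  f <- tab$count / N
  sum(f * log2(f / p0))
}

#' Information gain of a selection round over the background
#'
#' Kullback-Leibler divergence (in bits) of the observed round-r k-mer
#' frequency distribution from the background-model distribution, over
#' canonical keys when merging strands.
#'
#' Reads are duplicate-collapsed first (\code{dedup}): at finite library
#' size, selection and PCR resample whole probes, and duplicates inflate the
#' divergence by about two bits per added base without carrying any
#' information about binding-site width. When an R0 pool is supplied, the
#' same plug-in statistic is computed on equally sized blocks of unselected
#' reads and subtracted: the plug-in estimator has a support-size bias that
#' grows with 4^k, and the matched baseline cancels it by construction, so
#' the net value measures information gained by selection.
#'
#' @param pool_r a selection-round \code{\link{read_pool}} (round >= 1).
#' @param bg a \code{\link{markov_background}} fitted on R0.
#' @param k k-mer length.
#' @param r0_pool optional R0 \code{\link{read_pool}} providing the matched
#'   baseline (recommended for length selection).
#' @param merge_revcomp merge strand-equivalent k-mers.
#' @param dedup collapse duplicate reads before counting (default TRUE).
#' @param baseline_blocks maximum number of disjoint R0 baseline blocks to
#'   average (default 3).
#' @return information gain in bits.
#' @export
information_gain <- function(pool_r, bg, k, r0_pool = NULL,
                             merge_revcomp = TRUE, dedup = TRUE,
                             baseline_blocks = 3) {
  seqs <- pool_r$sequences
  if (dedup) seqs <- unique(seqs)
  if (is.null(r0_pool)) {
    return(.plugin_kl(seqs, bg, k, merge_revcomp, pool_r$round_index))
  }
  u0 <- r0_pool$sequences
  if (dedup) u0 <- unique(u0)
  n <- min(length(seqs), length(u0))
  nb <- max(1L, min(baseline_blocks, floor(length(u0) / n)))
  base <- mean(vapply(seq_len(nb), function(b) {
    .plugin_kl(u0[((b - 1) * n + 1):(b * n)], bg, k, merge_revcomp, 0L)
  }, numeric(1)))
  .plugin_kl(seqs[seq_len(n)], bg, k, merge_revcomp, pool_r$round_index) - base
}

#' Motif-length selection by the information-gain plateau rule
#'
#' Computes the information gain for each k in \code{k_range} and returns the
#' smallest k whose gain reaches \code{(1 - plateau_tol)} of the maximum:
#' the underlying divergence is non-decreasing under refinement, so
#' "maximal" is read as the onset of saturation.
#'
#' @param pool_r the selection-round pool to evaluate (typically R2).
#' @param bg background model fitted on R0.
#' @param k_range contiguous candidate k values (default 6:14).
#' @param plateau_tol relative plateau tolerance (default 0.01).
#' @param r0_pool optional R0 pool for the matched-baseline estimator
#'   (see \code{\link{information_gain}}).
#' @param ... passed to \code{\link{information_gain}}.
#' @return list with \code{k} (selected length) and \code{profile}
#'   (data.frame: k, ig).
#' @export
select_k <- function(pool_r, bg, k_range = 6:14, plateau_tol = 0.01,
                     r0_pool = NULL, ...) {
  if (!length(k_range)) stop("k_range must be non-empty")
  ig <- vapply(k_range, function(k)
    information_gain(pool_r, bg, k, r0_pool = r0_pool, ...), numeric(1))
  list(k = .plateau_onset(k_range, ig, plateau_tol),
       profile = data.frame(k = k_range, ig = ig))
}

# smallest k whose gain reaches (1 - tol) of the maximum
.plateau_onset <- function(k_range, ig, tol = 0.01) {
  mx <- max(ig)
  thr <- if (mx > 0) (1 - tol) * mx else mx
  min(k_range[ig >= thr])
}
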