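#' Markov background model of an initial SELEX library
#'
#' Order-m Markov model fitted to R0 reads (as sequenced; strands are not
#' pooled), used to predict expected k-mer counts in the absence of
#' selection. Windows are treated as starting from the stationary-style
#' m-mer marginal estimated from all read positions.
#'
#' @param order Markov order m (>= 0).
#' @param initial named probability vector over all m-mers (length 4^m;
#'   a single unnamed 1 for m = 0).
#' @param transitions 4^m x 4 matrix of conditional probabilities
#'   P(base | previous m bases), rows named by context, columns A, C, G, T.
#' @param alpha pseudocount used in fitting (metadata).
#' @return an object of class \code{markov_background}.
#' @export
markov_background <- function(order, initial, transitions, alpha = 0.5) {
  order <- as.integer(order)
  stopifnot(order >= 0, nrow(transitions) == 4^order, ncol(transitions) == 4)
  if (any(abs(rowSums(transitions) - 1) > 1e-9)) {
    stop("every conditional distribution must sum to 1")
  }
  if (abs(sum(initial) - 1) > 1e-9) stop("initial distribution must sum to 1")
  colnames(transitions) <- DNA_BASES
  structure(list(order = order, initial = initial, transitions = transitions,
                 alpha = alpha),
            class = "markov_background")
}

#' @export
print.markov_background <- function(x, ...) {
  cat(sprintf("Markov background of order %d (pseudocount %.3g)\n",
              x$order, x$alpha))
  invisible(x)
}

# context code in 1..4^m from an n x m matrix of base codes (1..4)
.ctx_code <- function(M) {
  m <- ncol(M)
  if (m == 0L) return(rep(1L, nrow(M)))
  code <- rep(0, nrow(M))
  for (i in seq_len(m)) code <- code * 4 + (M[, i] - 1L)
  code + 1L
}

#' Fit a Markov background model to a read pool
#'
#' Maximum-likelihood estimates with additive pseudocount \code{alpha} from
#' all read positions of the forward reads. Windows containing N are skipped.
#'
#' @param pool a \code{\link{read_pool}} (typically R0).
#' @param order Markov order m; must be smaller than the read length.
#' @param alpha additive pseudocount (default 0.5; avoids zero conditionals
#'   for high orders on small pools).
#' @return a \code{\link{markov_background}}.
#' @export
fit_markov <- function(pool, order, alpha = 0.5) {
  m <- as.integer(order)
  L <- read_length(pool)
  if (m >= L) stop("order must be smaller than the read length")
  M <- dna_index_matrix(pool$sequences)   # N -> NA
  K <- 4^m
  trans_counts <- matrix(0, nrow = K, ncol = 4)
  init_counts <- numeric(K)
  for (j in seq_len(L - m)) {
    ctxM <- M[, j + seq_len(m) - 1L, drop = FALSE]
    ctx <- .ctx_code(ctxM)
    nxt <- M[, j + m]
    ok <- !is.na(ctx) & !is.na(nxt)
    if (any(ok)) {
      tab <- tabulate((ctx[ok] - 1L) * 4L + nxt[ok], nbins = 4L * K)
      trans_counts <- trans_counts + matrix(tab, nrow = K, ncol = 4,
                                            byrow = TRUE)
    }
    if (any(ok)) init_counts <- init_counts + tabulate(ctx[ok], nbins = K)
  }
  # last m-mer window has no successor but still informs the marginal
  if (m >= 1) {
    ctx <- .ctx_code(M[, L - m + seq_len(m), drop = FALSE])
    ok <- !is.na(ctx)
    init_counts <- init_counts + tabulate(ctx[ok], nbins = K)
  }
  trans <- (trans_counts + alpha) / (rowSums(trans_counts) + 4 * alpha)
  init <- (init_counts + alpha) / (sum(init_counts) + K * alpha)
  if (alpha == 0) {
    # guard 0/0 contexts never observed
    bad <- rowSums(trans_counts) == 0
    trans[bad, ] <- 0.25
    if (sum(init_counts) == 0) init[] <- 1 / K
  }
  ctx_names <- if (m >= 1) all_kmers(m) else NULL
  rownames(trans) <- ctx_names
  names(init) <- ctx_names
  markov_background(m, init, trans, alpha = alpha)
}

#' Probability of k-mers under a Markov background
#'
#' Chains the m-mer marginal of the first m bases with the conditional
#' distributions for the remaining bases: a per-window probability, so that
#' probabilities over all 4^k k-mers sum to 1.
#'
#' @param bg a \code{\link{markov_background}}.
#' @param kmers character vector over A/C/G/T, all of one length.
#' @return numeric vector of probabilities.
#' @export
kmer_probability <- function(bg, kmers) {
  k <- nchar(kmers[1])
  m <- bg$order
  X <- dna_index_matrix(kmers)
  if (k <= m) {
    # marginalize the m-mer initial distribution over suffixes
    full <- all_kmers(m)
    p_full <- bg$initial
    pref <- substr(full, 1L, k)
    agg <- rowsum(p_full, pref)
    return(as.numeric(agg[kmers, 1]))
  }
  if (m == 0L) {
    p <- rep(1, nrow(X))
    for (j in seq_len(k)) p <- p * bg$transitions[1L, ][X[, j]]
    return(p)
  }
  ctx <- .ctx_code(X[, seq_len(m), drop = FALSE])
  p <- bg$initial[ctx]
  Km1 <- 4^(m - 1)
  for (j in (m + 1):k) {
    b <- X[, j]
    p <- p * bg$transitions[ctx + (b - 1L) * 4^m]
    ctx <- ((ctx - 1L) %% Km1) * 4L + (b - 1L) + 1L
  }
  unname(p)
}

#' Expected k-mer counts under the background model
#'
#' Expected sliding-window counts for a pool of \code{n_reads} reads of
#' length \code{read_len}: \code{n_reads * (read_len - k + 1) * P(w)}. With
#' \code{merge_revcomp}, expectations of a k-mer and its reverse complement
#' are summed onto the canonical (lexicographically smaller) key;
#' reverse-complement palindromes are unchanged.
#'
#' @param bg a \code{\link{markov_background}}.
#' @param k k-mer length.
#' @param n_reads,read_len pool geometry.
#' @param merge_revcomp merge strand-equivalent k-mers (default TRUE).
#' @param kmers optional k-mers to evaluate (canonical keys when merging);
#'   defaults to all 4^k (or all canonical k-mers), feasible only for small k.
#' @return \code{data.frame} with columns \code{kmer}, \code{expected}.
#' @export
expected_kmer_counts <- function(bg, k, n_reads, read_len,
                                 merge_revcomp = TRUE, kmers = NULL) {
  if (k > read_len) stop("k exceeds the read length")
  windows <- n_reads * (read_len - k + 1)
  if (is.null(kmers)) {
    kmers <- all_kmers(k)
    if (merge_revcomp) kmers <- sort(unique(canonicalize(kmers)))
  }
  p <- kmer_probability(bg, kmers)
  if (merge_revcomp) {
    rc <- revcomp(kmers)
    pal <- kmers == rc
    p <- p + ifelse(pal, 0, kmer_probability(bg, rc))
  }
  data.frame(kmer = kmers, expected = windows * p, stringsAsFactors = FALSE)
}

#' Cross-replicate selection of the background Markov order
#'
#' For each candidate order, fits the model on one R0 replicate and predicts
#' the other replicate's observed 8-mer counts, scoring the prediction with
#' the coefficient of determination R^2 over all 4^k k-mers; the two
#' directions are averaged. Returns the smallest order whose mean R^2 is
#' within \code{tol} of the maximum (parsimony tie-break: near-ties between
#' adjacent orders are common).
#'
#' @param poolA,poolB two R0 replicates.
#' @param orders candidate orders (default 0:5).
#' @param k k-mer length used for prediction (default 8).
#' @param alpha fitting pseudocount.
#' @param tol tie tolerance on R^2 (default 0.001).
#' @return list with \code{best_order} and a data.frame \code{profile}
#'   (order, r2).
#' @export
select_order <- function(poolA, poolB, orders = 0:5, k = 8, alpha = 0.5,
                         tol = 0.001) {
  if (missing(poolB) || is.null(poolB)) {
    stop("two R0 replicates are required; with a single pool, split it in ",
         "half and pass the halves as pseudo-replicates")
  }
  kmers <- all_kmers(k)
  obs <- list(A = .full_kmer_counts(poolA, k, kmers),
              B = .full_kmer_counts(poolB, k, kmers))
  geom <- list(A = c(length(poolA$sequences), read_length(poolA)),
               B = c(length(poolB$sequences), read_length(poolB)))
  r2 <- sapply(orders, function(m) {
    fits <- list(A = fit_markov(poolA, m, alpha), B = fit_markov(poolB, m, alpha))
    mean(c(.r2_predict(fits$A, obs$B, geom$B, k, kmers),
           .r2_predict(fits$B, obs$A, geom$A, k, kmers)))
  })
  best <- min(orders[r2 >= max(r2) - tol])
  list(best_order = best,
       profile = data.frame(order = orders, r2 = r2))
}

.full_kmer_counts <- function(pool, k, kmers) {
  ct <- count_kmers(pool, k, merge_revcomp = FALSE)
  v <- setNames(numeric(length(kmers)), kmers)
  v[ct$table$kmer] <- ct$table$count
  v
}

.r2_predict <- function(bg, observed, geom, k, kmers) {
  exp_ct <- geom[1] * (geom[2] - k + 1) * kmer_probability(bg, kmers)
  ss_res <- sum((observed - exp_ct)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  1 - ss_res / ss_tot
}

# sample an n x L base-code matrix from a Markov background
.sample_markov_matrix <- function(bg, n, L) {
  m <- bg$order
  M <- matrix(0L, n, L)
  if (m == 0L) {
    M[] <- sample.int(4L, n * L, replace = TRUE, prob = bg$transitions[1L, ])
    return(M)
  }
  if (L < m) stop("read length shorter than the background order")
  start <- sample.int(4^m, n, replace = TRUE, prob = bg$initial)
  rem <- start - 1L
  for (i in m:1) {
    M[, i] <- (rem %% 4L) + 1L
    rem <- rem %/% 4L
  }
  ctx <- start
  Km1 <- 4^(m - 1)
  cum <- t(apply(bg$transitions, 1, cumsum))
  for (j in (m + 1):L) {
    u <- runif(n)
    b <- 1L + (u > cum[ctx, 1L]) + (u > cum[ctx, 2L]) + (u > cum[ctx, 3L])
    M[, j] <- b
    ctx <- ((ctx - 1L) %% Km1) * 4L + (b - 1L) + 1L
  }
  M
}
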