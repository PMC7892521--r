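#' Weighted sequence set
#'
#' Equal-length sequences over A/C/G/T/N with positive real weights; the
#' training material for motif discovery and dependence modelling.
#'
#' @param sequences character vector of equal-length sequences.
#' @param weights positive numeric weights (default 1).
#' @return an object of class \code{weighted_seqs}.
#' @export
weighted_seqs <- function(sequences, weights = rep(1, length(sequences))) {
  check_dna(sequences, allow_n = TRUE, what = "sequence")
  if (length(sequences)) {
    L <- nchar(sequences[1])
    if (any(nchar(sequences) != L)) stop("sequences must have equal length")
  }
  if (length(weights) != length(sequences) || any(weights <= 0)) {
    stop("weights must be positive and match the sequences")
  }
  structure(list(sequences = sequences, weights = as.numeric(weights)),
            class = "weighted_seqs")
}

#' Position weight matrix
#'
#' @param mat 4 x L matrix of column-stochastic probabilities (rows A,C,G,T).
#' @param pseudocount pseudocount used when estimating the matrix (metadata).
#' @param orientation free-text orientation tag.
#' @return an object of class \code{pwm} (the matrix, with attributes).
#' @export
pwm <- function(mat, pseudocount = NA_real_, orientation = "as_fitted") {
  stopifnot(is.matrix(mat), nrow(mat) == 4)
  if (any(mat < 0) || any(abs(colSums(mat) - 1) > 1e-9)) {
    stop("PWM columns must be probability distributions")
  }
  rownames(mat) <- DNA_BASES
  structure(mat, pseudocount = pseudocount, orientation = orientation,
            class = c("pwm", "matrix"))
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM of length %d (consensus %s)\n", ncol(x),
              iupac_consensus(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Reverse complement of a PWM
#' @param x a \code{\link{pwm}}.
#' @return the reverse-complement \code{\link{pwm}}.
#' @export
pwm_revcomp <- function(x) {
  pwm(unclass(x)[c(4, 3, 2, 1), ncol(x):1, drop = FALSE],
      pseudocount = attr(x, "pseudocount"),
      orientation = attr(x, "orientation"))
}

#' Build the motif-discovery training set from an affinity table
#'
#' Keeps k-mers with affinity above \code{cutoff}, pads each with k/2 N's on
#' both sides (so incomplete occurrences can slide into register during
#' discovery) and weights it by \code{scale} times its affinity.
#'
#' @param aff an \code{\link{affinity_table}}.
#' @param cutoff affinity cutoff (default 0.4; kept are strictly above).
#' @param scale weight upscaling factor (default 1e3).
#' @param use_flagged also keep low-confidence k-mers (default FALSE: k-mers
#'   whose apparent affinity rests on few counts or few distinct reads are
#'   duplication artifacts at desk scale and would pollute the motif).
#' @return a \code{\link{weighted_seqs}} of sequences of length 2k.
#' @export
build_training_set <- function(aff, cutoff = 0.4, scale = 1e3,
                               use_flagged = FALSE) {
  tab <- aff$table
  keep <- tab$affinity > cutoff
  if (!use_flagged && !is.null(tab$low_confidence)) {
    keep <- keep & !tab$low_confidence
  }
  if (!any(keep)) {
    stop("no k-mer has affinity above the cutoff; lower the cutoff")
  }
  pad <- strrep("N", floor(aff$k / 2))
  weighted_seqs(paste0(pad, tab$kmer[keep], pad),
                scale * tab$affinity[keep])
}

# log-likelihood terms of all windows x strands under a PWM (N contributes 0)
.window_scores <- function(M, lpwm, lpwm_rc, L) {
  n <- nrow(M); W <- ncol(M)
  nw <- W - L + 1L
  S <- matrix(0, n, 2L * nw)
  for (s in seq_len(nw)) {
    ap <- numeric(n); am <- numeric(n)
    for (j in seq_len(L)) {
      b <- M[, s + j - 1L]
      ok <- !is.na(b)
      idx <- b[ok] + (j - 1L) * 4L
      ap[ok] <- ap[ok] + lpwm[idx]
      am[ok] <- am[ok] + lpwm_rc[idx]
    }
    S[, s] <- ap
    S[, nw + s] <- am
  }
  S
}

#' De novo PWM discovery by weighted OOPS expectation maximization
#'
#' One occurrence per sequence, all windows on both strands with a uniform
#' position/strand prior, uniform 0.25 background; N positions are
#' marginalized (emission factor 1 under both motif and background), keeping
#' likelihoods comparable across sequences with different N counts. The best
#' of \code{restarts} random initializations is returned; equal-likelihood
#' runs are tie-broken by the lexicographically smallest consensus. The
#' output orientation is canonicalized so the consensus places CC before GG
#' when applicable.
#'
#' @param set a \code{\link{weighted_seqs}}.
#' @param L motif length (default 10).
#' @param restarts number of random initializations (default 200).
#' @param seed integer seed making the run deterministic.
#' @param max_iter,tol EM stopping rule (weighted log-likelihood gain per
#'   unit total weight below \code{tol}, or \code{max_iter} iterations).
#' @param pseudocount pseudocount per cell added to the final weighted count
#'   matrix (default 0.5).
#' @return a \code{\link{pwm}} with attributes \code{loglik} (weighted OOPS
#'   log likelihood of the returned matrix, natural log, with emissions as
#'   ratios to the uniform background) and \code{monotone} (TRUE if the EM
#'   objective never decreased).
#' @export
discover_pwm <- function(set, L = 10, restarts = 200, seed = 1,
                         max_iter = 500, tol = 1e-6, pseudocount = 0.5) {
  W <- nchar(set$sequences[1])
  if (W < L) stop("sequences are shorter than the motif length")
  M <- dna_index_matrix(set$sequences)
  if (all(is.na(M))) stop("degenerate training set: all positions are N")
  n <- nrow(M); nw <- W - L + 1L
  w <- set$weights
  set.seed(seed)
  # candidate window seeds: distinct data windows, most informative (fewest
  # N) first — for N-padded k-mer training sets the k-mers themselves seed
  # the search; ties are shuffled deterministically under the seed
  wseed <- unique(do.call(rbind, lapply(seq_len(nw), function(s)
    M[, s:(s + L - 1L), drop = FALSE])))
  wseed <- wseed[sample.int(nrow(wseed)), , drop = FALSE]
  wseed <- wseed[order(-rowSums(!is.na(wseed))), , drop = FALSE]
  best <- NULL
  for (rs in seq_len(restarts)) {
    if (rs %% 2 == 1 && (rs + 1) %/% 2 <= nrow(wseed)) {
      b <- wseed[(rs + 1) %/% 2, ]
      theta <- matrix(0.1, 4, L)
      for (j in seq_len(L)) if (!is.na(b[j])) theta[b[j], j] <- 0.7
      theta <- sweep(theta, 2, colSums(theta), "/")
    } else {
      theta <- matrix(stats::rgamma(4 * L, shape = 1), 4, L)
      theta <- sweep(theta, 2, colSums(theta), "/")
    }
    ll_old <- -Inf
    monotone <- TRUE
    for (it in seq_len(max_iter)) {
      lth <- log(theta) - log(0.25)
      lth_rc <- log(theta[c(4, 3, 2, 1), L:1, drop = FALSE]) - log(0.25)
      S <- .window_scores(M, lth, lth_rc, L)
      mx <- apply(S, 1, max)
      E <- exp(S - mx)
      rs_sum <- rowSums(E)
      ll <- sum(w * (mx + log(rs_sum) - log(2 * nw)))
      Z <- E / rs_sum
      cnt <- matrix(0, 4, L)
      for (s in seq_len(nw)) {
        zp <- w * Z[, s]
        zm <- w * Z[, nw + s]
        for (j in seq_len(L)) {
          b <- M[, s + j - 1L]
          ok <- !is.na(b)
          if (any(ok)) {
            # plus strand: window offset j is motif position j; minus strand:
            # base maps to motif position L+1-j as its complement (rev of the
            # base-indexed tabulation)
            cnt[, j] <- cnt[, j] + .wtab4(b[ok], zp[ok])
            cnt[, L + 1L - j] <- cnt[, L + 1L - j] + rev(.wtab4(b[ok], zm[ok]))
          }
        }
      }
      theta_new <- cnt + 1e-8 * mean(w)
      theta_new <- sweep(theta_new, 2, colSums(theta_new), "/")
      if (ll < ll_old - 1e-8) monotone <- FALSE
      # gain per unit total weight, so convergence (and hence the fit) is
      # invariant under rescaling all weights
      if (it > 1 && (ll - ll_old) / sum(w) < tol) {
        theta <- theta_new
        break
      }
      ll_old <- ll
      theta <- theta_new
    }
    final <- pwm(sweep(cnt + pseudocount, 2, colSums(cnt + pseudocount), "/"),
                 pseudocount = pseudocount)
    cons <- iupac_consensus(final)
    if (is.null(best) || ll > best$ll + 1e-9 ||
        (abs(ll - best$ll) <= 1e-9 && cons < best$cons)) {
      best <- list(ll = ll, pwm = final, cons = cons, monotone = monotone)
    }
  }
  out <- .canonical_orientation(best$pwm)
  # report the objective of the matrix actually returned (the tracked EM
  # value lags one M-step behind)
  attr(out, "loglik") <- .oops_loglik(set, out, L)
  attr(out, "monotone") <- best$monotone
  out
}

# OOPS marginal weighted log-likelihood of a set under a given PWM
# (same scale as discover_pwm's "loglik" attribute: emissions as ratios to
# the uniform background, uniform window/strand prior)
.oops_loglik <- function(set, p, L = ncol(p)) {
  M <- dna_index_matrix(set$sequences)
  nw <- ncol(M) - L + 1L
  lth <- log(unclass(p)) - log(0.25)
  lth_rc <- log(unclass(p)[c(4, 3, 2, 1), L:1, drop = FALSE]) - log(0.25)
  S <- .window_scores(M, lth, lth_rc, L)
  mx <- apply(S, 1, max)
  sum(set$weights * (mx + log(rowSums(exp(S - mx))) - log(2 * nw)))
}

# weighted base tabulation: length-4 vector of sum of z by base code
.wtab4 <- function(b, z) {
  out <- numeric(4)
  agg <- rowsum(z, b)
  out[as.integer(rownames(agg))] <- agg
  out
}

# flip a PWM so its consensus shows CC before GG when applicable; if both
# orientations qualify (or neither), the lexicographically smaller consensus
# wins, so reverse-complement-equivalent fits canonicalize identically
.canonical_orientation <- function(p) {
  cons <- iupac_consensus(p)
  rc <- pwm_revcomp(p)
  cons_rc <- iupac_consensus(rc)
  ok <- function(cs) {
    i <- regexpr("CC", cs, fixed = TRUE)
    j <- regexpr("GG", cs, fixed = TRUE)
    i > 0 && j > 0 && i < j
  }
  use_rc <- if (ok(cons) != ok(cons_rc)) ok(cons_rc) else cons_rc < cons
  if (use_rc) {
    attr(rc, "orientation") <- "reverse_complemented"
    return(rc)
  }
  p
}

#' IUPAC consensus of a PWM
#'
#' Per column: the top base if its probability is at least 0.5 and at least
#' twice the runner-up; the two-letter IUPAC code if the top two sum to at
#' least 0.75; otherwise N.
#'
#' @param p a \code{\link{pwm}}.
#' @return IUPAC consensus string.
#' @export
iupac_consensus <- function(p) {
  m <- unclass(p)
  paste(vapply(seq_len(ncol(m)), function(j) {
    o <- order(m[, j], decreasing = TRUE)
    p1 <- m[o[1], j]; p2 <- m[o[2], j]
    if (p1 >= 0.5 && p1 >= 2 * p2) {
      DNA_BASES[o[1]]
    } else if (p1 + p2 >= 0.75) {
      iupac_code(DNA_BASES[o[1:2]])
    } else "N"
  }, character(1)), collapse = "")
}

#' Per-position PWM table with information content
#'
#' @param p a \code{\link{pwm}}.
#' @return data.frame: position, A, C, G, T, ic_bits.
#' @export
pwm_table <- function(p) {
  m <- t(unclass(p))
  ic <- 2 + rowSums(ifelse(m > 0, m * log2(m), 0))
  data.frame(position = seq_len(nrow(m)), m, ic_bits = ic)
}
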