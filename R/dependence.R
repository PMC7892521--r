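# the 15 set partitions of {1,2,3,4} as restricted-growth strings
.partitions4 <- local({
  out <- list()
  rec <- function(prefix) {
    if (length(prefix) == 4L) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (v in seq_len(max(prefix) + 1L)) rec(c(prefix, v))
  }
  rec(1L)
  out
})

.neff <- function(w) sum(w)^2 / sum(w^2)

# weighted (context, base) count matrix; ctx in 1..K, base in 1..4
.ctx_base_counts <- function(ctx, base, w, K) {
  cnt <- numeric(4L * K)
  idx <- (ctx - 1L) * 4L + base
  agg <- rowsum(w, idx)
  cnt[as.integer(rownames(agg))] <- agg
  matrix(cnt, nrow = K, ncol = 4, byrow = TRUE)
}

# weighted log-likelihood (nats) of base given context under smoothed
# conditionals derived from the same counts
.cond_loglik <- function(counts, alpha) {
  rs <- rowSums(counts)
  probs <- (counts + alpha) / (rs + 4 * alpha)
  if (alpha == 0) probs[rs == 0, ] <- 0.25  # unvisited contexts
  ll <- sum(ifelse(counts > 0, counts * log(pmax(probs, 1e-300)), 0))
  list(loglik = ll, probs = probs)
}

#' Fit an intra-motif dependence model
#'
#' Models each motif position's nucleotide distribution conditional on a set
#' of preceding positions (an acyclic left-to-right factorization).
#' \code{proximal} models fix the parents to the \code{d} immediately
#' preceding positions (truncated at the left edge); \code{distal} models
#' search, for every position, over all parent subsets of preceding positions
#' of size at most \code{d}, maximizing the BIC-penalized weighted
#' log-likelihood (\code{logL - free_params/2 * log(Neff)};
#' \code{penalty = "none"} uses the unpenalized likelihood, in which case the
#' search picks the largest-likelihood subset). Conditionals are
#' pseudocount-smoothed weighted ML estimates. Optional context-tree merging
#' chooses, per parent level, among the 15 set partitions of {A,C,G,T} by
#' dynamic programming under BIC, pooling contexts that behave alike.
#'
#' @param set a \code{\link{weighted_seqs}} of aligned, equal-length
#'   sequences; sequences containing N are dropped with a warning.
#' @param model_type "proximal" or "distal".
#' @param d model order: number of parents a position may have.
#' @param penalty "BIC" or "none".
#' @param alpha pseudocount for the conditional estimates (default 0.5).
#' @param merge_contexts apply context-tree merging (default FALSE).
#' @return an object of class \code{dependence_model}: per-position parents,
#'   context maps and conditional tables, plus the fitted weighted
#'   log-likelihood (nats) and effective sample size.
#' @export
fit_dependence <- function(set, model_type = c("proximal", "distal"), d = 1,
                           penalty = c("BIC", "none"), alpha = 0.5,
                           merge_contexts = FALSE) {
  model_type <- match.arg(model_type)
  penalty <- match.arg(penalty)
  hasN <- grepl("N", set$sequences, fixed = TRUE)
  if (any(hasN)) {
    warning(sprintf("dropping %d sequences containing N", sum(hasN)))
    set <- weighted_seqs(set$sequences[!hasN], set$weights[!hasN])
  }
  M <- dna_index_matrix(set$sequences)
  L <- ncol(M)
  if (L < 2) stop("aligned sequences must be at least 2 positions long")
  w <- set$weights
  neff <- .neff(w)
  use_pen <- penalty == "BIC"
  positions <- vector("list", L)
  total_ll <- 0
  for (j in seq_len(L)) {
    if (model_type == "proximal") {
      cand <- list(seq.int(max(1L, j - d), length.out = min(d, j - 1L)))
      if (j == 1L) cand <- list(integer(0))
    } else {
      cand <- list(integer(0))
      pre <- seq_len(j - 1L)
      for (size in seq_len(min(d, j - 1L))) {
        combs <- utils::combn(pre, size, simplify = FALSE)
        cand <- c(cand, combs)
      }
    }
    best <- NULL
    for (S in cand) {
      fitS <- .fit_position(M, w, j, S, alpha, use_pen, neff, merge_contexts)
      if (is.null(best) || fitS$score > best$score + 1e-9) best <- fitS
    }
    positions[[j]] <- best
    total_ll <- total_ll + best$loglik
  }
  structure(list(model_type = model_type, order = as.integer(d),
                 penalty = penalty, alpha = alpha,
                 merge_contexts = merge_contexts,
                 positions = positions, length = L,
                 loglik = total_ll, neff = neff),
            class = "dependence_model")
}

# fit one position given a parent set; returns parents, context_map (full
# context code -> conditional row), probs, loglik and the model-choice score
.fit_position <- function(M, w, j, S, alpha, use_pen, neff, merge_contexts) {
  K <- 4^length(S)
  ctx <- .ctx_code(M[, S, drop = FALSE])
  counts <- .ctx_base_counts(ctx, M[, j], w, K)
  if (merge_contexts && length(S) > 0) {
    merged <- .merge_context_tree(M, w, j, S, alpha, neff)
    return(c(list(parents = S), merged))
  }
  cl <- .cond_loglik(counts, alpha)
  free <- 3 * K
  score <- cl$loglik - if (use_pen) free / 2 * log(neff) else 0
  list(parents = S, context_map = seq_len(K), probs = cl$probs,
       loglik = cl$loglik, score = score, free = free)
}

# context-tree merging by DP over the 15 partitions of {A,C,G,T} per level;
# parents are split in order, each node may pool parent symbols into blocks
.merge_context_tree <- function(M, w, j, S, alpha, neff) {
  dpth <- length(S)
  pen <- log(neff) / 2
  build <- function(level, filt) {
    if (level > dpth) {
      counts <- matrix(vapply(1:4, function(b) sum(w[filt & M[, j] == b]),
                              numeric(1)), nrow = 1)
      cl <- .cond_loglik(counts, alpha)
      return(list(score = cl$loglik - 3 * pen,
                  leaves = list(list(levels = list(), probs = cl$probs[1, ],
                                     loglik = cl$loglik))))
    }
    parent <- S[level]
    best <- NULL
    for (part in .partitions4) {
      blocks <- split(1:4, part)
      total <- 0
      leaves <- list()
      for (blk in blocks) {
        sub <- filt & (M[, parent] %in% blk)
        res <- build(level + 1L, sub)
        total <- total + res$score
        for (lf in res$leaves) {
          lf$levels <- c(list(blk), lf$levels)
          leaves[[length(leaves) + 1L]] <- lf
        }
      }
      if (is.null(best) || total > best$score + 1e-9) {
        best <- list(score = total, leaves = leaves)
      }
    }
    best
  }
  res <- build(1L, rep(TRUE, nrow(M)))
  # materialize: map each full context code to its leaf
  K <- 4^dpth
  context_map <- integer(K)
  probs <- matrix(0, length(res$leaves), 4)
  ll <- 0
  full <- as.matrix(expand.grid(rev(replicate(dpth, 1:4, simplify = FALSE))))
  full <- full[, rev(seq_len(dpth)), drop = FALSE]  # columns follow S order
  codes <- .ctx_code(full)
  for (li in seq_along(res$leaves)) {
    lf <- res$leaves[[li]]
    probs[li, ] <- lf$probs
    ll <- ll + lf$loglik
    inblk <- rep(TRUE, nrow(full))
    for (lev in seq_len(dpth)) {
      inblk <- inblk & (full[, lev] %in% lf$levels[[lev]])
    }
    context_map[codes[inblk]] <- li
  }
  list(context_map = context_map, probs = probs, loglik = ll,
       score = res$score, free = 3 * length(res$leaves))
}

#' @export
print.dependence_model <- function(x, ...) {
  cat(sprintf("%s dependence model, order %d (%s penalty)\n",
              x$model_type, x$order, x$penalty))
  for (j in seq_len(x$length)) {
    pj <- x$positions[[j]]$parents
    cat(sprintf("  position %2d <- {%s}\n", j,
                paste(pj, collapse = ",")))
  }
  invisible(x)
}

#' Per-sequence log2-likelihood under a dependence model
#'
#' @param model a \code{\link{dependence_model}}.
#' @param set a \code{\link{weighted_seqs}} of matching length (N-free).
#' @return numeric vector of log2 probabilities, one per sequence.
#' @export
loglik2_dependence <- function(model, set) {
  M <- dna_index_matrix(set$sequences)
  if (ncol(M) != model$length) stop("sequence length does not match the model")
  if (anyNA(M)) stop("sequences must be N-free for likelihood evaluation")
  ll <- numeric(nrow(M))
  for (j in seq_len(model$length)) {
    pos <- model$positions[[j]]
    ctx <- .ctx_code(M[, pos$parents, drop = FALSE])
    row <- pos$context_map[ctx]
    p <- pos$probs[cbind(row, M[, j])]
    ll <- ll + log2(pmax(p, 1e-300))
  }
  ll
}

#' Intra-motif complexity (IMC)
#'
#' The weighted mean per-sequence log2-likelihood gain of a dependence model
#' over the mononucleotide (PWM) model fitted on the same data with the same
#' smoothing — the amount of statistical dependence, in bits, that the model
#' representation captures beyond independent columns. The PWM model itself
#' has IMC 0 by definition, and with unpenalized ML fits IMC is non-negative
#' and non-decreasing along nested model families.
#'
#' @param model a \code{\link{dependence_model}} fitted on \code{set}.
#' @param set the \code{\link{weighted_seqs}} the model was fitted on.
#' @return IMC in bits.
#' @export
imc <- function(model, set) {
  hasN <- grepl("N", set$sequences, fixed = TRUE)
  if (any(hasN)) set <- weighted_seqs(set$sequences[!hasN],
                                      set$weights[!hasN])
  base <- fit_dependence(set, model_type = "proximal", d = 0,
                         penalty = model$penalty, alpha = model$alpha)
  llm <- loglik2_dependence(model, set)
  llb <- loglik2_dependence(base, set)
  w <- set$weights
  sum(w * (llm - llb)) / sum(w)
}
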