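.entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

.jsd_column <- function(p, q) {
  .entropy2((p + q) / 2) - (.entropy2(p) + .entropy2(q)) / 2
}

#' Jensen-Shannon divergence between two PWMs
#'
#' Per position, \code{JSD_j = H((p_j + q_j)/2) - (H(p_j) + H(q_j))/2} with
#' log base 2 (so each position lies in [0, 1] bits); the aggregate is the
#' sum (default) or mean over positions. Because the discovery strand is
#' arbitrary, the reverse complement of \code{q} is also evaluated by default
#' and the orientation minimizing the aggregate is reported.
#'
#' @param p,q \code{\link{pwm}}s of equal length.
#' @param aggregate "sum" or "mean".
#' @param try_revcomp also evaluate \code{q} reverse-complemented.
#' @return list with \code{divergence} (aggregate), \code{per_position}
#'   (numeric vector, bits), \code{orientation} ("as_given" or
#'   "reverse_complement") and \code{aggregate}.
#' @export
pwm_jsd <- function(p, q, aggregate = c("sum", "mean"), try_revcomp = TRUE) {
  aggregate <- match.arg(aggregate)
  if (ncol(p) != ncol(q)) stop("PWMs must have equal lengths")
  per_pos <- function(a, b) {
    vapply(seq_len(ncol(a)), function(j) .jsd_column(a[, j], b[, j]),
           numeric(1))
  }
  agg <- function(v) if (aggregate == "sum") sum(v) else mean(v)
  v1 <- per_pos(unclass(p), unclass(q))
  best <- list(divergence = agg(v1), per_position = v1,
               orientation = "as_given", aggregate = aggregate)
  if (try_revcomp) {
    v2 <- per_pos(unclass(p), unclass(pwm_revcomp(q)))
    if (agg(v2) < best$divergence) {
      best <- list(divergence = agg(v2), per_position = v2,
                   orientation = "reverse_complement", aggregate = aggregate)
    }
  }
  best
}

#' Numeric difference-logo table between two PWMs
#'
#' Per position, the stack height is the Jensen-Shannon divergence of the two
#' columns (bits), and each letter gets the signed height
#' \code{JSD_j * (p_j(a) - q_j(a)) / sum_b |p_j(b) - q_j(b)|} (positive =
#' enriched in \code{p}); identical columns give zero heights.
#'
#' @param p,q \code{\link{pwm}}s of equal length, orientation already
#'   resolved.
#' @param aggregate "sum" or "mean" for the aggregate divergence.
#' @return an object of class \code{difference_logo}: list with
#'   \code{per_position} (bits), \code{heights} (4 x L signed matrix),
#'   \code{divergence} and \code{aggregate}.
#' @export
difference_logo <- function(p, q, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  if (ncol(p) != ncol(q)) stop("PWMs must have equal lengths")
  P <- unclass(p); Q <- unclass(q)
  L <- ncol(P)
  jsd <- vapply(seq_len(L), function(j) .jsd_column(P[, j], Q[, j]),
                numeric(1))
  heights <- matrix(0, 4, L, dimnames = list(DNA_BASES, NULL))
  for (j in seq_len(L)) {
    dif <- P[, j] - Q[, j]
    tot <- sum(abs(dif))
    if (tot > 0) heights[, j] <- jsd[j] * dif / tot
  }
  structure(list(per_position = jsd, heights = heights,
                 divergence = if (aggregate == "sum") sum(jsd) else mean(jsd),
                 aggregate = aggregate),
            class = "difference_logo")
}

#' @export
print.difference_logo <- function(x, ...) {
  cat(sprintf("Difference logo: aggregate JSD (%s) = %.4f bits\n",
              x$aggregate, x$divergence))
  print(round(rbind(x$heights, jsd = x$per_position), 4))
  invisible(x)
}

#' Pairwise Jensen-Shannon divergence matrix
#'
#' @param pwms named list of \code{\link{pwm}}s of one length.
#' @param ... passed to \code{\link{pwm_jsd}}.
#' @return symmetric numeric matrix of aggregate divergences.
#' @export
jsd_matrix <- function(pwms, ...) {
  n <- length(pwms)
  out <- matrix(0, n, n, dimnames = list(names(pwms), names(pwms)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) {
        out[i, j] <- out[j, i] <- pwm_jsd(pwms[[i]], pwms[[j]], ...)$divergence
      }
    }
  }
  out
}
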