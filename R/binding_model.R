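#' Planted binding model for the SELEX simulator
#'
#' A dimer-binding energy model over a fixed-width core (default 10 nt, the
#' CArG-box width): per-position base energies (dimensionless; lower =
#' tighter), optional flanking-base bonuses just outside the core, an
#' inverse-temperature scaling \code{beta} and a strictly positive
#' nonspecific baseline weight so every probe has positive selection weight.
#' Scoring always sums Boltzmann factors over all windows on both strands,
#' so probe weights are strand symmetric by construction.
#'
#' @param core_energy 4 x L numeric matrix of energies, rows A, C, G, T.
#' @param flank_bonus 4 x n numeric matrix of log-scale bonuses with column
#'   names giving core-relative offsets ("-2", "-1" upstream of the core
#'   start; "1", "2" downstream of the core end), rows A, C, G, T; or NULL.
#' @param beta inverse-temperature scaling (> 0).
#' @param nonspecific baseline weight epsilon (> 0) added to every probe.
#' @param boundary_ct optional energy for position 2 of the window whose
#'   first two bases are the 5' adapter's terminal CT (plus strand only):
#'   models the observation that the adapter's CT can serve as the 5' border
#'   of a binding site, which is what creates the position-bias artifact of
#'   incomplete CArG-boxes near the read start. NULL disables the effect.
#' @return an object of class \code{binding_model}.
#' @export
binding_model <- function(core_energy, flank_bonus = NULL, beta = 1,
                          nonspecific = 0.05, boundary_ct = NULL) {
  stopifnot(is.matrix(core_energy), nrow(core_energy) == 4,
            beta >= 0, nonspecific > 0)
  rownames(core_energy) <- DNA_BASES
  if (!is.null(flank_bonus)) {
    stopifnot(is.matrix(flank_bonus), nrow(flank_bonus) == 4,
              !is.null(colnames(flank_bonus)))
    rownames(flank_bonus) <- DNA_BASES
  }
  structure(list(core_energy = core_energy, flank_bonus = flank_bonus,
                 beta = beta, nonspecific = nonspecific,
                 boundary_ct = boundary_ct),
            class = "binding_model")
}

#' Preset binding models
#'
#' \describe{
#'   \item{wt}{SRF-type CArG-box with a W-tolerant, A-tract-preferring center
#'     (minimum-energy sequence CCAAAAATGG, tolerant at positions 3-8) and
#'     flank bonuses for T at offsets -2/-1 and A at +1/+2 (the TTN-/-NAA
#'     flank preference).}
#'   \item{mutant}{shorter A/T core with C/G-tolerant borders
#'     (CCSAAAASGG-like), emulating the R3 mutant binding mode.}
#'   \item{single_target}{one sharply preferred 10-mer (CCAAAATTGG) with a
#'     tiny nonspecific baseline; used for stringent-selection checks.}
#' }
#'
#' @param name one of "wt", "mutant", "single_target".
#' @return a \code{\link{binding_model}}.
#' @export
binding_model_preset <- function(name = c("wt", "mutant", "single_target")) {
  name <- match.arg(name)
  E <- function(...) {
    m <- cbind(...)
    rownames(m) <- DNA_BASES
    m
  }
  if (name == "wt") {
    core <- E(
      c(3.0, 0.0, 3.0, 3.0),   # 1: C
      c(3.0, 0.0, 3.0, 3.0),   # 2: C
      c(0.0, 0.3, 0.3, 0.15),  # 3: N-tolerant, A preferred
      c(0.0, 2.2, 2.2, 0.30),  # 4: W
      c(0.0, 2.2, 2.2, 1.6),   # 5: A (lone mid-T = no A-tract: expensive)
      c(0.0, 2.2, 2.2, 1.6),   # 6: A (same)
      c(0.0, 2.2, 2.2, 0.35),  # 7: A
      c(0.35, 2.2, 2.2, 0.0),  # 8: T
      c(3.0, 3.0, 0.0, 3.0),   # 9: G
      c(3.0, 3.0, 0.0, 3.0)    # 10: G
    )
    fb <- matrix(0, 4, 4, dimnames = list(DNA_BASES, c("-2", "-1", "1", "2")))
    fb["T", c("-2", "-1")] <- 0.3
    fb["A", c("1", "2")] <- 0.3
    binding_model(core, fb, beta = 1, nonspecific = 0.05, boundary_ct = 0.6)
  } else if (name == "mutant") {
    core <- E(
      c(3.0, 0.0, 3.0, 3.0),   # 1: C
      c(3.0, 0.0, 3.0, 2.0),   # 2: C
      c(0.8, 0.0, 0.0, 1.5),   # 3: S
      c(0.0, 2.5, 2.5, 0.8),   # 4: A
      c(0.0, 2.5, 2.5, 0.8),   # 5: A
      c(0.0, 2.5, 2.5, 0.8),   # 6: A
      c(0.0, 2.5, 2.5, 0.8),   # 7: A
      c(0.8, 0.0, 0.0, 1.5),   # 8: S
      c(3.0, 3.0, 0.0, 3.0),   # 9: G
      c(3.0, 3.0, 0.0, 3.0)    # 10: G
    )
    fb <- matrix(0, 4, 4, dimnames = list(DNA_BASES, c("-2", "-1", "1", "2")))
    fb["T", c("-2", "-1")] <- 0.15
    fb["A", c("1", "2")] <- 0.15
    binding_model(core, fb, beta = 1, nonspecific = 0.05)
  } else {
    target <- "CCAAAATTGG"
    core <- matrix(6, 4, 10, dimnames = list(DNA_BASES, NULL))
    b <- strsplit(target, "")[[1]]
    for (j in seq_along(b)) core[b[j], j] <- 0
    binding_model(core, NULL, beta = 2, nonspecific = 1e-4)
  }
}

# complement-permuted energy/bonus matrices for minus-strand scanning
.revcomp_energy <- function(E) {
  out <- E[c(4, 3, 2, 1), ncol(E):1, drop = FALSE]
  rownames(out) <- DNA_BASES
  out
}

#' Selection weight of probes under a binding model
#'
#' The weight of a probe is \code{epsilon + sum over all full core-width
#' windows on both strands of exp(-beta * E(window) + flank bonuses)}.
#' When a \code{design} is supplied, scanning context includes the tail of
#' the 5' adapter (which ends in CT) and the head of barcode + 3' adapter,
#' so binding that straddles the constant parts of the probe — the source of
#' the position-bias artifact — is reproduced. Windows that would extend
#' past the available context are skipped; flank-bonus terms falling outside
#' the context are dropped.
#'
#' @param model a \code{\link{binding_model}}.
#' @param sequences character vector of variable regions (no N).
#' @param design optional \code{\link{probe_design}} providing adapter
#'   context; NULL scores the bare sequences.
#' @param barcode barcode used for the 3' context when \code{design} is given.
#' @return numeric vector of strictly positive weights.
#' @export
probe_weight <- function(model, sequences, design = NULL, barcode = "ACTG") {
  check_dna(sequences, allow_n = FALSE, what = "probe")
  k <- ncol(model$core_energy)
  fb <- model$flank_bonus
  max_fl <- if (is.null(fb)) 0L else max(abs(as.integer(colnames(fb))))
  if (!is.null(design)) {
    ctx <- k - 1L + max_fl
    pre <- substr(design$adapter5,
                  max(1L, nchar(design$adapter5) - ctx + 1L),
                  nchar(design$adapter5))
    post_src <- paste0(barcode, design$adapter3)
    post <- substr(post_src, 1L, min(ctx, nchar(post_src)))
    full <- paste0(pre, sequences, post)
    n_pre <- nchar(pre)
  } else {
    full <- sequences
    n_pre <- 0L
  }
  M <- dna_index_matrix(full)
  n <- nrow(M); L <- ncol(M)
  if (L < k) return(rep(model$nonspecific, n))
  Ep <- model$core_energy
  Em <- .revcomp_energy(Ep)
  offs <- if (is.null(fb)) integer(0) else as.integer(colnames(fb))
  # plus-strand window whose first two bases are the adapter's terminal CT
  ct_window <- if (!is.null(design) && !is.null(model$boundary_ct) &&
                   n_pre >= 2L) n_pre - 1L else 0L
  w <- rep(model$nonspecific, n)
  for (s in seq_len(L - k + 1L)) {
    ep <- numeric(n); em <- numeric(n)
    for (j in seq_len(k)) {
      b <- M[, s + j - 1L]          # linear index into 4 x k matrices
      ep <- ep + Ep[b + (j - 1L) * 4L]
      em <- em + Em[b + (j - 1L) * 4L]
    }
    if (s == ct_window) {
      # the adapter CT serves as the 5' window border at a reduced cost
      ep <- ep - Ep["T", 2L] + model$boundary_ct
    }
    bp <- numeric(n); bm <- numeric(n)
    for (ii in seq_along(offs)) {
      o <- offs[ii]
      pos_p <- if (o < 0) s + o else s + k - 1L + o
      if (pos_p >= 1L && pos_p <= L) {
        bp <- bp + fb[M[, pos_p] + (ii - 1L) * 4L]
      }
      # minus strand: its offset o sits at the mirrored plus position,
      # read as the complemented base
      pos_m <- if (o < 0) s + k - 1L - o else s - o
      if (pos_m >= 1L && pos_m <= L) {
        bm <- bm + fb[(5L - M[, pos_m]) + (ii - 1L) * 4L]
      }
    }
    w <- w + exp(-model$beta * ep + bp) + exp(-model$beta * em + bm)
  }
  unname(w)
}

#' Planted relative affinity of k-mers under a binding model
#'
#' The analytically predictable target of the (obs/exp)^(1/r) affinity
#' estimator under the Boltzmann-sum occupancy model. A read containing
#' k-mer w is selected over r rounds with probability proportional to
#' weight^r, so the estimator converges to \code{E[weight^r | contains
#' w]^(1/r)}, where the expectation runs over the random context around w.
#' This is computed analytically: the log-weight contribution of every
#' core-width window overlapping w (both strands, flank bonuses included)
#' factorizes over positions, with positions covered by w fixed and the
#' rest averaged over the background base distribution; for r = 2 the second
#' moment sums these factors over all ordered window pairs. The round-aware
#' target matters because "hitchhiking" k-mers — k-mers that overlap a
#' strong site without being one — have skewed conditional weight
#' distributions, so their means and root-mean-squares differ substantially.
#' Values are normalized so the strongest queried k-mer scores 1.
#'
#' @param model a \code{\link{binding_model}}.
#' @param kmers character vector of k-mers (one common length >= 1).
#' @param r selection round of the estimator being predicted (1 or 2).
#' @param design optional \code{\link{probe_design}}: when given, the
#'   expectation is additionally marginalized over the k-mer's placement in
#'   the read, with the constant adapter tail / barcode letters fixed at the
#'   read edges — this is what makes partial sites assisted by the
#'   adapter's terminal CT predictable.
#' @param barcode barcode for the 3' context when \code{design} is given.
#' @param read_len read length used for placement marginalization.
#' @param include_nonspecific add the nonspecific baseline before
#'   normalizing (default TRUE; it is the floor the estimator sees).
#' @param base_probs background base probabilities for uncovered positions.
#' @return named numeric vector of planted affinities in (0, 1].
#' @export
planted_affinity <- function(model, kmers, r = 2, design = NULL,
                             barcode = "ACTG", read_len = 25,
                             include_nonspecific = TRUE,
                             base_probs = rep(0.25, 4)) {
  if (!r %in% c(1, 2)) stop("r must be 1 or 2")
  k <- ncol(model$core_energy)
  kw <- nchar(kmers[1])
  if (any(nchar(kmers) != kw)) stop("k-mers must have one common length")
  M <- dna_index_matrix(kmers)
  n <- nrow(M)
  fb <- model$flank_bonus
  offs <- if (is.null(fb)) integer(0) else as.integer(colnames(fb))
  fbp <- if (is.null(fb)) matrix(0, 4, 0) else fb
  # minus strand: the bonus at minus-offset o sits at plus-offset -o with
  # the complemented base
  fbm_minus <- fbp
  for (ii in seq_along(offs)) {
    src <- which(offs == -offs[ii])
    fbm_minus[, ii] <- if (length(src)) fb[c(4, 3, 2, 1), src] else 0
  }
  Etab <- list(model$core_energy, .revcomp_energy(model$core_energy))
  Btab <- list(fbp, fbm_minus)
  max_fl <- if (length(offs)) max(abs(offs)) else 0L
  eps <- if (include_nonspecific) model$nonspecific else 0
  # mean Boltzmann mass of one fully random window position (both strands)
  bbar <- sum(vapply(1:2, function(strand) {
    f <- prod(vapply(seq_len(k), function(j)
      sum(base_probs * exp(-model$beta * Etab[[strand]][, j])), numeric(1)))
    if (length(offs)) {
      f <- f * prod(vapply(seq_along(offs), function(ii)
        sum(base_probs * exp(Btab[[strand]][, ii])), numeric(1)))
    }
    f
  }, numeric(1)))

  # log-weight contribution matrices of windows overlapping the k-mer
  # (coordinates relative to the k-mer start; position 1..kw = the k-mer)
  span <- (1 - k - max_fl):(kw + k - 1 + max_fl)
  build_aligns <- function(starts) {
    out <- list()
    for (strand in 1:2) {
      for (s in starts) {
        G <- matrix(0, 4, length(span))
        for (j in seq_len(k)) {
          ci <- s + j - 1L - span[1] + 1L
          G[, ci] <- G[, ci] - model$beta * Etab[[strand]][, j]
        }
        for (ii in seq_along(offs)) {
          o <- offs[ii]
          p <- if (o < 0) s + o else s + k - 1L + o
          ci <- p - span[1] + 1L
          if (ci >= 1 && ci <= length(span)) {
            G[, ci] <- G[, ci] + Btab[[strand]][, ii]
          }
        }
        out[[length(out) + 1L]] <- G
      }
    }
    out
  }
  # E[ prod_p exp(G(p, b_p)) ]: b fixed by the k-mer inside it, fixed by
  # ctx_fix where the probe is constant, background-averaged elsewhere
  expect_factor <- function(G, ctx_fix) {
    active <- which(colSums(G != 0) > 0)
    fac <- rep(1, n)
    for (ci in active) {
      p <- span[ci]
      eg <- exp(G[, ci])
      fix <- ctx_fix[as.character(p)]
      if (p >= 1 && p <= kw) {
        fac <- fac * eg[M[, p]]
      } else if (!is.na(fix)) {
        fac <- fac * eg[fix]
      } else {
        fac <- fac * sum(base_probs * eg)
      }
    }
    fac
  }
  moment <- function(starts, ctx_fix, n_far) {
    eps_u <- eps + n_far * bbar
    if (!length(starts)) {
      return(if (r == 1) rep(eps_u, n) else rep(eps_u^2, n))
    }
    aligns <- build_aligns(starts)
    m1 <- Reduce(`+`, lapply(aligns, expect_factor, ctx_fix = ctx_fix))
    if (r == 1) {
      eps_u + m1
    } else {
      m2 <- numeric(n)
      for (a in seq_along(aligns)) {
        for (b2 in seq_along(aligns)) {
          m2 <- m2 + expect_factor(aligns[[a]] + aligns[[b2]], ctx_fix)
        }
      }
      eps_u^2 + 2 * eps_u * m1 + m2
    }
  }
  no_ctx <- setNames(rep(NA_integer_, length(span)), as.character(span))

  if (is.null(design)) {
    v <- moment((1 - k + 1):kw, no_ctx, 0)
    val <- if (r == 1) v else sqrt(v)
    return(setNames(val / max(val), kmers))
  }
  # placement-marginalized with fixed adapter/barcode letters at the edges
  ctx_w <- k - 1L + max_fl
  pre <- substr(design$adapter5,
                max(1L, nchar(design$adapter5) - ctx_w + 1L),
                nchar(design$adapter5))
  post <- substr(paste0(barcode, design$adapter3), 1L, ctx_w)
  pre_code <- match(strsplit(pre, "")[[1]], DNA_BASES)
  post_code <- match(strsplit(post, "")[[1]], DNA_BASES)
  n_place <- read_len - kw + 1L
  acc <- numeric(n)
  for (u in seq_len(n_place)) {
    # in k-mer coordinates the read spans (2-u)..(read_len-u+1); the
    # scannable probe context extends past it by the adapter/barcode tails
    lo <- (2 - u) - length(pre_code)
    hi <- (read_len - u + 1) + length(post_code)
    ctx_fix <- no_ctx
    pre_pos <- as.character(lo:(lo + length(pre_code) - 1))
    post_pos <- as.character((hi - length(post_code) + 1):hi)
    ctx_fix[intersect(pre_pos, names(ctx_fix))] <-
      pre_code[pre_pos %in% names(ctx_fix)]
    ctx_fix[intersect(post_pos, names(ctx_fix))] <-
      post_code[post_pos %in% names(ctx_fix)]
    starts <- ((1 - k + 1):kw)
    starts <- starts[starts >= lo & starts + k - 1 <= hi]
    n_all <- hi - lo + 1 - k + 1
    n_far <- max(0, n_all - length(starts))
    acc <- acc + moment(starts, ctx_fix, n_far)
  }
  v <- acc / n_place
  val <- if (r == 1) v else sqrt(v)
  setNames(val / max(val), kmers)
}
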