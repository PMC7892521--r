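test_that("training-set construction follows the cutoff/padding/weight rules", {
  tab <- data.frame(kmer = c("CCAAAAATGG", "ACGTACGTAC"),
                    count = c(100L, 50L), expected = c(1, 1),
                    raw = c(2, 0.78), affinity = c(1.0, 0.39),
                    low_confidence = FALSE)
  aff <- structure(list(k = 10L, round = 2L, provenance = "R2",
                        merge_revcomp = TRUE, table = tab),
                   class = "affinity_table")
  ts <- build_training_set(aff)
  expect_equal(ts$sequences, paste0(strrep("N", 5), "CCAAAAATGG",
                                    strrep("N", 5)))
  expect_equal(nchar(ts$sequences), 20L)
  expect_equal(ts$weights, 1000)
  aff$table$affinity <- c(0.4, 0.39)
  expect_error(build_training_set(aff), "cutoff")
})

test_that("the training set of a WT run has the expected working size", {
  run <- wt_run()
  ts <- build_training_set(run$aff2)
  expect_gte(length(ts$sequences), 50)
  expect_lte(length(ts$sequences), 200)
})

test_that("EM recovers a planted site from unambiguous training data", {
  set <- weighted_seqs(rep("NNNNNCCAAAATTGGNNNNN", 20))
  p <- discover_pwm(set, L = 10, restarts = 10, seed = 2)
  expect_equal(iupac_consensus(p), "CCAAAATTGG")
  expect_true(attr(p, "monotone"))
  # reverse-complementing every sequence gives the identical canonical PWM
  set_rc <- weighted_seqs(revcomp(set$sequences))
  p_rc <- discover_pwm(set_rc, L = 10, restarts = 10, seed = 2)
  expect_lt(max(abs(unclass(p_rc) - unclass(p))), 1e-9)
})

test_that("EM likelihood dominates every hard window/strand assignment", {
  set.seed(7)
  seqs <- c("ACGTAC", "CCAATT", "TTGGCA", "CACGTG")
  set <- weighted_seqs(seqs, weights = runif(4, 0.5, 2))
  L <- 4
  best_em <- attr(discover_pwm(set, L = L, restarts = 50, seed = 5,
                               pseudocount = 1e-9, tol = 1e-9,
                               max_iter = 2000), "loglik")
  nw <- nchar(seqs[1]) - L + 1
  # enumerate all (window, strand) hard assignments, fit the ML PWM of the
  # assigned sites, evaluate the OOPS marginal likelihood at that PWM
  choices <- expand.grid(rep(list(seq_len(2 * nw)), length(seqs)))
  site_of <- function(seq, a) {
    s <- if (a <= nw) substr(seq, a, a + L - 1) else
      revcomp(substr(seq, a - nw, a - nw + L - 1))
    s
  }
  best_hard <- -Inf
  for (i in seq_len(nrow(choices))) {
    sites <- mapply(site_of, seqs, as.integer(choices[i, ]))
    cnt <- matrix(1e-9, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (si in seq_along(sites)) {
      b <- strsplit(sites[si], "")[[1]]
      for (j in seq_len(L)) {
        cnt[b[j], j] <- cnt[b[j], j] + set$weights[si]
      }
    }
    theta <- pwm(sweep(cnt, 2, colSums(cnt), "/"))
    ll <- cargselex:::.oops_loglik(set, theta)
    if (ll > best_hard) best_hard <- ll
  }
  expect_gte(best_em + 1e-6, best_hard)
})

test_that("PWM discovery is deterministic under a seed and weight scaling", {
  run <- wt_run()
  ts <- build_training_set(run$aff2)
  p1 <- discover_pwm(ts, restarts = 8, seed = 4)
  p2 <- discover_pwm(ts, restarts = 8, seed = 4)
  expect_identical(unclass(p1), unclass(p2))
  # weights are upscaled affinities (~10^3); doubling them leaves the fit
  # unchanged up to the fixed final pseudocount
  ts2 <- weighted_seqs(ts$sequences, 2 * ts$weights)
  p3 <- discover_pwm(ts2, restarts = 8, seed = 4)
  expect_lt(max(abs(unclass(p3) - unclass(p1))), 1e-3)
})

test_that("the WT-preset consensus matches CCNWAAATGG at >= 8 of 10 positions", {
  run <- wt_run()
  ts <- build_training_set(run$aff2)
  p <- discover_pwm(ts, L = 10, restarts = 40, seed = 6)
  expect_gte(consensus_agreement(iupac_consensus(p), "CCNWAAATGG"), 8)
})

test_that("IUPAC consensus rules are applied per column", {
  mk <- function(a, c, g, t) matrix(c(a, c, g, t), 4)
  expect_equal(iupac_consensus(pwm(mk(0.25, 0.25, 0.25, 0.25))), "N")
  expect_equal(iupac_consensus(pwm(mk(0.45, 0.05, 0.05, 0.45))), "W")
  expect_equal(iupac_consensus(pwm(mk(0.05, 0.9, 0.03, 0.02))), "C")
  expect_equal(iupac_consensus(pwm(mk(0.45, 0.40, 0.10, 0.05))), "M")
  # p1 = 0.5 but p2 > p1/2: two-letter code, not a single base
  expect_equal(iupac_consensus(pwm(mk(0.5, 0.3, 0.1, 0.1))), "M")
})

test_that("degenerate training sets are rejected", {
  expect_error(discover_pwm(weighted_seqs(rep("NNNNNNNNNNNN", 3)), L = 10),
               "degenerate")
  expect_error(discover_pwm(weighted_seqs("ACGT"), L = 10), "shorter")
})
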