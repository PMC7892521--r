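# sample aligned sequences column-wise from per-position distributions
sample_cols <- function(n, probs, seed) {
  set.seed(seed)
  L <- length(probs)
  m <- vapply(probs, function(p)
    sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
    character(n))
  apply(m, 1, paste, collapse = "")
}

test_that("proximal models have adjacent-predecessor structure by definition", {
  seqs <- random_kmers(200, 6, seed = 7)
  m1 <- fit_dependence(weighted_seqs(seqs), "proximal", d = 1)
  expect_equal(lapply(m1$positions, `[[`, "parents"),
               list(integer(0), 1L, 2L, 3L, 4L, 5L))
  m2 <- fit_dependence(weighted_seqs(seqs), "proximal", d = 2)
  expect_equal(m2$positions[[4]]$parents, c(2L, 3L))
  expect_equal(m2$positions[[2]]$parents, 1L)
  expect_error(fit_dependence(weighted_seqs("A"), "proximal"), "at least 2")
})

test_that("BIC distal search returns independent columns as a PWM", {
  probs <- replicate(5, c(0.4, 0.3, 0.2, 0.1), simplify = FALSE)
  seqs <- sample_cols(1e4, probs, seed = 11)
  m <- fit_dependence(weighted_seqs(seqs), "distal", d = 2, penalty = "BIC")
  expect_true(all(lengths(lapply(m$positions, `[[`, "parents")) == 0))
})

test_that("a Watson-Crick-paired column is detected as a parent", {
  set.seed(13)
  b1 <- sample(c("A", "T"), 5000, replace = TRUE)
  b2 <- chartr("AT", "TA", b1)
  b3 <- sample(c("A", "C", "G", "T"), 5000, replace = TRUE)
  seqs <- paste0(b1, b2, b3)
  m <- fit_dependence(weighted_seqs(seqs), "distal", d = 1, penalty = "BIC")
  expect_equal(m$positions[[2]]$parents, 1L)
  # IMC approaches the 1 bit of mutual information carried by the pairing
  val <- imc(m, weighted_seqs(seqs))
  expect_gt(val, 0.9)
  expect_lt(val, 1.1)
})

test_that("the PWM model has IMC exactly zero on arbitrary data", {
  for (seed in c(3, 17)) {
    seqs <- random_kmers(100, 10, seed = seed)
    set <- weighted_seqs(seqs, weights = runif(100, 0.5, 2))
    base <- fit_dependence(set, "proximal", d = 0, penalty = "none")
    expect_identical(imc(base, set), 0)
  }
})

test_that("unpenalized IMC obeys the nestedness ordering", {
  run <- wt_run()
  fl <- flank_extract_orient(run$pools$R2, seed = 1)
  set <- weighted_seqs(fl$sequences, fl$weights)
  vals <- sapply(c("proximal", "distal"), function(mt)
    sapply(1:2, function(d) {
      imc(fit_dependence(set, mt, d = d, penalty = "none", alpha = 0), set)
    }))
  expect_gte(vals[1, "proximal"], 0)
  expect_gte(vals[2, "proximal"], vals[1, "proximal"])
  expect_gte(vals[1, "distal"], vals[1, "proximal"])
  expect_gte(vals[2, "distal"], vals[2, "proximal"])
  expect_gte(vals[2, "distal"], vals[1, "distal"])
})

test_that("IMC is invariant under weight rescaling", {
  seqs <- random_kmers(300, 8, seed = 19)
  w <- runif(300, 0.5, 3)
  s1 <- weighted_seqs(seqs, w)
  s2 <- weighted_seqs(seqs, 10 * w)
  m1 <- fit_dependence(s1, "proximal", d = 1, penalty = "none", alpha = 0)
  m2 <- fit_dependence(s2, "proximal", d = 1, penalty = "none", alpha = 0)
  expect_equal(imc(m1, s1), imc(m2, s2), tolerance = 1e-9)
})

test_that("data simulated from a PWM shows near-zero IMC everywhere", {
  probs <- list(c(.7, .1, .1, .1), c(.1, .7, .1, .1), c(.25, .25, .25, .25),
                c(.4, .1, .4, .1), c(.1, .4, .1, .4), c(.7, .1, .1, .1))
  seqs <- sample_cols(1e4, probs, seed = 23)
  set <- weighted_seqs(seqs)
  for (mt in c("proximal", "distal")) {
    for (d in 1:2) {
      m <- fit_dependence(set, mt, d = d, penalty = "none", alpha = 0)
      expect_lt(imc(m, set), 0.05)
    }
  }
})

test_that("context-tree merging pools equivalent parent symbols", {
  set.seed(29)
  # position 2 depends only on whether position 1 is a purine
  b1 <- sample(c("A", "C", "G", "T"), 4000, replace = TRUE)
  pur <- b1 %in% c("A", "G")
  b2 <- ifelse(pur, sample(c("A", "C"), 4000, TRUE, prob = c(.9, .1)),
               sample(c("G", "T"), 4000, TRUE, prob = c(.9, .1)))
  set <- weighted_seqs(paste0(b1, b2))
  m <- fit_dependence(set, "proximal", d = 1, penalty = "BIC",
                      merge_contexts = TRUE)
  pos2 <- m$positions[[2]]
  # A and G share a conditional row, C and T share the other
  expect_equal(pos2$context_map[1], pos2$context_map[3])
  expect_equal(pos2$context_map[2], pos2$context_map[4])
  expect_lte(length(unique(pos2$context_map)), 2)
  # evaluation through the merged tree stays consistent
  expect_gte(imc(m, set), 0)
})

test_that("sequences containing N are dropped with a warning", {
  set <- weighted_seqs(c("ACGT", "ACNT", "GGTT"))
  expect_warning(m <- fit_dependence(set, "proximal", d = 1), "dropping 1")
  expect_equal(m$neff, 2)
})
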