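test_that("R0 base composition matches the configured multinomial", {
  cfg <- sim_config(n_reads = 1e5, n_rounds = 0, seed = 7)
  r0 <- simulate_r0(cfg, probe_design())
  tab <- table(strsplit(paste(r0$sequences[1:20000], collapse = ""), "")[[1]])
  freq <- tab / sum(tab)
  expect_true(all(abs(freq - 0.25) < 0.01))
  expect_equal(nchar(r0$sequences[1]), 25L)
})

test_that("degenerate composition and seeding behave as declared", {
  cfg <- sim_config(n_reads = 50, n_rounds = 0,
                    base_composition = c(1, 0, 0, 0), seed = 3)
  r0 <- simulate_r0(cfg)
  expect_true(all(r0$sequences == strrep("A", 25)))
  cfg2 <- sim_config(n_reads = 100, n_rounds = 1, seed = 42)
  a <- simulate_selex(cfg2)
  b <- simulate_selex(cfg2)
  expect_identical(lapply(a, `[[`, "sequences"), lapply(b, `[[`, "sequences"))
})

test_that("probe weight is analytic at beta = 0 and rewards the consensus", {
  m <- binding_model_preset("wt")
  m0 <- binding_model(m$core_energy, NULL, beta = 0, nonspecific = 0.05)
  seqs <- random_kmers(20, 25, seed = 13)
  w <- probe_weight(m0, seqs)
  # 16 windows x 2 strands, each contributing exp(0) = 1
  expect_equal(w, rep(0.05 + 32, 20))
  planted <- paste0(strrep("G", 7), "CCAAAAATGG", strrep("C", 8))
  expect_gt(probe_weight(m, planted), max(probe_weight(m, seqs)))
})

test_that("probe weights are strand symmetric", {
  m <- binding_model_preset("wt")
  seqs <- random_kmers(100, 25, seed = 17)
  expect_equal(probe_weight(m, seqs), probe_weight(m, revcomp(seqs)),
               tolerance = 1e-12)
})

test_that("selection-free rounds preserve the R0 k-mer distribution", {
  m <- binding_model_preset("wt")
  # beta = 0 and no flank/boundary terms: every probe has the same weight
  m0 <- binding_model(m$core_energy, NULL, beta = 0, nonspecific = 0.05)
  cfg <- sim_config(n_reads = 3e4, n_rounds = 1, seed = 23)
  r0 <- simulate_r0(cfg)
  r1 <- run_rounds(m0, r0, cfg)[[1]]
  c0 <- count_kmers(r0, 3, merge_revcomp = FALSE)
  c1 <- count_kmers(r1, 3, merge_revcomp = FALSE)
  o0 <- c0$table$count[order(c0$table$kmer)]
  o1 <- c1$table$count[order(c1$table$kmer)]
  # chi-square goodness of fit of round-1 counts against R0 proportions
  p <- suppressWarnings(chisq.test(o1, p = o0 / sum(o0)))$p.value
  expect_gt(p, 0.01)
})

test_that("extreme selection drives the planted 10-mer to >90% of round 2", {
  m <- binding_model_preset("single_target")
  cfg <- sim_config(n_reads = 2e4, n_rounds = 2, seed = 31)
  pools <- simulate_selex(cfg, model = m)
  hit <- grepl("CCAAAATTGG", pools$R2$sequences, fixed = TRUE) |
    grepl(revcomp("CCAAAATTGG"), pools$R2$sequences, fixed = TRUE)
  expect_gt(mean(hit), 0.9)
})

test_that("enrichment of the planted CArG family is monotone over rounds", {
  cfg <- sim_config(n_reads = 2e4, n_rounds = 3, seed = 37)
  pools <- simulate_selex(cfg)
  # the family pattern is closed under reverse complement
  frac <- vapply(pools, function(p)
    mean(grepl("CC[AT]{6}GG", p$sequences)), numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_gt(frac[["R3"]], frac[["R0"]])
})

test_that("round-r frequency ratio of two k-mers grows like the weight ratio", {
  # single-mismatch variant vs consensus under the WT preset
  run <- wt_run()
  m <- run$model
  cons <- "CCAAAAATGG"
  var1 <- "CCTAAAATGG"   # pos 3 A->T, energy + 0.2
  pa <- planted_affinity(m, c(cons, var1))
  rho <- pa[[1]] / pa[[2]]   # per-round frequency gain ratio (with floor)
  ct <- function(pool, w) {
    sum(grepl(w, pool$sequences, fixed = TRUE) |
          grepl(revcomp(w), pool$sequences, fixed = TRUE))
  }
  # both 10-mers are equally likely in R0, so the round-2 count ratio
  # estimates rho^2; allow a generous band around it for sampling noise
  r2_ratio <- ct(run$pools$R2, cons) / ct(run$pools$R2, var1)
  expect_gt(r2_ratio, rho)
  expect_lt(r2_ratio, rho^3)
})

test_that("PCR bias tilts GC content in the configured direction", {
  m <- binding_model_preset("wt")
  gc_of <- function(pool) {
    mean(nchar(gsub("[AT]", "", pool$sequences)) / 25)
  }
  cfg_pos <- sim_config(n_reads = 2e4, n_rounds = 1, pcr_bias_gamma = 2,
                        seed = 41)
  cfg_neg <- sim_config(n_reads = 2e4, n_rounds = 1, pcr_bias_gamma = -2,
                        seed = 41)
  r0 <- simulate_r0(cfg_pos)
  up <- run_rounds(m, r0, cfg_pos)[[1]]
  dn <- run_rounds(m, r0, cfg_neg)[[1]]
  expect_gt(gc_of(up), gc_of(dn))
})
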