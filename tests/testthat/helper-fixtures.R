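# memoized simulation fixtures shared across test files
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# main WT SELEX fixture: 1e5 sequenced reads drawn from a 4e5-molecule
# library, two selection rounds under the wildtype CArG-box preset
wt_run <- function() {
  fixture("wt_run", function() {
    cfg <- sim_config(n_reads = 1e5, n_rounds = 2, library_size = 4e5,
                      seed = 101)
    model <- binding_model_preset("wt")
    design <- probe_design()
    pools <- simulate_selex(cfg, design, model = model)
    r0 <- read_pool(pools$R0$sequences[seq_len(cfg$n_reads)], 0L, "R0_reads")
    bg <- fit_markov(r0, 2)
    list(cfg = cfg, model = model, design = design, pools = pools, r0 = r0,
         bg = bg, aff2 = estimate_affinities(pools$R2, bg, 10, r = 2))
  })
}

# mechanism-targeted fixture for the flank-preference property: the same
# core with strong TTN-/-NAA flank bonuses, so the preference is
# measurable among the few hundred CArG-matching windows at desk scale
flank_run <- function() {
  fixture("flank_run", function() {
    wt <- binding_model_preset("wt")
    fb <- wt$flank_bonus
    fb[, ] <- 0
    fb["T", c("-2", "-1")] <- 0.6
    fb["A", c("1", "2")] <- 0.6
    model <- binding_model(wt$core_energy, fb, beta = 1, nonspecific = 0.05,
                           boundary_ct = 0.6)
    cfg <- sim_config(n_reads = 1e5, n_rounds = 2, library_size = 4e5,
                      seed = 11)
    list(model = model, pools = simulate_selex(cfg, model = model))
  })
}

# mechanism-targeted fixture for the adapter-CT position-bias artifact:
# a strongly CT-assisted boundary
posbias_run <- function() {
  fixture("posbias_run", function() {
    wt <- binding_model_preset("wt")
    model <- binding_model(wt$core_energy, wt$flank_bonus, beta = 1,
                           nonspecific = 0.05, boundary_ct = 0.2)
    cfg <- sim_config(n_reads = 1e5, n_rounds = 2, seed = 11)
    pools <- simulate_selex(cfg, model = model)
    bg <- fit_markov(pools$R0, 2)
    list(model = model, pools = pools, bg = bg,
         aff2 = estimate_affinities(pools$R2, bg, 10, r = 2))
  })
}

# motif trio for divergence comparisons: two WT replicates and one mutant
jsd_motif <- function(name, seed, preset) {
  fixture(name, function() {
    cfg <- sim_config(n_reads = 5e4, n_rounds = 2, library_size = 2e5,
                      seed = seed)
    pools <- simulate_selex(cfg, model = binding_model_preset(preset))
    r0 <- read_pool(pools$R0$sequences[seq_len(cfg$n_reads)], 0L)
    bg <- fit_markov(r0, 2)
    aff <- estimate_affinities(pools$R2, bg, 10, r = 2)
    discover_pwm(build_training_set(aff), restarts = 25, seed = seed)
  })
}

random_kmers <- function(n, k, seed) {
  set.seed(seed)
  apply(matrix(sample(c("A", "C", "G", "T"), n * k, replace = TRUE), n, k),
        1, paste, collapse = "")
}

# independent reverse-complement oracle (no Biostrings)
rc_oracle <- function(x) {
  vapply(x, function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# IUPAC-compatible position match count between two consensus strings,
# taking the better of the two orientations (discovery strand is arbitrary)
consensus_agreement <- function(got, target) {
  sets <- cargselex:::IUPAC_SETS
  score <- function(g) {
    sum(mapply(function(a, b) {
      all(sets[[a]] %in% sets[[b]]) || all(sets[[b]] %in% sets[[a]])
    }, strsplit(g, "")[[1]], strsplit(target, "")[[1]]))
  }
  rc <- vapply(strsplit(got, "")[[1]], function(ch) {
    comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", ch)
    comp
  }, character(1))
  got_rc <- paste(rev(rc), collapse = "")
  max(score(got), score(got_rc))
}
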