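test_that("probe design invariants are enforced", {
  d <- probe_design()
  expect_equal(d$total_length, 99L)
  expect_true(endsWith(d$adapter5, "CT"))
  expect_error(probe_design(adapter5 = "ACGTACGTAA"), "CT")
  expect_error(probe_design(barcodes = c(a = "GATC", b = "GATC")), "distinct")
  expect_error(probe_design(barcodes = c(a = "GAT")), "length")
  expect_error(probe_design(total_length = 90), "total_length")
})

test_that("assemble_probe builds 99-nt probes and checks part lengths", {
  d <- probe_design()
  p <- assemble_probe(d, strrep("A", 25), "GATC")
  expect_equal(nchar(p), 99L)
  expect_true(endsWith(p, d$adapter3))
  expect_true(startsWith(p, d$adapter5))
  # empty-adapter test design: 25 + 4
  d0 <- probe_design(adapter5 = "CT", adapter3 = "A",
                     barcodes = c(x = "GATC"))
  expect_equal(nchar(assemble_probe(d0, strrep("G", 25), "GATC")), 32L)
  expect_error(assemble_probe(d, "AAA", "GATC"), "variable")
  expect_error(assemble_probe(d, strrep("A", 25), "GATCA"), "barcode")
})

test_that("parse_reads splits variable region and barcode at declared offsets", {
  d <- probe_design(barcodes = c(lib1 = "GATC"))
  r <- parse_reads(paste0(strrep("A", 25), "GATC"), d)
  expect_named(r$pools, "lib1")
  expect_equal(r$pools$lib1$sequences, strrep("A", 25))
  expect_equal(r$unmatched, 0L)
  r2 <- parse_reads(paste0(strrep("A", 25), "GATC"),
                    probe_design(barcodes = c(lib1 = "TTTT")))
  expect_length(r2$pools, 0)
  expect_equal(r2$unmatched, 1L)
})

test_that("demultiplexing conserves reads and honors exact barcode match", {
  d <- probe_design(barcodes = c(a = "GATC", b = "CTAG"))
  set.seed(5)
  vr <- random_kmers(1000, 25, seed = 5)
  bc <- sample(c("GATC", "CTAG", "AAAA"), 1000, replace = TRUE,
               prob = c(0.45, 0.45, 0.10))
  res <- parse_reads(paste0(vr, bc), d)
  expect_equal(sum(res$assigned) + res$unmatched, 1000L)
  expect_equal(unname(res$assigned["a"]), sum(bc == "GATC"))
  expect_equal(unname(res$assigned["b"]), sum(bc == "CTAG"))
  expect_equal(res$unmatched, sum(bc == "AAAA"))
})

test_that("parse_reads round-trips assembled probes for arbitrary designs", {
  d <- probe_design(barcodes = c(x = "TGCA", y = "ACGT"))
  vr <- random_kmers(50, 25, seed = 9)
  bc <- rep(c("TGCA", "ACGT"), 25)
  # sequenced reads = variable + barcode (per the probe layout)
  res <- parse_reads(paste0(vr, bc), d)
  expect_setequal(c(res$pools$x$sequences, res$pools$y$sequences), vr)
  expect_equal(res$pools$x$sequences, vr[bc == "TGCA"])
})

test_that("reads with non-DNA letters or short records are rejected", {
  d <- probe_design(barcodes = c(lib1 = "GATC"))
  expect_error(parse_reads(paste0(strrep("X", 25), "GATC"), d), "record 1")
  expect_error(parse_reads("ACGT", d), "record 1")
  expect_error(read_pool(c("ACGT", "ACGU")), "read 2")
})

test_that("FASTA and FASTQ files round-trip through write_reads/parse_reads", {
  d <- probe_design(barcodes = c(lib1 = "GATC"))
  pool <- read_pool(random_kmers(20, 25, seed = 3), 1, "lib1")
  for (ext in c("fa", "fq")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_reads(pool, f, barcode = "GATC")
    res <- parse_reads(f, d, round_index = 1)
    expect_equal(res$pools$lib1$sequences, pool$sequences)
  }
})

test_that("contamination fraction and flag follow the threshold rule", {
  sig <- "TTATTTCCTAATTAGGTAAATTTGG"
  clean <- random_kmers(90, 25, seed = 11)
  clean <- clean[clean != sig]
  pool <- read_pool(c(clean[1:90], rep(sig, 10)), 1)
  res <- contamination_fraction(pool, sig)
  expect_equal(res$fraction, 0.10)
  expect_true(res$flagged)
  res0 <- contamination_fraction(read_pool(clean, 1), sig)
  expect_equal(res0$fraction, 0)
  expect_false(res0$flagged)
  expect_error(contamination_fraction(read_pool(character(0)), sig), "empty")
})

test_that("simulator contamination spike is recovered within binomial bounds", {
  cfg <- sim_config(n_reads = 4000, n_rounds = 1, contamination = 0.30,
                    seed = 21)
  pools <- simulate_selex(cfg)
  res <- contamination_fraction(pools$R1, cfg$contaminant)
  ci <- qbinom(c(0.005, 0.995), 4000, 0.30) / 4000
  expect_gte(res$fraction, ci[1])
  expect_lte(res$fraction, ci[2])
  expect_true(res$flagged)
})

test_that("affinity tables and PWMs round-trip through their file formats", {
  run <- wt_run()
  aff <- run$aff2
  f <- tempfile(fileext = ".tsv")
  write_affinity_tsv(aff, f)
  back <- read_affinity_tsv(f)
  expect_equal(back$table$affinity, aff$table$affinity)
  expect_equal(back$table$kmer, aff$table$kmer)
  expect_equal(back$k, aff$k)

  p <- pwm(matrix(rep(c(0.1, 0.2, 0.3, 0.4), 10), nrow = 4))
  fm <- tempfile(fileext = ".meme")
  write_meme(list(m1 = p), fm)
  lines <- readLines(fm)
  expect_length(grep("^[0-9.]+ [0-9.]+ [0-9.]+ [0-9.]+$", lines), 10)
  back_p <- read_meme(fm)$m1
  expect_equal(unclass(back_p), unclass(p), tolerance = 1e-5,
               ignore_attr = TRUE)

  bg <- run$bg
  fb <- tempfile(fileext = ".json")
  write_markov(bg, fb)
  bg2 <- read_markov(fb)
  expect_equal(bg2$transitions, bg$transitions, ignore_attr = TRUE)
  expect_equal(unname(bg2$initial), unname(bg$initial))
})

test_that("export_tables writes an empty table as header-only without error", {
  f <- tempfile()
  df <- data.frame(kmer = character(0), affinity = numeric(0))
  export_tables(list(empty = df), f, seed = 1)
  lines <- readLines(paste0(f, "_empty.tsv"))
  expect_equal(length(lines), 1L)
  expect_match(lines, "kmer\taffinity")
  meta <- jsonlite::read_json(paste0(f, "_metadata.json"))
  expect_equal(meta$seed, 1L)
})
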