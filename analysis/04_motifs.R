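#!/usr/bin/env Rscript
# De novo motif discovery, flank analysis and position-bias diagnostics.
#
# High-affinity k-mers (> 0.4) are N-padded and weighted by 10^3 x affinity;
# a single PWM is learned by OOPS EM on both strands. Flank preferences come
# from a guided extraction of N4-CArG-N4 windows with orientation EM, and
# the position-bias histograms classify top k-mers as complete / incomplete
# CArG-boxes (the incomplete class concentrates at the 5' end of the reads,
# where the adapter's terminal CT can substitute for the missing border).

source("analysis/00_config.R")

meta <- jsonlite::read_json(file.path(RESULTS_DIR, "03_metadata.json"))
k <- meta$params$k
order_m <- meta$params$order

objects <- list()
for (label in LIBRARIES$label) {
  pools <- load_library(label)
  aff <- read_affinity_tsv(file.path(RESULTS_DIR,
                                     sprintf("03_affinity_%s.tsv", label)))
  train <- build_training_set(aff)
  motif <- discover_pwm(train, L = k, restarts = 200, seed = BASE_SEED)
  message(label, ": ", length(train$sequences),
          " training k-mers, consensus ", iupac_consensus(motif))
  fl <- flank_extract_orient(pools$R2, seed = BASE_SEED)
  pb <- position_bias(pools$R2, head(aff$table$kmer, 100))
  inc <- pb$classes$class == "incomplete"
  if (any(inc)) {
    h <- colSums(pb$histogram[inc, , drop = FALSE])
    message("  incomplete-box histogram mode at offset ", which.max(h))
  }
  objects[[paste0("motif_", label)]] <- motif
  objects[[paste0("motif_table_", label)]] <- pwm_table(motif)
  objects[[paste0("flank_pwm_", label)]] <- fl$pwm
  objects[[paste0("flank_table_", label)]] <- pwm_table(fl$pwm)
  objects[[paste0("posbias_", label)]] <- pb$histogram
  objects[[paste0("posbias_classes_", label)]] <- pb$classes
}
export_tables(objects, file.path(RESULTS_DIR, "04"), seed = BASE_SEED,
              params = list(k = k, cutoff = 0.4, restarts = 200))
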