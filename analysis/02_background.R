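#!/usr/bin/env Rscript
# Markov background modelling of the initial pools.
#
# The model order is chosen by cross-replicate prediction: a model fitted on
# one R0 replicate predicts the other replicate's 8-mer counts, scored by
# R^2 over all 4^8 8-mers (both directions averaged, parsimony tie-break).
# The selected-order model of each library's own R0 is serialized for the
# downstream scripts.

source("analysis/00_config.R")

wt1 <- load_library("WT_rep1")
wt2 <- load_library("WT_rep2")

sel <- select_order(wt1$R0, wt2$R0, orders = 0:4)
message("cross-replicate R^2 profile:")
print(sel$profile, row.names = FALSE)
message("selected background order: ", sel$best_order)

objects <- list(order_profile = sel$profile)
for (label in LIBRARIES$label) {
  pools <- load_library(label)
  bg <- fit_markov(pools$R0, sel$best_order)
  objects[[paste0("background_", label)]] <- bg
}
export_tables(objects, file.path(RESULTS_DIR, "02"), seed = BASE_SEED,
              params = list(orders_tested = 0:4,
                            selected_order = sel$best_order))
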