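#!/usr/bin/env Rscript
# Motif length selection and relative affinities.
#
# The binding-site width is chosen on the wildtype replicate with the
# information-gain criterion (R0 -> R2, matched-baseline estimator, plateau
# onset). Relative affinities are computed per library from R1 and R2 and
# integrated by local regression on the log scale; the CArG-box / A-tract
# enrichment table and the top-21 report come from the integrated estimates.

source("analysis/00_config.R")

meta <- jsonlite::read_json(file.path(RESULTS_DIR, "02_metadata.json"))
order_m <- meta$params$selected_order

wt1 <- load_library("WT_rep1")
bg1 <- fit_markov(wt1$R0, order_m)
ksel <- select_k(wt1$R2, bg1, k_range = 6:14, r0_pool = wt1$R0)
message("information-gain profile (WT replicate 1):")
print(ksel$profile, row.names = FALSE)
message("selected motif length: ", ksel$k)

objects <- list(ig_profile = ksel$profile)
for (label in LIBRARIES$label) {
  pools <- load_library(label)
  bg <- fit_markov(pools$R0, order_m)
  a1 <- estimate_affinities(pools$R1, bg, ksel$k, r = 1)
  a2 <- estimate_affinities(pools$R2, bg, ksel$k, r = 2)
  comb <- loess_combine(a1, a2)
  objects[[paste0("affinity_", label)]] <- comb
  objects[[paste0("top21_", label)]] <- top_affinity_report(comb, 21)
  if (ksel$k == 10) {
    carg <- atract_affinity_table(comb)
    objects[[paste0("cargbox_", label)]] <- carg
    message(label, ": ", sum(carg$has_a_tract[1:10]),
            " of the 10 top-ranked CArG-boxes carry an A-tract; ",
            sum(objects[[paste0("top21_", label)]]$is_srf_cargbox),
            " of the top 21 k-mers are SRF-type CArG-boxes")
  }
}
export_tables(objects, file.path(RESULTS_DIR, "03"), seed = BASE_SEED,
              params = list(k = ksel$k, order = order_m))
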