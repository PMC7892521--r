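#!/usr/bin/env Rscript
# Motif divergence: pairwise Jensen-Shannon divergence and difference logos.
#
# The discovered PWMs of the libraries are compared pairwise (orientation
# resolved by the reverse-complement check); replicate pairs are expected to
# diverge far less than wildtype vs mutant pairs.

source("analysis/00_config.R")

pwms <- list()
for (label in LIBRARIES$label) {
  pwms[[label]] <- read_meme(file.path(RESULTS_DIR,
                                       sprintf("04_motif_%s.meme",
                                               label)))[[1]]
}
mat <- jsd_matrix(pwms)
message("pairwise JSD (sum over positions, bits):")
print(round(mat, 3))

objects <- list(jsd_matrix = as.data.frame(mat))
ref <- pwms[[1]]
for (label in names(pwms)[-1]) {
  q <- pwms[[label]]
  cmp <- pwm_jsd(ref, q)
  if (cmp$orientation == "reverse_complement") q <- pwm_revcomp(q)
  dl <- difference_logo(ref, q)
  objects[[paste0("difflogo_", names(pwms)[1], "_vs_", label)]] <-
    data.frame(position = seq_along(dl$per_position),
               t(dl$heights), jsd_bits = dl$per_position)
}
export_tables(objects, file.path(RESULTS_DIR, "06"), seed = BASE_SEED,
              params = list(aggregate = "sum"))
message("replicate vs mutant ordering holds: ",
        mat["WT_rep1", "WT_rep2"] < mat["WT_rep1", "R3mut_rep1"])
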