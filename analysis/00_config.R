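# Shared configuration for the analysis scripts.
#
# Three SELEX libraries are emulated at desk scale: two replicates of the
# wildtype protein and one R3-mutant library, each with an R0 pool and two
# selection rounds. Libraries are tied to barcodes of the default probe
# design; the scanning context uses each library's own barcode.

suppressMessages(library(cargselex))

RESULTS_DIR <- "results"
READS_DIR <- file.path(RESULTS_DIR, "reads")

N_READS <- 5e4
LIBRARY_SIZE <- 2e5   # molecules carried through selection; reads are a sample
N_ROUNDS <- 2
BASE_SEED <- 20260919L

LIBRARIES <- data.frame(
  label = c("WT_rep1", "WT_rep2", "R3mut_rep1"),
  preset = c("wt", "wt", "mutant"),
  barcode_name = c("probe4", "probe5", "probe6"),
  seed = BASE_SEED + 1:3,
  stringsAsFactors = FALSE
)

DESIGN <- probe_design()

simulate_library <- function(lib) {
  cfg <- sim_config(n_reads = N_READS, n_rounds = N_ROUNDS,
                    library_size = LIBRARY_SIZE, seed = lib$seed)
  pools <- simulate_selex(cfg, DESIGN,
                          model = binding_model_preset(lib$preset),
                          barcode = DESIGN$barcodes[[lib$barcode_name]],
                          label = lib$label)
  # report a read-sized sample of the R0 library as the sequenced R0 pool
  pools$R0 <- read_pool(pools$R0$sequences[seq_len(N_READS)], 0L, lib$label)
  pools
}

# deterministic reload: parse the FASTA files written by 01_simulate.R
load_library <- function(label) {
  out <- list()
  for (r in 0:N_ROUNDS) {
    f <- file.path(READS_DIR, sprintf("%s_R%d.fasta", label, r))
    if (!file.exists(f)) {
      stop("run analysis/01_simulate.R first (missing ", f, ")")
    }
    res <- parse_reads(f, DESIGN, round_index = r)
    stopifnot(length(res$pools) == 1)
    out[[sprintf("R%d", r)]] <- res$pools[[1]]
  }
  out
}
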