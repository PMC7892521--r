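#' Simulation configuration
#'
#' @param n_reads reads sampled (sequenced) per round.
#' @param n_rounds number of selection rounds to simulate.
#' @param library_size number of distinct molecules carried through the
#'   selection rounds (default: equal to \code{n_reads}). A real SELEX
#'   library holds vastly more molecules than are ever sequenced; raising
#'   this emulates that separation, while the default gives the fully
#'   read-limited regime.
#' @param base_composition probabilities of A, C, G, T in the R0 library
#'   (default near-uniform hand-mixed synthesis, 25\% each).
#' @param background optional \code{\link{markov_background}}; when supplied,
#'   R0 is generated from this Markov chain instead of i.i.d. bases
#'   (emulating synthesis bias in the initial pools).
#' @param pcr_bias_gamma smooth GC-content PCR bias; each sampled probe's
#'   weight is multiplied by \code{exp(gamma * (GC - 0.5))}. Default 0.
#' @param contamination contaminant fraction spiked into each selected round
#'   (carry-over of the positive control). Default 0.
#' @param contaminant variable-region sequence of the control probe.
#' @param seed integer seed; all stages are reproducible given the seed.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_reads = 1e5, n_rounds = 2, library_size = n_reads,
                       base_composition = c(0.25, 0.25, 0.25, 0.25),
                       background = NULL, pcr_bias_gamma = 0,
                       contamination = 0,
                       contaminant = "TTATTTCCTAATTAGGTAAATTTGG",
                       seed = 1L) {
  stopifnot(n_reads > 0, n_rounds >= 0, library_size >= n_reads,
            length(base_composition) == 4, all(base_composition >= 0),
            abs(sum(base_composition) - 1) < 1e-9,
            contamination >= 0, contamination < 1)
  structure(list(n_reads = as.integer(n_reads), n_rounds = as.integer(n_rounds),
                 library_size = as.integer(library_size),
                 base_composition = base_composition, background = background,
                 pcr_bias_gamma = pcr_bias_gamma, contamination = contamination,
                 contaminant = contaminant, seed = as.integer(seed)),
            class = "sim_config")
}

.collapse_base_matrix <- function(M) {
  ch <- matrix(DNA_BASES[M], nrow = nrow(M))
  do.call(paste0, as.data.frame(ch, stringsAsFactors = FALSE))
}

#' Simulate an initial (R0) SELEX library
#'
#' Draws \code{n_reads} variable regions of the design's variable length,
#' i.i.d. from the configured base composition, or from a Markov chain when
#' \code{config$background} is set.
#'
#' @param config a \code{\link{sim_config}}.
#' @param design a \code{\link{probe_design}} (supplies the variable length).
#' @param label library label for the returned pool.
#' @return a \code{\link{read_pool}} with \code{round_index = 0}.
#' @export
simulate_r0 <- function(config, design = probe_design(), label = "sim") {
  set.seed(config$seed)
  n <- max(config$n_reads, config$library_size)
  L <- design$variable_length
  if (is.null(config$background)) {
    M <- matrix(sample.int(4L, n * L, replace = TRUE,
                           prob = config$base_composition),
                nrow = n, ncol = L)
  } else {
    M <- .sample_markov_matrix(config$background, n, L)
  }
  read_pool(.collapse_base_matrix(M), round_index = 0L, library_label = label)
}

#' Simulate successive SELEX selection rounds
#'
#' Each round draws \code{n_reads} probes from the previous round by weighted
#' sampling with replacement, with probability proportional to
#' \code{\link{probe_weight}} times the optional GC-content PCR factor, then
#' spikes in the configured contaminant fraction (mimicking positive-control
#' carry-over after selection).
#'
#' @param model a \code{\link{binding_model}}.
#' @param r0 the initial \code{\link{read_pool}}.
#' @param config a \code{\link{sim_config}}.
#' @param design a \code{\link{probe_design}} giving adapter context (NULL
#'   scores bare variable regions).
#' @param barcode barcode providing 3' scanning context.
#' @return list of \code{\link{read_pool}}s for rounds 1..n_rounds.
#' @export
run_rounds <- function(model, r0, config, design = probe_design(),
                       barcode = "ACTG") {
  if (!length(r0$sequences)) stop("r0 must be non-empty")
  set.seed(config$seed + 1L)
  seqs <- r0$sequences
  n_mol <- max(length(seqs), config$library_size)
  out <- vector("list", config$n_rounds)
  for (r in seq_len(config$n_rounds)) {
    w <- probe_weight(model, seqs, design = design, barcode = barcode)
    if (config$pcr_bias_gamma != 0) {
      gc <- (nchar(gsub("[AT]", "", seqs))) / nchar(seqs)
      w <- w * exp(config$pcr_bias_gamma * (gc - 0.5))
    }
    # the molecule population is carried at library_size; sequencing reads
    # are a subsample of it (they coincide when library_size == n_reads)
    idx <- sample.int(length(seqs), n_mol, replace = TRUE, prob = w)
    seqs <- seqs[idx]
    if (config$contamination > 0) {
      n_spike <- round(config$contamination * n_mol)
      if (n_spike > 0) {
        pos <- sample.int(n_mol, n_spike)
        seqs[pos] <- config$contaminant
      }
    }
    out[[r]] <- read_pool(seqs[seq_len(config$n_reads)], round_index = r,
                          library_label = r0$library_label)
  }
  out
}

#' Simulate a full SELEX experiment
#'
#' Convenience wrapper: R0 plus \code{n_rounds} of selection.
#'
#' @inheritParams run_rounds
#' @param label library label.
#' @return named list of \code{\link{read_pool}}s: \code{R0, R1, ...}.
#' @export
simulate_selex <- function(config, design = probe_design(),
                           model = binding_model_preset("wt"),
                           barcode = "ACTG", label = "sim") {
  r0 <- simulate_r0(config, design, label = label)
  rounds <- run_rounds(model, r0, config, design = design, barcode = barcode)
  out <- c(list(r0), rounds)
  names(out) <- paste0("R", seq_along(out) - 1L)
  out
}
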