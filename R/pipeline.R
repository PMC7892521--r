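# small deterministic polynomial hash of a config for output provenance
# (kept within 2^31 so all arithmetic is exact in doubles)
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 17
  for (v in utf8ToInt(s)) {
    h <- (h * 31 + v) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Full-analysis run configuration
#'
#' @param pools optional named list of \code{\link{read_pool}}s (R0, R1, ...);
#'   when NULL, a SELEX experiment is simulated from \code{preset}.
#' @param preset simulator preset ("wt", "mutant", "single_target").
#' @param n_reads,n_rounds,library_size simulation size (used when
#'   \code{pools} is NULL).
#' @param design a \code{\link{probe_design}}.
#' @param orders candidate background orders.
#' @param k_range candidate motif lengths.
#' @param analysis_round round used for affinity/motif analysis (default 2).
#' @param affinity_cutoff training-set affinity cutoff.
#' @param use_flagged keep low-confidence k-mers in the motif training set
#'   (useful for very small smoke runs; default FALSE).
#' @param restarts EM restarts for motif discovery.
#' @param dependence_orders orders fitted for the dependence/IMC table.
#' @param control_signature contaminant signature for QC.
#' @param contamination_threshold QC flag threshold.
#' @param outdir output directory (created); NULL skips file output.
#' @param seed integer seed controlling the whole run.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(pools = NULL, preset = "wt", n_reads = 2e4,
                       n_rounds = 2, library_size = n_reads,
                       design = probe_design(),
                       orders = 0:3, k_range = 6:12, analysis_round = 2,
                       affinity_cutoff = 0.4, use_flagged = FALSE,
                       restarts = 50,
                       dependence_orders = 1:2,
                       control_signature = "TTATTTCCTAATTAGGTAAATTTGG",
                       contamination_threshold = 0.05,
                       outdir = NULL, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full SELEX-seq analysis
#'
#' Executes, in order: simulation (or loading) of per-round pools;
#' contamination QC (a flag raises a warning, never auto-exclusion, since
#' exclusion of contaminated libraries is a manual decision); background
#' order selection on split halves of R0 (or across two R0 replicates if a
#' pool named \code{R0b} is supplied); motif-length selection by information
#' gain; relative affinities from R1 and R2 and their LOESS combination; the
#' affinity-weighted training set, PWM discovery and IUPAC consensus; guided
#' flank analysis; position-bias histograms of the top k-mers; proximal and
#' distal dependence models with the IMC table; the divergence between the
#' discovered motif and the flank-set core motif with a difference-logo
#' table; and the CArG-box / A-tract tables. All tables are written under
#' \code{config$outdir} (when set) with the seed and config hash in the
#' metadata sidecar.
#'
#' @param config a \code{\link{run_config}}.
#' @return a named list of all stage results (invisible file writes).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  design <- config$design
  if (is.null(config$pools)) {
    sim <- sim_config(n_reads = config$n_reads, n_rounds = config$n_rounds,
                      library_size = config$library_size, seed = config$seed)
    pools <- simulate_selex(sim, design,
                            model = binding_model_preset(config$preset))
    pools$R0 <- read_pool(pools$R0$sequences[seq_len(config$n_reads)], 0L,
                          pools$R0$library_label)
  } else {
    pools <- config$pools
  }
  rounds <- grep("^R\\d+$", names(pools), value = TRUE)
  qc <- lapply(pools[rounds], contamination_fraction,
               control_signature = config$control_signature,
               threshold = config$contamination_threshold)
  for (nm in names(qc)) {
    if (isTRUE(qc[[nm]]$flagged)) {
      warning(sprintf("pool %s: contaminated fraction %.3f exceeds %.3f",
                      nm, qc[[nm]]$fraction, config$contamination_threshold))
    }
  }
  r0 <- pools$R0
  if (!is.null(pools$R0b)) {
    repA <- r0; repB <- pools$R0b
  } else {
    half <- seq_len(floor(length(r0$sequences) / 2))
    repA <- read_pool(r0$sequences[half], 0L, "R0_halfA")
    repB <- read_pool(r0$sequences[-half], 0L, "R0_halfB")
  }
  order_sel <- select_order(repA, repB, orders = config$orders)
  bg <- fit_markov(r0, order_sel$best_order)
  r_use <- sprintf("R%d", config$analysis_round)
  if (is.null(pools[[r_use]])) stop("analysis round pool not available")
  ksel <- select_k(pools[[r_use]], bg, k_range = config$k_range,
                   r0_pool = r0)
  k <- ksel$k
  aff <- list()
  if (!is.null(pools$R1)) aff$R1 <- estimate_affinities(pools$R1, bg, k, r = 1)
  aff[[r_use]] <- estimate_affinities(pools[[r_use]], bg, k,
                                      r = config$analysis_round)
  aff_main <- aff[[r_use]]
  if (!is.null(aff$R1) && config$analysis_round == 2) {
    aff$loess <- tryCatch(loess_combine(aff$R1, aff$R2),
                          error = function(e) NULL)
    if (!is.null(aff$loess)) aff_main <- aff$loess
  }
  train <- build_training_set(aff[[r_use]], cutoff = config$affinity_cutoff,
                              use_flagged = config$use_flagged)
  motif <- discover_pwm(train, L = k, restarts = config$restarts,
                        seed = config$seed)
  consensus <- iupac_consensus(motif)
  flanks <- flank_extract_orient(pools[[r_use]], seed = config$seed)
  tab_r <- aff[[r_use]]$table
  top100 <- head(tab_r$kmer[!tab_r$low_confidence], 100)
  if (!length(top100)) top100 <- head(tab_r$kmer, 100)  # tiny smoke runs
  posbias <- position_bias(pools[[r_use]], top100)
  flank_set <- weighted_seqs(flanks$sequences, flanks$weights)
  dep_grid <- expand.grid(model_type = c("proximal", "distal"),
                          order = config$dependence_orders,
                          stringsAsFactors = FALSE)
  imc_table <- do.call(rbind, lapply(seq_len(nrow(dep_grid)), function(i) {
    m <- fit_dependence(flank_set, dep_grid$model_type[i],
                        d = dep_grid$order[i], penalty = "BIC")
    data.frame(model = dep_grid$model_type[i], order = dep_grid$order[i],
               imc_bits = imc(m, flank_set), stringsAsFactors = FALSE)
  }))
  core_cols <- 5:14
  flank_core_pwm <- pwm(unclass(flanks$pwm)[, core_cols, drop = FALSE])
  if (ncol(motif) == ncol(flank_core_pwm)) {
    divergence <- pwm_jsd(motif, flank_core_pwm)
    q_use <- if (divergence$orientation == "reverse_complement") {
      pwm_revcomp(flank_core_pwm)
    } else flank_core_pwm
    dlogo <- difference_logo(motif, q_use)
  } else {
    # selected k differs from the fixed guided-flank core width
    divergence <- NULL
    dlogo <- NULL
  }
  # CArG-boxes are 10-mers by definition; reuse the main table when k = 10
  aff_carg <- if (k == 10) aff_main else {
    estimate_affinities(pools[[r_use]], bg, 10, r = config$analysis_round)
  }
  carg <- atract_affinity_table(aff_carg)
  top21 <- top_affinity_report(aff_main, 21)
  results <- list(qc = qc, order_selection = order_sel, background = bg,
                  k_selection = ksel, affinities = aff, training_set = train,
                  motif = motif, consensus = consensus, flanks = flanks,
                  position_bias = posbias, imc_table = imc_table,
                  divergence = divergence, difference_logo = dlogo,
                  cargbox_table = carg, top21 = top21)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    prefix <- file.path(config$outdir, "run")
    cfg_for_hash <- config[setdiff(names(config), "pools")]
    objects <- list(order_profile = order_sel$profile, background = bg,
                    ig_profile = ksel$profile,
                    affinity_main = aff_main,
                    motif = motif, flank_pwm = flanks$pwm,
                    motif_table = pwm_table(motif),
                    imc_table = imc_table,
                    cargbox_table = carg, top21 = top21,
                    position_bias = posbias$histogram,
                    consensus = data.frame(consensus = consensus))
    if (!is.null(divergence)) {
      objects$jsd_per_position <- data.frame(
        position = seq_along(divergence$per_position),
        jsd_bits = divergence$per_position)
      objects$difference_logo <- as.data.frame(t(dlogo$heights))
    }
    export_tables(
      objects,
      prefix, seed = config$seed,
      params = list(config_hash = .config_hash(cfg_for_hash),
                    k = k, order = order_sel$best_order,
                    analysis_round = config$analysis_round,
                    affinity_cutoff = config$affinity_cutoff,
                    restarts = config$restarts))
  }
  results
}
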