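## Forward simulation of reporter intensities from the planted truth.
##
## Expected log2 soluble-fraction signal of an aggregator relaxes linearly
## from its planted drop back to 0 at the planted slope (truncated at 0);
## heavy-label signal accumulates as 1 - exp(-k (t + 1.5 h)), the 1.5 h
## reflecting label incorporation during the pre-shock medium-switch window,
## damped by a translational stall after heat shock that decays over
## recovery. Multiplicative log-normal noise, per-channel scale effects,
## per-batch offsets and probit left-censoring are layered on top.

## expected log2 solubility of the pre-existing pool during recovery
.relax <- function(drop, slope, t) pmin(0, drop + slope * t)

## heavy-label pool on the log2 scale (relative to abundance)
.heavy_log2 <- function(k, t, condition, induction, stall_depth) {
  heat <- condition == "heat"
  stall <- if (heat) 1 - stall_depth * exp(-t) else 1
  ind <- if (heat) log2(induction) * t / 5 else 0
  log2(1 - exp(-k * (t + 1.5))) + log2(stall) + ind
}

.apply_noise_censor <- function(log2_expected, meta, noise_sd, channel_sd,
                                batch_sd, censor_quantile, censor_width) {
  n_chan <- nrow(meta)
  batches <- unique(meta$batch)
  batch_off <- stats::setNames(stats::rnorm(length(batches), 0, batch_sd),
                               batches)
  chan_off <- stats::rnorm(n_chan, 0, channel_sd)
  v <- sweep(log2_expected, 2, batch_off[meta$batch] + chan_off, `+`)
  v <- v + matrix(stats::rnorm(length(v), 0, noise_sd), nrow(v))
  if (censor_quantile > 0) {
    theta <- stats::quantile(v, censor_quantile, na.rm = TRUE, names = FALSE)
    p_miss <- stats::pnorm((theta - v) / censor_width)
    v[matrix(stats::runif(length(v)), nrow(v)) < p_miss] <- NA
  }
  2^v
}

.peptide_support <- function(truth, n_rep) {
  lam <- pmin(30, pmax(0.6, (log2(truth$abundance) - 10) / 2.5))
  ps <- matrix(stats::rpois(nrow(truth) * n_rep, rep(lam, n_rep)),
               ncol = n_rep,
               dimnames = list(truth$protein_id, paste0("r", seq_len(n_rep))))
  ps
}

#' Simulate the SILAC/TMT heat-shock recovery time course
#'
#' Emits one raw `intensity_table` holding, for each replicate: light- and
#' heavy-SILAC NP-40 (soluble) channels for heat and mock conditions at every
#' design time point, a pre-shock NP-40 channel, and SDS (total) channels at
#' t = 0 for heat, mock and pre-shock. In the noise-free limit the light
#' heat/mock log2 ratio of a protein equals its planted relaxation trajectory
#' exactly, and SDS channels always carry at least the NP-40 expectation
#' (soluble is a subset of total).
#'
#' @param truth a `proteome_truth`.
#' @param design an `experiment_design`.
#' @param noise_sd SD of the cell-level log2 measurement noise.
#' @param channel_sd SD of per-channel scale effects (log2).
#' @param batch_sd SD of per-batch offsets (log2).
#' @param censor_quantile detection quantile for probit left-censoring; 0
#'   disables missingness.
#' @param censor_width probit width (log2 units) of the censoring band.
#' @param stall_depth depth of the post-shock translational stall on heavy
#'   synthesis (0 disables it; default 0.5 halves synthesis right after the
#'   shock, recovering with a 1 h time constant).
#' @param seed integer seed.
#' @return An `intensity_table` (raw scale) with peptide support.
#' @export
simulate_solubility_course <- function(truth, design = experiment_design(),
                                       noise_sd = 0.15, channel_sd = 0.05,
                                       batch_sd = 0.1,
                                       censor_quantile = 0.03,
                                       censor_width = 0.5,
                                       stall_depth = 0.5, seed) {
  stopifnot(inherits(truth, "proteome_truth"),
            inherits(design, "experiment_design"))
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  tps <- design$timepoints_h
  reps <- seq_len(design$n_replicates)

  meta <- rbind(
    expand.grid(condition = c("heat", "mock"), time_h = tps,
                silac = c("light", "heavy"), replicate = reps,
                lysis = "NP40", stringsAsFactors = FALSE),
    expand.grid(condition = "preshock", time_h = 0,
                silac = c("light", "heavy"), replicate = reps,
                lysis = "NP40", stringsAsFactors = FALSE),
    expand.grid(condition = c("heat", "mock", "preshock"), time_h = 0,
                silac = c("light", "heavy"), replicate = reps,
                lysis = "SDS", stringsAsFactors = FALSE))
  meta$batch <- design$batches[meta$replicate]
  meta$temperature_C <- NA_real_
  meta$channel_id <- sprintf("%s_%s_t%g_%s_r%d", meta$silac, meta$lysis,
                             meta$time_h, meta$condition, meta$replicate)
  meta <- meta[, c("channel_id", "condition", "time_h", "silac", "replicate",
                   "batch", "lysis", "temperature_C")]

  base <- log2(truth$abundance)
  exp_log2 <- matrix(NA_real_, nrow(truth), nrow(meta),
                     dimnames = list(truth$protein_id, meta$channel_id))
  for (j in seq_len(nrow(meta))) {
    cond <- meta$condition[j]; t <- meta$time_h[j]
    sol <- if (cond == "heat") .relax(truth$true_drop, truth$true_slope, t)
           else 0
    v <- base
    if (meta$silac[j] == "heavy")
      v <- v + .heavy_log2(truth$synthesis_rate, t, cond, truth$induction,
                           stall_depth)
    if (meta$lysis[j] == "NP40") v <- v + truth$total_sol_pre + sol
    exp_log2[, j] <- v
  }
  values <- .apply_noise_censor(exp_log2, meta, noise_sd, channel_sd,
                                batch_sd, censor_quantile, censor_width)
  intensity_table(values, meta,
                  peptide_support = .peptide_support(truth,
                                                     design$n_replicates),
                  scale = "raw")
}

#' Simulate the 2D thermal-proteome-profiling experiment
#'
#' Emits one raw `intensity_table` over the 12-temperature gradient with 2
#' mock and 3 heat-shock replicates. Heat-condition melting curves use
#' `Tm + delta_Tm`; for aggregators the heat channels at the two lowest
#' (sub-shock) temperatures are additionally scaled by `2^true_drop`,
#' modelling the pool already lost to aggregates before the gradient.
#'
#' @inheritParams simulate_solubility_course
#' @return An `intensity_table` (raw scale) with peptide support.
#' @export
simulate_tpp2d <- function(truth, design = experiment_design(),
                           noise_sd = 0.1, channel_sd = 0.05,
                           batch_sd = 0.05, censor_quantile = 0,
                           censor_width = 0.5, seed) {
  stopifnot(inherits(truth, "proteome_truth"),
            inherits(design, "experiment_design"))
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  temps <- design$tpp_temperatures
  low2 <- temps[1:2]
  grid <- rbind(
    expand.grid(condition = "mock",
                replicate = seq_len(design$tpp_replicates[["mock"]]),
                temperature_C = temps, stringsAsFactors = FALSE),
    expand.grid(condition = "heat",
                replicate = seq_len(design$tpp_replicates[["heat"]]),
                temperature_C = temps, stringsAsFactors = FALSE))
  meta <- data.frame(
    channel_id = sprintf("tpp_%s_r%d_T%.1f", grid$condition, grid$replicate,
                         grid$temperature_C),
    condition = grid$condition, time_h = NA_real_, silac = "light",
    replicate = grid$replicate,
    batch = paste0(grid$condition, grid$replicate),
    lysis = "NP40", temperature_C = grid$temperature_C,
    stringsAsFactors = FALSE)

  base <- log2(truth$abundance)
  is_agg <- truth$class == "aggregator"
  exp_log2 <- matrix(NA_real_, nrow(truth), nrow(meta),
                     dimnames = list(truth$protein_id, meta$channel_id))
  for (j in seq_len(nrow(meta))) {
    Tj <- meta$temperature_C[j]
    tm <- truth$Tm + if (meta$condition[j] == "heat") truth$delta_Tm else 0
    v <- base + log2(melting_fraction(Tj, tm, truth$melt_slope,
                                      truth$plateau))
    if (meta$condition[j] == "heat" && Tj %in% low2)
      v <- v + ifelse(is_agg, truth$true_drop, 0)
    exp_log2[, j] <- v
  }
  n_rep_total <- sum(design$tpp_replicates)
  values <- .apply_noise_censor(exp_log2, meta, noise_sd, channel_sd,
                                batch_sd, censor_quantile, censor_width)
  intensity_table(values, meta,
                  peptide_support = .peptide_support(truth, n_rep_total),
                  scale = "raw")
}

#' Write a complete simulated study to disk
#'
#' Writes the wide intensity + channel-metadata TSV pair for each table, the
#' truth table, complex memberships, and the sequences as FASTA.
#'
#' @param truth a `proteome_truth`.
#' @param tables named list of `intensity_table`s (names become file
#'   prefixes).
#' @param outdir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(truth, tables, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables))
    paths <- c(paths, write_intensity_table(tables[[nm]],
                                            file.path(outdir, nm)))
  truth_path <- file.path(outdir, "truth.tsv")
  utils::write.table(as.data.frame(truth), truth_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cpx_path <- file.path(outdir, "complexes.tsv")
  utils::write.table(attr(truth, "complexes"), cpx_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fa_path <- file.path(outdir, "sequences.fasta")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(attr(truth, "sequences")), fa_path)
  invisible(c(paths, truth = truth_path, complexes = cpx_path,
              fasta = fa_path))
}
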