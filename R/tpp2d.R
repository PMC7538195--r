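## 2D thermal-proteome-profiling stability score: per-temperature
## normalization, fold changes against the 37.0 degC sample, the
## baseline-corrected summed heat-minus-mock difference, a 500-round
## replicate-resampling bootstrap, per-round z-standardization across
## proteins, and dual local/global FDR hit calling.

#' Normalize a TPP table one temperature at a time
#'
#' Applies [normalize_vs()] separately to the channel subset of each
#' temperature (conditions and replicates of one temperature are calibrated
#' against each other, never across temperatures, so the melting signal is
#' preserved).
#'
#' @param table raw `intensity_table` with a `temperature_C` metadata column.
#' @return A glog2-scale `intensity_table` with channels in original order.
#' @export
normalize_tpp <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  meta <- table$channel_meta
  if (is.null(meta$temperature_C) || all(is.na(meta$temperature_C)))
    stop("channel metadata lacks temperatures")
  v <- table$values
  for (Tj in unique(meta$temperature_C)) {
    idx <- which(meta$temperature_C == Tj)
    sub <- normalize_vs(subset_channels(table, meta$channel_id[idx]))
    v[, idx] <- sub$values
  }
  out <- table
  out$values <- v
  out$scale <- "glog2"
  out
}

#' Fold-change curves against the 37.0 degC sample
#'
#' For every condition and replicate, `fc(T) = log2 I(T) - log2 I(37.0)` of
#' the same condition and replicate; fc at 37.0 degC is 0 by construction.
#'
#' @param table normalized (log-scale) TPP `intensity_table`.
#' @return Object of class `tpp_curves`: list with `heat` and `mock` 3-d
#'   arrays (protein x temperature x replicate), `temperatures`, and
#'   `n_temps` (per protein, the number of temperatures quantified in every
#'   condition and replicate).
#' @export
fold_changes <- function(table) {
  stopifnot(inherits(table, "intensity_table"))
  if (table$scale == "raw") stop("fold changes require log-scale intensities")
  meta <- table$channel_meta
  temps <- sort(unique(meta$temperature_C))
  ref_T <- temps[1]
  arrays <- list()
  for (cond in c("mock", "heat")) {
    reps <- sort(unique(meta$replicate[meta$condition == cond]))
    a <- array(NA_real_,
               dim = c(nrow(table$values), length(temps), length(reps)),
               dimnames = list(rownames(table$values),
                               sprintf("%.1f", temps), paste0("r", reps)))
    for (ri in seq_along(reps)) {
      ref <- .channels_where(meta, condition = cond, replicate = reps[ri],
                             temperature_C = ref_T)
      if (length(ref) != 1)
        stop("missing 37.0 degC channel for ", cond, " replicate ", reps[ri])
      for (ti in seq_along(temps)) {
        ci <- .channels_where(meta, condition = cond, replicate = reps[ri],
                              temperature_C = temps[ti])
        if (length(ci) != 1) next
        a[, ti, ri] <- table$values[, ci] - table$values[, ref]
      }
    }
    arrays[[cond]] <- a
  }
  n_temps <- rowSums(
    apply(!is.na(arrays$heat), c(1, 2), all) &
      apply(!is.na(arrays$mock), c(1, 2), all))
  structure(list(heat = arrays$heat, mock = arrays$mock,
                 temperatures = temps, n_temps = n_temps),
            class = "tpp_curves")
}

#' Baseline-corrected thermal stability score
#'
#' For matched heat and mock fold-change curves: `d_T = fc_heat(T) -
#' fc_mock(T)`; the baseline `b` is the mean of `d` at the first two
#' (sub-heat-shock) gradient temperatures -- correcting for aggregation that
#' happened before the gradient -- and the score is the sum over all
#' quantified temperatures of `d_T - b`. Adding a constant to every `d_T`
#' leaves the score unchanged.
#'
#' @param heat_fc,mock_fc numeric vectors over the same ordered temperature
#'   grid (NA allowed beyond the first two temperatures).
#' @return The raw score; `NA` if either of the first two temperatures is
#'   unquantified.
#' @export
stability_score <- function(heat_fc, mock_fc) {
  if (length(heat_fc) != length(mock_fc))
    stop("curves must cover the same temperature grid")
  d <- heat_fc - mock_fc
  if (anyNA(d[1:2])) return(NA_real_)
  b <- mean(d[1:2])
  sum(d - b, na.rm = TRUE)
}

#' Replicate-resampling bootstrap of stability scores
#'
#' Per round, one heat replicate and one mock replicate are drawn uniformly
#' and independently FOR EACH TEMPERATURE (the same draw applies to every
#' protein, since a replicate is an experiment-level unit); composite curves
#' are assembled and scored with [stability_score()]. Deterministic under
#' the seed.
#'
#' @param curves a `tpp_curves` object.
#' @param n_rounds bootstrap rounds.
#' @param seed integer seed.
#' @return Matrix proteins x `n_rounds` of raw scores.
#' @export
bootstrap_scores <- function(curves, n_rounds = 500, seed) {
  stopifnot(inherits(curves, "tpp_curves"))
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  nT <- length(curves$temperatures)
  nP <- dim(curves$heat)[1]
  Rh <- dim(curves$heat)[3]
  Rm <- dim(curves$mock)[3]
  if (Rh < 1 || Rm < 1) stop("need >= 1 replicate per condition")
  heat2 <- matrix(curves$heat, nP, nT * Rh)
  mock2 <- matrix(curves$mock, nP, nT * Rm)
  h_idx <- matrix(sample.int(Rh, n_rounds * nT, replace = TRUE), n_rounds)
  m_idx <- matrix(sample.int(Rm, n_rounds * nT, replace = TRUE), n_rounds)
  scores <- matrix(NA_real_, nP, n_rounds,
                   dimnames = list(dimnames(curves$heat)[[1]], NULL))
  tseq <- seq_len(nT)
  for (r in seq_len(n_rounds)) {
    d <- heat2[, (h_idx[r, ] - 1) * nT + tseq, drop = FALSE] -
      mock2[, (m_idx[r, ] - 1) * nT + tseq, drop = FALSE]
    b <- rowMeans(d[, 1:2, drop = FALSE])
    scores[, r] <- rowSums(d - b, na.rm = TRUE)
    scores[is.na(b), r] <- NA_real_
  }
  scores
}

#' Per-round z-standardization and the bootstrap deviation test
#'
#' Within each bootstrap round, raw scores are standardized ACROSS PROTEINS
#' (mean 0, SD 1 per round); per protein, `mean_z` is the mean of its
#' standardized scores, `p_raw` a two-sided one-sample t-test of those
#' values against 0, `p_adj_local` the BH adjustment across proteins (the
#' "local FDR" of the hit rule), and `final_score` the across-protein
#' z-score of `mean_z`.
#'
#' @param boot matrix proteins x rounds from [bootstrap_scores()].
#' @return data.frame `protein_id`, `mean_z`, `p_raw`, `p_adj_local`,
#'   `final_score`; rounds dropped for zero across-protein SD are counted
#'   in `attr(, "n_rounds_dropped")`.
#' @export
zscore_and_test <- function(boot) {
  if (nrow(boot) < 10) stop("need >= 10 proteins")
  mu <- colMeans(boot, na.rm = TRUE)
  sdv <- apply(boot, 2, stats::sd, na.rm = TRUE)
  keep <- is.finite(sdv) & sdv > 0
  n_dropped <- sum(!keep)
  z <- sweep(sweep(boot[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep],
             `/`)
  mean_z <- rowMeans(z, na.rm = TRUE)
  nr <- rowSums(!is.na(z))
  sz <- apply(z, 1, stats::sd, na.rm = TRUE)
  t_stat <- mean_z / (sz / sqrt(nr))
  p_raw <- 2 * stats::pt(-abs(t_stat), nr - 1)
  p_raw[sz == 0] <- ifelse(mean_z[sz == 0] == 0, 1, 0)
  fs <- (mean_z - mean(mean_z, na.rm = TRUE)) /
    stats::sd(mean_z, na.rm = TRUE)
  out <- data.frame(protein_id = rownames(boot), mean_z = mean_z,
                    p_raw = p_raw, p_adj_local = bh_adjust(p_raw),
                    final_score = fs, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "n_rounds_dropped") <- n_dropped
  out
}

#' Global FDR from an empirical null on the final scores
#'
#' The null is `Normal(0, sigma0)` with `sigma0` the median absolute
#' deviation of the final scores rescaled by 1/0.6745 (i.e. the robust SD
#' determined by the central 50% of the score distribution). Two-sided
#' tail-area p-values from that null are converted to q-values by BH with
#' `pi0` estimated as the fraction of scores within one null SD divided by
#' the standard-normal central mass, clipped to `[0, 1]`.
#'
#' @param final_scores numeric vector (>= 50 values).
#' @return Numeric vector of q-values, with `sigma0` and `pi0` attributes.
#' @export
global_fdr <- function(final_scores) {
  x <- final_scores[!is.na(final_scores)]
  if (length(x) < 50) stop("need >= 50 final scores")
  sigma0 <- stats::mad(x)
  if (sigma0 == 0) stop("degenerate score distribution")
  p <- 2 * stats::pnorm(-abs(final_scores) / sigma0)
  pi0 <- mean(abs(x) <= sigma0) /
    (stats::pnorm(1) - stats::pnorm(-1))
  pi0 <- min(max(pi0, 0), 1)
  q <- pmin(1, pi0 * stats::p.adjust(p, method = "BH"))
  attr(q, "sigma0") <- sigma0
  attr(q, "pi0") <- pi0
  q
}

#' Dual-FDR hit calling
#'
#' A protein is a hit iff its local FDR (BH-adjusted bootstrap p) and its
#' global FDR are both below `alpha` AND it was quantified at >= `min_temps`
#' temperatures; the sign of the final score assigns stabilized (+) vs
#' destabilized (-).
#'
#' @param results data.frame from [zscore_and_test()] with a `global_fdr`
#'   column added.
#' @param n_temps named vector of per-protein quantified-temperature counts.
#' @param alpha dual FDR threshold.
#' @param min_temps minimum quantified temperatures.
#' @return Character vector: `"stabilized"`, `"destabilized"` or `"none"`.
#' @export
call_hits <- function(results, n_temps, alpha = 0.01, min_temps = 6) {
  nt <- n_temps[match(results$protein_id, names(n_temps))]
  gate <- !is.na(results$p_adj_local) & results$p_adj_local < alpha &
    !is.na(results$global_fdr) & results$global_fdr < alpha &
    !is.na(nt) & nt >= min_temps
  unname(ifelse(gate, ifelse(results$final_score > 0, "stabilized",
                             "destabilized"), "none"))
}

#' Run the full 2D-TPP stability-score pipeline
#'
#' Per-temperature normalization (unless the table is already on a log
#' scale), fold changes against 37.0 degC, the replicate-resampling
#' bootstrap, per-round z-standardization with the deviation test, global
#' FDR from the empirical null, and dual-FDR hit calling.
#'
#' @param table a TPP `intensity_table` (raw or already normalized).
#' @param n_rounds bootstrap rounds (500 by default).
#' @param seed integer seed for the bootstrap.
#' @param alpha dual FDR threshold for hit calling.
#' @param min_temps minimum quantified temperatures for a hit.
#' @return Object of class `tpp2d_fit`: the per-protein results data.frame
#'   (`protein_id`, `n_temps`, `mean_z`, `p_raw`, `p_adj_local`,
#'   `final_score`, `global_fdr`, `hit`) in `$results`, plus `curves` and
#'   the call parameters.
#' @export
tpp2d <- function(table, n_rounds = 500, seed, alpha = 0.01, min_temps = 6) {
  if (missing(seed)) stop("'seed' is required")
  if (table$scale == "raw") table <- normalize_tpp(table)
  curves <- fold_changes(table)
  boot <- bootstrap_scores(curves, n_rounds = n_rounds, seed = seed)
  res <- zscore_and_test(boot)
  q <- global_fdr(res$final_score)
  res$global_fdr <- as.numeric(q)
  res$n_temps <- curves$n_temps[match(res$protein_id,
                                      names(curves$n_temps))]
  res$hit <- call_hits(res, curves$n_temps, alpha = alpha,
                       min_temps = min_temps)
  res <- res[, c("protein_id", "n_temps", "mean_z", "p_raw", "p_adj_local",
                 "final_score", "global_fdr", "hit")]
  structure(list(results = res, curves = curves, n_rounds = n_rounds,
                 alpha = alpha, min_temps = min_temps,
                 sigma0 = attr(q, "sigma0"), pi0 = attr(q, "pi0")),
            class = "tpp2d_fit")
}

#' @export
print.tpp2d_fit <- function(x, ...) {
  h <- table(factor(x$results$hit,
                    levels = c("stabilized", "destabilized", "none")))
  cat(sprintf(
    "tpp2d_fit: %d proteins, %d bootstrap rounds\n", nrow(x$results),
    x$n_rounds))
  cat(sprintf(
    "  hits (local & global FDR < %g, >= %d temps): %d stabilized, %d destabilized\n",
    x$alpha, x$min_temps, h[["stabilized"]], h[["destabilized"]]))
  cat(sprintf("  empirical null: sigma0 = %.3f, pi0 = %.3f\n",
              x$sigma0, x$pi0))
  invisible(x)
}

#' @export
summary.tpp2d_fit <- function(object, ...) {
  print(object)
  cat("final score quartiles:\n")
  print(stats::quantile(object$results$final_score,
                        c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE))
  invisible(object)
}

#' @export
plot.tpp2d_fit <- function(x, ...) {
  fs <- x$results$final_score
  hit <- x$results$hit
  graphics::hist(fs, breaks = 60, col = "grey85", border = "grey60",
                 main = "2D-TPP thermal stability scores",
                 xlab = "final score (across-protein z)", ...)
  graphics::rug(fs[hit == "stabilized"], col = "firebrick", lwd = 1.5)
  graphics::rug(fs[hit == "destabilized"], col = "navy", lwd = 1.5)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
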