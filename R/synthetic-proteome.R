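## Synthetic proteome with planted ground truth.
##
## The generator encodes the study conditions the analysis assumes: a small
## fraction of proteins lose solubility on heat shock (aggregators) and
## recover linearly on the log2 scale; disaggregation rate is rank-correlated
## with the depth of the solubility drop and with disorder content;
## aggregator sequences are composition-shifted toward charged residues and
## away from branched/aromatic hydrophobics.

# Kyte-Doolittle hydropathy values, as printed per residue
.GRAVY <- c(R = -4.5, K = -3.9, N = -3.5, D = -3.5, Q = -3.5, E = -3.5,
            H = -3.2, P = -1.6, Y = -1.3, W = -0.9, S = -0.8, T = -0.7,
            G = -0.4, A = 1.8, M = 1.9, C = 2.5, F = 2.8, L = 3.8,
            V = 4.2, I = 4.5)

.AA <- names(.GRAVY)

# background amino-acid frequencies (human-proteome-like), normalized in use
.AA_FREQ <- c(A = 0.070, R = 0.056, N = 0.036, D = 0.047, C = 0.023,
              Q = 0.048, E = 0.071, G = 0.066, H = 0.026, I = 0.043,
              L = 0.100, K = 0.057, M = 0.021, F = 0.037, P = 0.063,
              S = 0.083, T = 0.054, W = 0.011, Y = 0.027, V = 0.060)

# composition shift planted in aggregators: enrich K, R, E; deplete I, L, V, F
.AGG_SHIFT <- c(K = 0.025, R = 0.020, E = 0.010,
                I = -0.015, L = -0.020, V = -0.015, F = -0.010)

## Iman-Conover: reorder columns of 'x' (independent marginals) so their rank
## correlation matrix closely matches 'target'. The normal scores are
## decorrelated exactly, then recorrelated; a few calibration iterations
## absorb the residual noise of the rank transform, so the induced sample
## Spearman is tight for every seed.
.iman_conover <- function(x, target, tol = 0.005, max_iter = 25) {
  n <- nrow(x); k <- ncol(x)
  if (n < 4 * k) return(x)  # too few rows to shape a rank structure
  scores <- qnorm(seq_len(n) / (n + 1))
  m0 <- vapply(seq_len(k), function(j) sample(scores), numeric(n))
  m0 <- m0 %*% solve(chol(stats::cor(m0)))
  sorted <- apply(x, 2, sort)
  adj <- target
  best <- NULL; best_err <- Inf
  for (it in seq_len(max_iter)) {
    ch <- tryCatch(chol(adj), error = function(e) NULL)
    if (is.null(ch)) break
    m <- m0 %*% ch
    out <- x
    for (j in seq_len(k))
      out[, j] <- sorted[, j][rank(m[, j], ties.method = "first")]
    realized <- stats::cor(out, method = "spearman")
    err <- max(abs(realized - target))
    if (err < best_err) {
      best <- out
      best_err <- err
    }
    if (err < tol) break
    adj <- adj + 0.8 * (target - realized)
    diag(adj) <- 1
  }
  best
}

#' Sigmoid melting model
#'
#' Fraction of a protein remaining soluble after brief exposure to
#' temperature `T`: a descending logistic in temperature with a non-melting
#' plateau, `plateau + (1 - plateau) / (1 + exp((T - Tm)/melt_slope))`.
#'
#' @param T temperature in degC (vectorized).
#' @param Tm melting midpoint in degC.
#' @param melt_slope positive scale of the sigmoid in degC.
#' @param plateau non-melting fraction in `[0, 1)`.
#' @return Soluble fraction in `(plateau, 1]`, strictly decreasing in `T`.
#' @export
melting_fraction <- function(T, Tm, melt_slope, plateau = 0) {
  if (any(melt_slope <= 0)) stop("'melt_slope' must be positive")
  if (any(plateau < 0 | plateau >= 1)) stop("'plateau' must lie in [0, 1)")
  plateau + (1 - plateau) / (1 + exp((T - Tm) / melt_slope))
}

#' Generate a synthetic proteome with planted ground truth
#'
#' Draws per-protein truth for every downstream stage: class (aggregator vs
#' soluble), the planted log2 solubility drop at heat shock, the linear
#' recovery slope, disorder fraction, abundance, synthesis kinetics, melting
#' parameters, an amino-acid sequence, annotation categories, and protein
#' complex memberships. Among aggregators, the rank correlations between
#' the drop and the recovery slope and between disorder and the slope are
#' induced at the requested targets by an Iman-Conover rearrangement, and are
#' preserved by any monotone downstream summary.
#'
#' @param n_proteins number of proteins (>= 50).
#' @param aggregator_fraction fraction of proteins planted as aggregators,
#'   in (0, 0.5).
#' @param seed integer seed; the output is a pure function of the arguments.
#' @param corr_drop_slope target Spearman correlation between the (negative)
#'   solubility drop and the recovery slope among aggregators.
#' @param corr_disorder_slope target Spearman correlation between disorder
#'   fraction and recovery slope among aggregators.
#' @param drop_offset,drop_meanlog,drop_sdlog the planted drop is
#'   `-(drop_offset + Lognormal(drop_meanlog, drop_sdlog))`; the offset keeps
#'   every aggregator strictly below the log2(2/3) calling cut.
#' @param slope_shape,slope_scale Gamma parameters of the recovery slope in
#'   solubility-units/hour; the default mean of 0.1/h leaves the median
#'   planted loss only partially recovered by 5 h, the slow disaggregation
#'   regime observed in human cells.
#' @param insoluble_fraction fraction of proteins planted with a pre-stress
#'   insoluble sub-population (total solubility below -0.6).
#' @param induced_fraction fraction of proteins with heat-induced synthesis
#'   (an HSP-like transcriptional response).
#' @param stabilized_fraction fraction of proteins planted with a heat-shock
#'   thermal-stability shift of `delta_tm_shift` degC.
#' @param delta_tm_shift melting-midpoint shift (degC) given to the
#'   stabilized subset.
#' @param n_complexes number of protein complexes to draw (each >= 5 members).
#' @param coherent_fraction fraction of complexes planted as coherent: all
#'   members are aggregators with adjacent solubility drops.
#' @param complex_aggregator_weight sampling weight of aggregators when
#'   drawing members of ordinary complexes (values > 1 plant the enrichment
#'   of aggregators in complexes).
#'
#' @return A data.frame of class `proteome_truth` (one row per protein) with
#'   attributes `sequences` (named character vector) and `complexes`
#'   (data.frame `complex_id`, `protein_id`).
#' @export
generate_proteome <- function(n_proteins = 2000, aggregator_fraction = 0.063,
                              seed,
                              corr_drop_slope = -0.42,
                              corr_disorder_slope = 0.25,
                              drop_offset = 0.6,
                              drop_meanlog = log(0.5), drop_sdlog = 0.5,
                              slope_shape = 2, slope_scale = 0.05,
                              insoluble_fraction = 0.05,
                              induced_fraction = 0.005,
                              stabilized_fraction = 0,
                              delta_tm_shift = 3,
                              n_complexes = 40,
                              coherent_fraction = 0.25,
                              complex_aggregator_weight = 3) {
  if (missing(seed)) stop("'seed' is required")
  if (n_proteins < 50) stop("'n_proteins' must be >= 50")
  if (aggregator_fraction <= 0 || aggregator_fraction >= 0.5)
    stop("'aggregator_fraction' must lie in (0, 0.5)")
  if (insoluble_fraction < 0 || insoluble_fraction >= 1 ||
      induced_fraction < 0 || induced_fraction >= 1 ||
      stabilized_fraction < 0 || stabilized_fraction >= 1)
    stop("planted fractions must lie in [0, 1)")
  set.seed(seed)

  n <- n_proteins
  n_agg <- round(n * aggregator_fraction)
  ids <- sprintf("P%05d", seq_len(n))
  class <- rep("soluble", n)
  class[seq_len(n_agg)] <- "aggregator"

  ## --- aggregator drop / slope / disorder with planted rank correlations
  drop_mag <- drop_offset + stats::rlnorm(n_agg, drop_meanlog, drop_sdlog)
  slope_agg <- stats::rgamma(n_agg, shape = slope_shape, scale = slope_scale)
  dis_agg <- stats::rbeta(n_agg, 3, 4)
  # targets on (drop, slope) translate to (+|r|) on (|drop|, slope)
  a <- -corr_drop_slope
  b <- corr_disorder_slope
  target <- rbind(c(1, a, a * b),
                  c(a, 1, b),
                  c(a * b, b, 1))
  planted <- .iman_conover(cbind(drop_mag, slope_agg, dis_agg), target)
  true_drop <- rep(0, n)
  true_slope <- rep(0, n)
  disorder <- stats::rbeta(n, 2, 6)
  true_drop[seq_len(n_agg)] <- -planted[, 1]
  true_slope[seq_len(n_agg)] <- planted[, 2]
  disorder[seq_len(n_agg)] <- planted[, 3]

  ## --- abundance, synthesis, induction, melting
  abundance <- stats::rlnorm(n, log(1e6), 1.2)
  synthesis_rate <- stats::rlnorm(n, log(0.25), 0.5)
  induction <- rep(1, n)
  idx_ind <- sample.int(n, round(n * induced_fraction))
  induction[idx_ind] <- 2^stats::runif(length(idx_ind), 3, 5)
  Tm <- pmin(pmax(stats::rnorm(n, 50, 4), 41), 62)
  melt_slope <- stats::runif(n, 1.2, 2.2)
  plateau <- stats::runif(n, 0.02, 0.15)
  delta_Tm <- rep(0, n)
  idx_st <- sample.int(n, round(n * stabilized_fraction))
  delta_Tm[idx_st] <- delta_tm_shift

  ## --- pre-stress total solubility (NP-40/SDS log2 ratio)
  insol <- stats::runif(n) < insoluble_fraction
  total_sol_pre <- -pmin(stats::rexp(n, rate = 10), 0.55)
  total_sol_pre[insol] <- -(0.65 + stats::rexp(sum(insol), rate = 2.5))

  ## --- annotations (independent of class, as observed for chromosomes)
  locs <- c("cytosol", "nucleus", "mitochondrion", "ER",
            "plasma membrane", "secreted")
  localization <- sample(locs, n, replace = TRUE,
                         prob = c(0.35, 0.25, 0.12, 0.10, 0.10, 0.08))
  chromosome <- sample(c(as.character(1:22), "X"), n, replace = TRUE)

  ## --- sequences: per-class multinomial draws, lognormal lengths
  freq_sol <- .AA_FREQ[.AA] / sum(.AA_FREQ)
  freq_agg <- freq_sol
  freq_agg[names(.AGG_SHIFT)] <- freq_agg[names(.AGG_SHIFT)] + .AGG_SHIFT
  freq_agg <- pmax(freq_agg, 1e-4) / sum(pmax(freq_agg, 1e-4))
  len <- round(ifelse(class == "aggregator",
                      stats::rlnorm(n, log(480), 0.30),
                      stats::rlnorm(n, log(380), 0.35)))
  len <- pmax(len, 30)
  sequences <- vapply(seq_len(n), function(i) {
    p <- if (class[i] == "aggregator") freq_agg else freq_sol
    paste(sample(.AA, len[i], replace = TRUE, prob = p), collapse = "")
  }, character(1))
  names(sequences) <- ids

  mw <- molecular_weight(sequences)

  ## --- complexes
  complexes <- .generate_complexes(ids, class, true_drop, n_complexes,
                                   coherent_fraction,
                                   complex_aggregator_weight)

  truth <- data.frame(
    protein_id = ids, class = class, true_drop = true_drop,
    true_slope = true_slope, insoluble_subpop = insol,
    total_sol_pre = total_sol_pre, abundance = abundance,
    synthesis_rate = synthesis_rate, induction = induction,
    Tm = Tm, melt_slope = melt_slope, plateau = plateau,
    delta_Tm = delta_Tm, disorder_fraction = disorder, mw = mw,
    localization = localization, chromosome = chromosome,
    stringsAsFactors = FALSE)
  attr(truth, "sequences") <- sequences
  attr(truth, "complexes") <- complexes
  class(truth) <- c("proteome_truth", "data.frame")
  truth
}

## complexes: 'coherent' ones take aggregators adjacent in drop order
.generate_complexes <- function(ids, cls, drop, n_complexes,
                                coherent_fraction, w_agg) {
  if (n_complexes == 0)
    return(data.frame(complex_id = character(0), protein_id = character(0),
                      stringsAsFactors = FALSE))
  agg_idx <- which(cls == "aggregator")
  sizes <- sample(5:15, n_complexes, replace = TRUE)
  n_coh <- round(n_complexes * coherent_fraction)
  out <- vector("list", n_complexes)
  agg_by_drop <- agg_idx[order(drop[agg_idx])]
  w <- ifelse(cls == "aggregator", w_agg, 1)
  for (j in seq_len(n_complexes)) {
    sz <- sizes[j]
    if (j <= n_coh && length(agg_by_drop) >= sz) {
      start <- sample.int(length(agg_by_drop) - sz + 1, 1)
      members <- agg_by_drop[start:(start + sz - 1)]
    } else {
      members <- sample(seq_along(ids), sz, prob = w)
    }
    out[[j]] <- data.frame(complex_id = sprintf("CPX%03d", j),
                           protein_id = ids[members],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' @export
print.proteome_truth <- function(x, ...) {
  cat(sprintf("proteome_truth: %d proteins (%d aggregators, %d soluble)\n",
              nrow(x), sum(x$class == "aggregator"),
              sum(x$class == "soluble")))
  cat(sprintf("  complexes: %d; sequences attached: %s\n",
              length(unique(attr(x, "complexes")$complex_id)),
              !is.null(attr(x, "sequences"))))
  invisible(x)
}
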