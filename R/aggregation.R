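## Aggregator calling: empirical-Bayes moderated t on replicate-paired
## heat - mock solubilities at t = 0, BH adjustment, and the conjunction
## rule (adjusted p < 0.05 AND solubility < log2(2/3)).

#' Fit the empirical-Bayes variance prior (moderation parameters)
#'
#' Method-of-moments fit of a scaled inverse-chi-square prior to the
#' per-protein sample variances, on the log scale: under the hierarchical
#' model `s_g^2 ~ s0^2 * F(d, d0)`, the mean and variance of `log s_g^2` are
#' matched to their digamma/trigamma expressions and solved for `d0` and
#' `s0^2`. If the empirical spread of `log s_g^2` does not exceed
#' `trigamma(d/2)` (the spread expected from sampling alone), the prior
#' degrees of freedom are infinite and `s0^2` is the mean sample variance.
#'
#' @param s2 per-protein sample variances (finite, positive; >= 10 values).
#' @param df common residual degrees of freedom (`n - 1`).
#' @return List with `d0` (prior df, possibly `Inf`) and `s0_sq`.
#' @export
estimate_moderation <- function(s2, df) {
  s2 <- s2[is.finite(s2)]
  if (all(s2 == 0)) stop("all sample variances are zero")
  s2 <- s2[s2 > 0]
  if (length(s2) < 10)
    stop("need >= 10 proteins with finite positive variance")
  if (df < 1) stop("'df' must be >= 1")
  z <- log(s2)
  evar <- stats::var(z) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    return(list(d0 = Inf, s0_sq = mean(s2)))
  }
  d0 <- 2 * .trigamma_inverse(evar)
  s0_sq <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

## Newton inversion of the trigamma function (monotone decreasing on (0,Inf))
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Moderated one-sample t-statistic
#'
#' Shrinks the per-protein variance toward the prior:
#' `s_post^2 = (d0 * s0^2 + d * s_g^2) / (d0 + d)` with `d = n - 1`, then
#' `t = mean / (s_post / sqrt(n))`, two-sided p from a t distribution with
#' `d0 + d` degrees of freedom (standard normal when `d0` is infinite).
#' With `d0 = 0` this reduces to the ordinary one-sample t-test.
#'
#' @param x numeric matrix (proteins x replicates) or vector of
#'   replicate-paired differences.
#' @param params list with `d0` and `s0_sq` from [estimate_moderation()].
#' @return data.frame `mean`, `n`, `t_mod`, `p_raw` (rows with `n < 2` have
#'   `NA` statistics and are counted in `attr(, "n_skipped")`).
#' @export
moderated_t <- function(x, params) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  d0 <- params$d0; s0 <- params$s0_sq
  if (is.null(d0) || is.null(s0) || s0 <= 0) stop("invalid moderation params")
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  s2 <- apply(x, 1, stats::var, na.rm = TRUE)
  ok <- n >= 2
  d <- n - 1
  s_post2 <- if (is.infinite(d0)) rep(s0, nrow(x)) else
    (d0 * s0 + d * s2) / (d0 + d)
  t_mod <- m / sqrt(s_post2 / n)
  df_tot <- d0 + d
  p <- ifelse(is.infinite(df_tot), 2 * stats::pnorm(-abs(t_mod)),
              2 * stats::pt(-abs(t_mod), df_tot))
  t_mod[!ok] <- NA_real_
  p[!ok] <- NA_real_
  out <- data.frame(mean = m, n = n, t_mod = t_mod, p_raw = p)
  rownames(out) <- rownames(x)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment, returned in input order.
#'
#' @param p p-values in `[0, 1]` (NA allowed, propagated).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call aggregators from solubility profiles
#'
#' A protein is an aggregator iff its BH-adjusted moderated-t p-value at the
#' heat-shock time point (t = 0) is below `alpha` AND its mean solubility is
#' below `fc_cut` (default `log2(2/3)`, i.e. fold change < 2/3); both cuts
#' are strict.
#'
#' @param profiles a `solubility_profiles` object.
#' @param alpha significance cut on the BH-adjusted p-value.
#' @param fc_cut log2 fold-change cut (strict, negative).
#' @param time_h time point tested (default 0, the post-shock sample).
#' @param moderation `TRUE` to fit the empirical-Bayes prior, `FALSE` (or a
#'   list with `d0`, `s0_sq`) to use the ordinary t-test / fixed prior.
#' @param total_solubility optional matrix from
#'   [compute_total_solubility()]; when given, pre-shock insoluble
#'   sub-populations are flagged.
#' @return data.frame of class `aggregator_calls`: `protein_id`,
#'   `solubility_hs`, `t_mod`, `p_raw`, `p_adj`, `class`,
#'   `insoluble_subpop`.
#' @export
call_aggregators <- function(profiles, alpha = 0.05, fc_cut = log2(2 / 3),
                             time_h = 0, moderation = TRUE,
                             total_solubility = NULL) {
  stopifnot(inherits(profiles, "solubility_profiles"))
  tkey <- as.character(time_h)
  if (!tkey %in% dimnames(profiles$s)[[2]])
    stop("time point ", time_h, " not present in profiles")
  x <- profiles$s[, tkey, , drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- rowSums(!is.na(x))
  if (isTRUE(moderation)) {
    d_use <- max(1, stats::median(n[n >= 2]) - 1)
    s2 <- apply(x[n - 1 == d_use, , drop = FALSE], 1, stats::var,
                na.rm = TRUE)
    params <- estimate_moderation(s2, d_use)
  } else if (is.list(moderation)) {
    params <- moderation
  } else {
    params <- list(d0 = 0, s0_sq = 1)  # d0 = 0: ordinary t
  }
  mt <- moderated_t(x, params)
  p_adj <- bh_adjust(mt$p_raw)
  cls <- ifelse(!is.na(p_adj) & p_adj < alpha & mt$mean < fc_cut,
                "aggregator", "soluble")
  insol <- rep(NA, nrow(mt))
  if (!is.null(total_solubility)) {
    fl <- flag_insoluble_subpop(total_solubility)
    insol <- fl[match(profiles$protein_ids, names(fl))]
  }
  out <- data.frame(protein_id = profiles$protein_ids,
                    solubility_hs = mt$mean, t_mod = mt$t_mod,
                    p_raw = mt$p_raw, p_adj = p_adj, class = cls,
                    insoluble_subpop = insol, stringsAsFactors = FALSE)
  attr(out, "moderation") <- params
  attr(out, "alpha") <- alpha
  attr(out, "fc_cut") <- fc_cut
  class(out) <- c("aggregator_calls", "data.frame")
  out
}

#' @export
print.aggregator_calls <- function(x, ...) {
  cat(sprintf(
    "aggregator_calls: %d proteins, %d aggregators (adj. p < %g and solubility < %.3f)\n",
    nrow(x), sum(x$class == "aggregator"), attr(x, "alpha"),
    attr(x, "fc_cut")))
  invisible(x)
}

#' @export
summary.aggregator_calls <- function(object, ...) {
  mod <- attr(object, "moderation")
  cat("Aggregator calling (moderated t + fold-change gate)\n")
  cat(sprintf("  proteins tested:  %d\n", sum(!is.na(object$p_adj))))
  cat(sprintf("  aggregators:      %d\n",
              sum(object$class == "aggregator")))
  cat(sprintf("  soluble:          %d\n", sum(object$class == "soluble")))
  if (!all(is.na(object$insoluble_subpop)))
    cat(sprintf("  insoluble subpop: %d\n",
                sum(object$insoluble_subpop, na.rm = TRUE)))
  cat(sprintf("  prior: d0 = %s, s0^2 = %.4g\n",
              format(mod$d0, digits = 4), mod$s0_sq))
  invisible(object)
}

#' Flag pre-stress insoluble sub-populations
#'
#' `TRUE` iff the pre-shock total solubility (NP-40/SDS log2 ratio) is
#' strictly below `cut` (default -0.6).
#'
#' @param total_solubility matrix from [compute_total_solubility()] with a
#'   `"preshock"` column, or a named numeric vector of pre-shock values.
#' @param cut strict threshold.
#' @return Named logical vector (NA where pre-shock value missing, with the
#'   count reported via `attr(, "n_undefined")`).
#' @export
flag_insoluble_subpop <- function(total_solubility, cut = -0.6) {
  if (is.matrix(total_solubility)) {
    if (!"preshock" %in% colnames(total_solubility))
      stop("no 'preshock' condition in total solubility")
    ts <- total_solubility[, "preshock"]
  } else ts <- total_solubility
  out <- ts < cut
  attr(out, "n_undefined") <- sum(is.na(ts))
  out
}
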