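## Disaggregation kinetics: per-protein linear fits of mean solubility over
## the recovery time course; the slope is the disaggregation-rate estimate.

#' Ordinary least-squares slope of a solubility trajectory
#'
#' Closed-form OLS of mean solubility against time:
#' `slope = sum((t - tbar)(s - sbar)) / sum((t - tbar)^2)`.
#'
#' @param s mean solubility per time point (NA allowed).
#' @param timepoints matching time points in hours.
#' @return List with `slope`, `intercept`, `n_points`; slope/intercept are
#'   `NA` when fewer than 3 points are available.
#' @export
fit_slope <- function(s, timepoints) {
  ok <- !is.na(s)
  n <- sum(ok)
  if (n < 3)
    return(list(slope = NA_real_, intercept = NA_real_, n_points = n))
  t <- timepoints[ok]; y <- s[ok]
  tc <- t - mean(t)
  slope <- sum(tc * (y - mean(y))) / sum(tc^2)
  list(slope = slope, intercept = mean(y) - slope * mean(t), n_points = n)
}

#' Fit disaggregation slopes for all proteins
#'
#' Applies [fit_slope()] to each protein's across-replicate mean solubility
#' trajectory.
#'
#' @param profiles a `solubility_profiles` object.
#' @return data.frame `protein_id`, `slope`, `intercept`, `n_points`;
#'   proteins with fewer than 3 quantified time points carry `NA` and are
#'   counted in `attr(, "n_unfit")`.
#' @export
fit_slopes <- function(profiles) {
  stopifnot(inherits(profiles, "solubility_profiles"))
  tps <- profiles$timepoints
  res <- apply(profiles$mean_s, 1, fit_slope, timepoints = tps)
  out <- data.frame(
    protein_id = profiles$protein_ids,
    slope = vapply(res, `[[`, numeric(1), "slope"),
    intercept = vapply(res, `[[`, numeric(1), "intercept"),
    n_points = vapply(res, `[[`, numeric(1), "n_points"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_unfit") <- sum(is.na(out$slope))
  out
}

#' Shapiro-Wilk normality gate
#'
#' `TRUE` iff the Shapiro-Wilk p-value is at or above 0.05. A degenerate
#' (constant) sample is not testable and is reported as non-normal.
#'
#' @param x numeric sample, `3 <= length(x) <= 5000` after NA removal.
#' @return Logical; the p-value in `attr(, "p")` (`NA` if degenerate).
#' @export
assess_normality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000)
    stop("sample size out of the Shapiro-Wilk range [3, 5000]")
  if (stats::sd(x) == 0) {
    out <- FALSE
    attr(out, "p") <- NA_real_
    return(out)
  }
  p <- stats::shapiro.test(x)$p.value
  out <- p >= 0.05
  attr(out, "p") <- p
  out
}

#' Correlate disaggregation slopes with protein features
#'
#' Per feature: Pearson correlation if both the slope vector and the feature
#' pass the Shapiro-Wilk gate, Spearman otherwise; BH adjustment across the
#' tested features. Constant features are excluded (and reported) before
#' adjustment.
#'
#' @param slopes data.frame from [fit_slopes()] (restricted by the caller to
#'   aggregators) or a named numeric vector of slopes.
#' @param features data.frame of per-protein features with rownames (or a
#'   `protein_id` column) matching slope protein identifiers.
#' @param min_n minimum paired observations per feature.
#' @return data.frame `feature`, `method`, `n`, `coefficient`, `p_raw`,
#'   `p_adj`; skipped features listed in `attr(, "excluded")`.
#' @export
correlate_features <- function(slopes, features, min_n = 10) {
  if (is.data.frame(slopes)) {
    sl <- stats::setNames(slopes$slope, slopes$protein_id)
  } else sl <- slopes
  if (!is.null(features$protein_id)) {
    rownames(features) <- features$protein_id
    features$protein_id <- NULL
  }
  common <- intersect(names(sl), rownames(features))
  sl <- sl[common]
  features <- features[common, , drop = FALSE]
  rows <- list()
  excluded <- character(0)
  for (f in colnames(features)) {
    x <- features[[f]]
    ok <- !is.na(sl) & !is.na(x)
    if (sum(ok) < min_n) {
      excluded <- c(excluded, f)
      next
    }
    if (stats::sd(x[ok]) == 0) {
      excluded <- c(excluded, f)
      next
    }
    method <- if (isTRUE(assess_normality(sl[ok])[1]) &&
                  isTRUE(assess_normality(x[ok])[1])) "pearson" else
                    "spearman"
    ct <- suppressWarnings(
      stats::cor.test(sl[ok], x[ok], method = method,
                      exact = FALSE))
    rows[[f]] <- data.frame(feature = f, method = method, n = sum(ok),
                            coefficient = unname(ct$estimate),
                            p_raw = ct$p.value, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    out <- data.frame(feature = character(0), method = character(0),
                      n = integer(0), coefficient = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0))
  } else {
    out <- do.call(rbind, rows)
    out$p_adj <- bh_adjust(out$p_raw)
    rownames(out) <- NULL
  }
  attr(out, "excluded") <- excluded
  out
}

#' Tag slope deciles among aggregators
#'
#' The lowest `ceiling(0.1 n)` slopes are `bottom10` (non-disaggregating),
#' the highest `ceiling(0.1 n)` are `top10` (fast-disaggregating), the rest
#' `middle80`. Ties are broken by stable protein-identifier order, so the
#' tags always partition the input.
#'
#' @param slopes named numeric vector of slopes (names = protein ids) or a
#'   data.frame from [fit_slopes()].
#' @return Named character vector of tags in input order.
#' @export
tag_deciles <- function(slopes) {
  if (is.data.frame(slopes))
    slopes <- stats::setNames(slopes$slope, slopes$protein_id)
  slopes <- slopes[!is.na(slopes)]
  n <- length(slopes)
  if (n < 10) stop("need >= 10 slopes to tag deciles")
  k <- ceiling(0.1 * n)
  ord <- order(slopes, names(slopes))  # ascending; ties by identifier
  tags <- rep("middle80", n)
  tags[ord[seq_len(k)]] <- "bottom10"
  tags[ord[(n - k + 1):n]] <- "top10"
  stats::setNames(tags, names(slopes))
}
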