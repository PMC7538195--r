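## Quality filtering, batch correction, variance-stabilizing calibration,
## coefficient transfer and left-censored imputation.

#' Quality-filter proteins by peptide support and replicate coverage
#'
#' Retains proteins backed by at least `min_unique_peptides` unique peptides
#' in at least `min_replicates` biological replicates AND quantified (non-NA)
#' in at least `min_replicates` replicates of every condition present in the
#' channel metadata. Row order of retained proteins is preserved.
#'
#' @param table an `intensity_table` with `peptide_support`.
#' @param min_unique_peptides minimum unique-peptide count per replicate.
#' @param min_replicates minimum number of qualifying replicates.
#' @return The filtered `intensity_table`.
#' @export
filter_quality <- function(table, min_unique_peptides = 2,
                           min_replicates = 2) {
  stopifnot(inherits(table, "intensity_table"))
  if (nrow(table$values) == 0) return(table)
  if (is.null(table$peptide_support))
    stop("'peptide_support' is required for quality filtering")
  ps_ok <- rowSums(table$peptide_support >= min_unique_peptides) >=
    min_replicates
  meta <- table$channel_meta
  cond_ok <- rep(TRUE, nrow(table$values))
  for (cond in unique(meta$condition)) {
    idx <- which(meta$condition == cond)
    reps <- meta$replicate[idx]
    # replicates of this condition in which the protein has >= 1 value
    quant <- vapply(unique(reps), function(r) {
      rowSums(!is.na(table$values[, idx[reps == r], drop = FALSE])) > 0
    }, logical(nrow(table$values)))
    if (is.null(dim(quant))) quant <- matrix(quant, nrow = 1)
    cond_ok <- cond_ok & rowSums(quant) >= min_replicates
  }
  keep <- ps_ok & cond_ok
  out <- table
  out$values <- table$values[keep, , drop = FALSE]
  out$peptide_support <- table$peptide_support[keep, , drop = FALSE]
  out
}

#' Remove additive batch effects on the log scale
#'
#' Fits, per protein, the additive model value = protein mean + batch offset
#' by least squares and subtracts the batch offsets: each cell is adjusted by
#' (its protein's batch mean - its protein's grand mean), so per-batch means
#' are equalized and the per-protein grand mean is preserved. With a single
#' batch the table is returned unchanged. Applying the correction twice
#' equals applying it once.
#'
#' @param table an `intensity_table` on a log scale.
#' @param batch batch label per channel; defaults to the metadata column.
#' @return The corrected `intensity_table`.
#' @export
correct_batches <- function(table, batch = table$channel_meta$batch) {
  stopifnot(inherits(table, "intensity_table"))
  if (table$scale == "raw")
    stop("batch correction requires log-scale intensities")
  batch <- as.character(batch)
  if (length(batch) != ncol(table$values))
    stop("'batch' must give one label per channel")
  lv <- unique(batch)
  if (any(!lv %in% batch)) stop("batch with zero channels")
  if (length(lv) < 2) return(table)
  v <- table$values
  grand <- rowMeans(v, na.rm = TRUE)
  for (b in lv) {
    idx <- batch == b
    mb <- rowMeans(v[, idx, drop = FALSE], na.rm = TRUE)
    v[, idx] <- v[, idx, drop = FALSE] - (mb - grand)
  }
  out <- table
  out$values <- v
  out
}

#' Generalized log2
#'
#' `glog2(u) = log2(u + sqrt(u^2 + 1))`: strictly increasing, defined for all
#' reals, and asymptotically `log2(2u)` for large `u`.
#'
#' @param u numeric.
#' @return `glog2(u)`.
#' @export
glog2 <- function(u) log2(u + sqrt(u^2 + 1))

#' Variance-stabilizing calibration (vsn-style affine + glog)
#'
#' Each channel `c` is transformed by `x -> glog2((x - a_c) / b_c)` with the
#' affine coefficients chosen so the channel's 10th-90th percentile quantiles
#' match a reference channel's by least squares (regression of the channel's
#' quantiles on the reference's). This preserves within-channel rank order
#' exactly and equalizes channel scale and offset before ratio computation.
#'
#' @param table an `intensity_table` on the raw scale.
#' @param reference channel id of the reference; defaults to the channel
#'   whose median intensity is closest to the median of channel medians.
#' @param probs quantile probabilities matched between channels.
#' @return The transformed `intensity_table` (scale `"glog2"`) with the
#'   per-channel coefficients in `attr(, "vs_coefficients")` (data.frame
#'   `channel_id`, `a`, `b`) for reuse on a matched table.
#' @export
normalize_vs <- function(table, reference = NULL,
                         probs = seq(0.1, 0.9, by = 0.05)) {
  stopifnot(inherits(table, "intensity_table"))
  if (table$scale != "raw") stop("normalize_vs expects raw intensities")
  v <- table$values
  n_obs <- colSums(!is.na(v))
  if (any(n_obs == 0)) stop("channel with no observed values")
  meds <- apply(v, 2, stats::median, na.rm = TRUE)
  if (is.null(reference)) {
    reference <- colnames(v)[which.min(abs(meds - stats::median(meds)))]
  }
  if (!reference %in% colnames(v)) stop("unknown reference channel")
  qr <- stats::quantile(v[, reference], probs, na.rm = TRUE, names = FALSE)
  coefs <- data.frame(channel_id = colnames(v),
                      channel_key = .channel_key(table$channel_meta),
                      a = 0, b = 1, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(v))) {
    qc <- stats::quantile(v[, j], probs, na.rm = TRUE, names = FALSE)
    # least squares for q_c = a + b * q_ref, so (x - a)/b maps onto reference
    b <- stats::cov(qc, qr) / stats::var(qr)
    a <- mean(qc) - b * mean(qr)
    if (!is.finite(b) || b <= 0) {
      warning("non-positive scale fit for channel ", colnames(v)[j],
              "; falling back to scale-only calibration")
      b <- meds[j] / meds[reference]
      a <- 0
    }
    coefs$a[j] <- a
    coefs$b[j] <- b
  }
  out <- .apply_vs(table, coefs)
  attr(out, "vs_coefficients") <- coefs
  out
}

## physical TMT channel identity: everything but the SILAC label (light and
## heavy reporter ions of one channel share the calibration)
.channel_key <- function(meta) {
  cols <- intersect(c("condition", "time_h", "replicate", "lysis",
                      "temperature_C"), names(meta))
  do.call(paste, c(meta[cols], sep = "|"))
}

.apply_vs <- function(table, coefs) {
  v <- table$values
  idx <- match(colnames(v), coefs$channel_id)
  if (anyNA(idx) && !is.null(coefs$channel_key))
    idx[is.na(idx)] <- match(.channel_key(table$channel_meta),
                             coefs$channel_key)[is.na(idx)]
  if (anyNA(idx)) stop("missing calibration coefficient for channel(s): ",
                       paste(colnames(v)[is.na(idx)], collapse = ", "))
  v <- glog2(sweep(sweep(v, 2, coefs$a[idx], `-`), 2, coefs$b[idx], `/`))
  out <- table
  out$values <- v
  out$scale <- "glog2"
  out
}

#' Apply light-derived calibration coefficients to a heavy-label table
#'
#' Transforms the heavy-SILAC table with the `(a_c, b_c)` coefficients fitted
#' on the light fraction (matched by channel identity), with no
#' re-estimation: the accumulation of heavy label over the time course is a
#' real signal and must not be normalized away.
#'
#' @param heavy_table raw `intensity_table` of the heavy fraction.
#' @param coefficients the `vs_coefficients` data.frame from
#'   [normalize_vs()] (or a table carrying that attribute).
#' @return The transformed `intensity_table` (scale `"glog2"`).
#' @export
transfer_normalization <- function(heavy_table, coefficients) {
  stopifnot(inherits(heavy_table, "intensity_table"))
  if (heavy_table$scale != "raw")
    stop("transfer_normalization expects raw intensities")
  if (inherits(coefficients, "intensity_table"))
    coefficients <- attr(coefficients, "vs_coefficients")
  if (!is.data.frame(coefficients))
    stop("'coefficients' must be the vs_coefficients data.frame")
  .apply_vs(heavy_table, coefficients)
}

#' Impute missing values from a down-shifted Gaussian
#'
#' Each missing cell in channel `c` is drawn from
#' `Normal(mu_c - downshift * sigma_c, (width * sigma_c)^2)` where `mu_c` and
#' `sigma_c` are the channel's observed mean and SD -- the standard
#' left-censored imputation for label-based proteomics, matching the
#' missing-at-low-intensity mechanism. Observed cells are untouched.
#'
#' @param table an `intensity_table` on a log scale.
#' @param downshift shift of the imputation distribution, in channel SDs.
#' @param width SD of the imputation distribution, in channel SDs.
#' @param seed integer seed; imputation is deterministic given the seed.
#' @return The imputed `intensity_table`.
#' @export
impute_missing <- function(table, downshift = 1.8, width = 0.3, seed) {
  stopifnot(inherits(table, "intensity_table"))
  if (table$scale == "raw")
    stop("imputation requires log-scale intensities")
  v <- table$values
  if (!anyNA(v)) return(table)
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  for (j in seq_len(ncol(v))) {
    miss <- is.na(v[, j])
    if (!any(miss)) next
    obs <- v[!miss, j]
    if (length(obs) < 3)
      stop("channel ", colnames(v)[j],
           " has fewer than 3 observed values; cannot impute")
    mu <- mean(obs); s <- stats::sd(obs)
    v[miss, j] <- stats::rnorm(sum(miss), mu - downshift * s, width * s)
  }
  out <- table
  out$values <- v
  out
}
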