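# in-code fixtures shared across test files

# minimal intensity table: proteins x channels with free-form metadata
make_table <- function(values, condition, time_h = NA_real_, silac = "light",
                       replicate = 1L, batch = "b1", lysis = "NP40",
                       temperature_C = NA_real_,
                       scale = "log2", peptide_support = NULL) {
  n_chan <- ncol(values)
  meta <- data.frame(
    channel_id = if (is.null(colnames(values)))
      paste0("ch", seq_len(n_chan)) else colnames(values),
    condition = rep_len(condition, n_chan),
    time_h = rep_len(time_h, n_chan),
    silac = rep_len(silac, n_chan),
    replicate = rep_len(replicate, n_chan),
    batch = rep_len(batch, n_chan),
    lysis = rep_len(lysis, n_chan),
    temperature_C = rep_len(temperature_C, n_chan),
    stringsAsFactors = FALSE)
  colnames(values) <- meta$channel_id
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  intensity_table(values, meta, peptide_support = peptide_support,
                  scale = scale)
}

# solubility_profiles built directly from a replicate array
make_profiles <- function(s, timepoints) {
  # s: protein x time x replicate
  dimnames(s)[[2]] <- as.character(timepoints)
  mean_s <- apply(s, c(1, 2), mean, na.rm = TRUE)
  mean_s[is.nan(mean_s)] <- NA_real_
  structure(list(s = s, mean_s = mean_s, timepoints = timepoints,
                 protein_ids = dimnames(s)[[1]]),
            class = "solubility_profiles")
}

# replicate-difference profiles at t = 0 only, from a matrix of differences
profiles_from_t0 <- function(diffs) {
  if (is.null(rownames(diffs)))
    rownames(diffs) <- sprintf("P%04d", seq_len(nrow(diffs)))
  s <- array(diffs, dim = c(nrow(diffs), 1, ncol(diffs)),
             dimnames = list(rownames(diffs), "0", NULL))
  make_profiles(s, 0)
}

# two-sided Fisher p by full enumeration over tables with fixed margins,
# using the same definition as the implementation contract: sum of
# probabilities of all tables at most as probable as the observed one
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exact two-sided rank-sum p by full enumeration of group assignments
wilcox_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r_obs <- sum(rank(pooled)[seq_len(n1)])
  idx <- utils::combn(length(pooled), n1)
  r_all <- apply(idx, 2, function(i) sum(rank(pooled)[i]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(r_all - mu) >= abs(r_obs - mu) - 1e-9)
}
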