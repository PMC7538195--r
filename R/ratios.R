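## Ratio-type summaries: solubility, total solubility, synthesis accumulation.

#' Per-protein solubility profiles (heat/mock log2 ratios)
#'
#' Solubility at time `t`, replicate `r` is the replicate-matched difference
#' `value(heat, t, r) - value(mock, t, r)` on the log scale, computed on the
#' light (pre-existing) fraction by default.
#'
#' @param table a normalized (log-scale) `intensity_table` with matched heat
#'   and mock channels per time point and replicate.
#' @param silac which SILAC fraction to use.
#' @param lysis which lysis channels to use (soluble fraction = `"NP40"`).
#' @return An object of class `solubility_profiles`: list with `s` (3-d array
#'   protein x time x replicate), `mean_s` (matrix protein x time of
#'   across-replicate means), `timepoints`, `protein_ids`.
#' @export
compute_solubility <- function(table, silac = "light", lysis = "NP40") {
  stopifnot(inherits(table, "intensity_table"))
  if (table$scale == "raw") stop("solubility requires log-scale intensities")
  meta <- table$channel_meta
  idx <- .channels_where(meta, condition = c("heat", "mock"), silac = silac,
                         lysis = lysis)
  if (length(idx) == 0) stop("no heat/mock channels for silac=", silac)
  sub <- meta[idx, ]
  tps <- sort(unique(sub$time_h))
  reps <- sort(unique(sub$replicate))
  s <- array(NA_real_,
             dim = c(nrow(table$values), length(tps), length(reps)),
             dimnames = list(rownames(table$values), as.character(tps),
                             paste0("r", reps)))
  bad <- character(0)
  for (ti in seq_along(tps)) for (ri in seq_along(reps)) {
    hi <- idx[sub$condition == "heat" & sub$time_h == tps[ti] &
                sub$replicate == reps[ri]]
    mi <- idx[sub$condition == "mock" & sub$time_h == tps[ti] &
                sub$replicate == reps[ri]]
    if (length(hi) != 1 || length(mi) != 1) {
      bad <- c(bad, sprintf("t=%g r=%s (heat: %d, mock: %d channels)",
                            tps[ti], reps[ri], length(hi), length(mi)))
      next
    }
    s[, ti, ri] <- table$values[, hi] - table$values[, mi]
  }
  if (length(bad) > 0)
    stop("unmatched heat/mock replicate structure at: ",
         paste(bad, collapse = "; "))
  mean_s <- apply(s, c(1, 2), mean, na.rm = TRUE)
  mean_s[is.nan(mean_s)] <- NA_real_
  structure(list(s = s, mean_s = mean_s, timepoints = tps,
                 protein_ids = rownames(table$values)),
            class = "solubility_profiles")
}

#' @export
print.solubility_profiles <- function(x, ...) {
  cat(sprintf(
    "solubility_profiles: %d proteins, t = {%s} h, %d replicates\n",
    length(x$protein_ids), paste(x$timepoints, collapse = ", "),
    dim(x$s)[3]))
  invisible(x)
}

#' Total solubility: NP-40 (soluble) vs SDS (total) log2 ratio
#'
#' For each protein and condition, the across-replicate mean of the
#' replicate-matched difference log2(NP-40) - log2(SDS). A pre-shock value
#' below -0.6 flags a pre-existing insoluble sub-population.
#'
#' @param np40 a normalized `intensity_table`; if `sds` is `NULL` it must
#'   carry both lysis types in its metadata and is split internally.
#' @param sds optional matching SDS-lysis `intensity_table`.
#' @param silac SILAC fraction used (default light).
#' @return Matrix protein x condition of total-solubility values, with the
#'   count of proteins dropped for missing either lysis in
#'   `attr(, "n_omitted")`.
#' @export
compute_total_solubility <- function(np40, sds = NULL, silac = "light") {
  stopifnot(inherits(np40, "intensity_table"))
  if (np40$scale == "raw") stop("requires log-scale intensities")
  if (is.null(sds)) {
    meta <- np40$channel_meta
    sds <- subset_channels(np40, meta$lysis == "SDS")
    np40 <- subset_channels(np40, meta$lysis == "NP40")
  }
  common <- intersect(rownames(np40$values), rownames(sds$values))
  n_omitted <- length(union(rownames(np40$values),
                            rownames(sds$values))) - length(common)
  mn <- np40$channel_meta; ms <- sds$channel_meta
  conds <- intersect(unique(mn$condition), unique(ms$condition))
  out <- matrix(NA_real_, length(common), length(conds),
                dimnames = list(common, conds))
  for (cond in conds) {
    reps <- intersect(mn$replicate[mn$condition == cond & mn$silac == silac],
                      ms$replicate[ms$condition == cond & ms$silac == silac])
    d <- matrix(NA_real_, length(common), length(reps))
    for (k in seq_along(reps)) {
      ni <- .channels_where(mn, condition = cond, silac = silac,
                            replicate = reps[k])
      si <- .channels_where(ms, condition = cond, silac = silac,
                            replicate = reps[k])
      # restrict to the lowest time point when a time course is present
      if (length(ni) > 1 && !all(is.na(mn$time_h[ni])))
        ni <- ni[which.min(mn$time_h[ni])]
      if (length(si) > 1 && !all(is.na(ms$time_h[si])))
        si <- si[which.min(ms$time_h[si])]
      if (length(ni) != 1 || length(si) != 1) next
      d[, k] <- np40$values[common, ni] - sds$values[common, si]
    }
    out[, cond] <- rowMeans(d, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  attr(out, "n_omitted") <- n_omitted
  out
}

#' Synthesis-accumulation ratios of the heavy (newly synthesized) fraction
#'
#' Per protein and condition, the log2 ratio of heavy-label intensity at each
#' recovery time point to the pre-shock control, averaged over
#' replicate-matched pairs.
#'
#' @param heavy_table normalized (log-scale) `intensity_table` of the heavy
#'   fraction including `condition == "preshock"` channels.
#' @param lysis lysis channels to use.
#' @return Object of class `synthesis_ratios`: 3-d array protein x time x
#'   condition of mean log2 ratios.
#' @export
compute_synthesis_ratios <- function(heavy_table, lysis = "NP40") {
  stopifnot(inherits(heavy_table, "intensity_table"))
  if (heavy_table$scale == "raw") stop("requires log-scale intensities")
  meta <- heavy_table$channel_meta
  pre_idx <- .channels_where(meta, condition = "preshock", lysis = lysis)
  if (length(pre_idx) == 0) stop("missing pre-shock channel(s)")
  conds <- intersect(c("heat", "mock"), unique(meta$condition))
  tps <- sort(unique(meta$time_h[meta$condition %in% conds]))
  v <- heavy_table$values
  out <- array(NA_real_, dim = c(nrow(v), length(tps), length(conds)),
               dimnames = list(rownames(v), as.character(tps), conds))
  for (cond in conds) for (ti in seq_along(tps)) {
    ci <- .channels_where(meta, condition = cond, time_h = tps[ti],
                          lysis = lysis)
    d <- matrix(NA_real_, nrow(v), length(ci))
    for (k in seq_along(ci)) {
      pk <- pre_idx[meta$replicate[pre_idx] == meta$replicate[ci[k]]]
      if (length(pk) != 1) next
      d[, k] <- v[, ci[k]] - v[, pk]
    }
    out[, ti, cond] <- rowMeans(d, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  structure(out, class = c("synthesis_ratios", class(out)))
}

#' Rank proteins by heat-shock synthesis accumulation
#'
#' Stable descending sort on the heat-condition log2 ratio at the requested
#' time point (ties broken by protein identifier order).
#'
#' @param ratios a `synthesis_ratios` array from
#'   [compute_synthesis_ratios()].
#' @param time_h time point to rank on (default 5 h).
#' @param condition condition to rank on.
#' @return data.frame `protein_id`, `log2_ratio`, in rank order.
#' @export
rank_upregulated <- function(ratios, time_h = 5, condition = "heat") {
  tkey <- as.character(time_h)
  if (!tkey %in% dimnames(ratios)[[2]]) stop("time point not in ratios")
  if (!condition %in% dimnames(ratios)[[3]]) stop("condition not in ratios")
  x <- ratios[, tkey, condition]
  ord <- order(-x, names(x), na.last = TRUE)
  data.frame(protein_id = names(x)[ord], log2_ratio = unname(x[ord]),
             stringsAsFactors = FALSE)
}
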