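## Protein-complex membership and coherence analysis: Fisher enrichment of
## aggregators in complexes, mean pairwise Euclidean solubility distances,
## and the scrambled-complex permutation null.

#' Read (or validate) a protein-complex membership table
#'
#' @param x path to a TSV with columns `complex_id`, `protein_id`, or an
#'   equivalent data.frame.
#' @param min_members minimum distinct members per complex; smaller
#'   complexes are dropped with a message.
#' @return data.frame `complex_id`, `protein_id` of class `complex_db`.
#' @export
read_complex_db <- function(x, min_members = 5) {
  db <- if (is.character(x)) utils::read.delim(x, stringsAsFactors = FALSE)
        else as.data.frame(x)
  if (!all(c("complex_id", "protein_id") %in% names(db)))
    stop("complex table must have columns 'complex_id' and 'protein_id'")
  db <- unique(db[, c("complex_id", "protein_id")])
  sizes <- table(db$complex_id)
  small <- names(sizes)[sizes < min_members]
  if (length(small) > 0) {
    message("dropping ", length(small), " complex(es) with < ",
            min_members, " distinct members")
    db <- db[!db$complex_id %in% small, ]
  }
  rownames(db) <- NULL
  class(db) <- c("complex_db", "data.frame")
  db
}

#' Are aggregators enriched in protein complexes?
#'
#' Two-sided Fisher's exact test of the 2x2 table (aggregator vs soluble) x
#' (member of >= 1 complex vs none), with the sample odds ratio.
#'
#' @param calls an `aggregator_calls` data.frame.
#' @param complex_db a `complex_db` data.frame.
#' @return List with `table` (2x2), `odds_ratio` (sample OR, `Inf` allowed),
#'   and `p` (Fisher exact, two-sided).
#' @export
membership_enrichment <- function(calls, complex_db) {
  in_cpx <- calls$protein_id %in% complex_db$protein_id
  is_agg <- calls$class == "aggregator"
  tab <- table(factor(is_agg, levels = c(TRUE, FALSE)),
               factor(in_cpx, levels = c(TRUE, FALSE)),
               dnn = c("aggregator", "in_complex"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in the 2x2 table")
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(table = tab, odds_ratio = or, p = p)
}

#' Mean pairwise Euclidean solubility distance
#'
#' Mean over all unordered pairs of members of the Euclidean distance
#' between their solubility vectors; with a single time point this is the
#' mean absolute pairwise difference.
#'
#' @param x numeric matrix, members x time points (no NA).
#' @return Non-negative scalar; `NA` (with a message) for < 2 members.
#' @export
coherence_distance <- function(x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (nrow(x) < 2) {
    message("coherence distance undefined for < 2 members")
    return(NA_real_)
  }
  mean(stats::dist(x))
}

#' Per-complex aggregation coherence
#'
#' For each complex: the number of members quantified, the number of
#' aggregator members with complete solubility vectors, eligibility
#' (>= `min_quantified_frac` of members quantified AND >=
#' `min_aggregators` aggregators), and the mean pairwise Euclidean distance
#' between the aggregator members' solubility vectors.
#'
#' @param profiles a `solubility_profiles` object (quantified proteome).
#' @param calls an `aggregator_calls` data.frame.
#' @param complex_db a `complex_db` data.frame.
#' @param timepoints time points over which distances are computed (default:
#'   all in the profiles).
#' @param min_quantified_frac eligibility fraction of members quantified.
#' @param min_aggregators eligibility minimum aggregator members.
#' @return data.frame `complex_id`, `n_members`, `n_quantified`,
#'   `n_aggregators`, `mean_pairwise_distance`, `eligible`.
#' @export
complex_coherence <- function(profiles, calls, complex_db,
                              timepoints = profiles$timepoints,
                              min_quantified_frac = 0.75,
                              min_aggregators = 2) {
  tkeys <- as.character(timepoints)
  vec <- profiles$mean_s[, tkeys, drop = FALSE]
  quantified <- rownames(vec)[rowSums(is.na(vec)) == 0]
  agg_ids <- calls$protein_id[calls$class == "aggregator"]
  ids <- split(complex_db$protein_id, complex_db$complex_id)
  rows <- lapply(names(ids), function(cid) {
    members <- ids[[cid]]
    qm <- intersect(members, quantified)
    am <- intersect(qm, agg_ids)
    d <- if (length(am) >= 2)
      coherence_distance(vec[am, , drop = FALSE]) else NA_real_
    data.frame(complex_id = cid, n_members = length(members),
               n_quantified = length(qm), n_aggregators = length(am),
               mean_pairwise_distance = d,
               eligible = length(qm) / length(members) >=
                 min_quantified_frac && length(am) >= min_aggregators,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scrambled-complex permutation null
#'
#' Builds `n_perm` scrambled complexes by (i) drawing each scrambled
#' complex's aggregator slot count from the empirical per-complex aggregator
#' counts of the real eligible complexes (preserving their frequency
#' distribution), and (ii) filling the slots by sampling aggregators without
#' replacement (within a complex) from the pooled aggregator set; the mean
#' pairwise distance of each scrambled complex is computed exactly as for
#' real complexes.
#'
#' @param real_counts integer vector of per-complex aggregator counts of the
#'   eligible real complexes (>= 2 each).
#' @param agg_vectors numeric matrix (pooled aggregators x time points) of
#'   solubility vectors (no NA rows).
#' @param n_perm number of scrambled complexes.
#' @param seed integer seed.
#' @return Numeric vector of `n_perm` null distances, with the drawn counts
#'   in `attr(, "counts")`.
#' @export
scramble_complexes <- function(real_counts, agg_vectors, n_perm = 10000,
                               seed) {
  if (missing(seed)) stop("'seed' is required")
  if (length(real_counts) < 2) stop("need >= 2 eligible complexes")
  if (any(real_counts < 2)) stop("aggregator slot counts must be >= 2")
  if (is.vector(agg_vectors)) agg_vectors <- matrix(agg_vectors, ncol = 1)
  if (max(real_counts) > nrow(agg_vectors))
    stop("pooled aggregator set smaller than the largest slot count")
  set.seed(seed)
  counts <- sample(real_counts, n_perm, replace = TRUE)
  null <- vapply(counts, function(k) {
    coherence_distance(
      agg_vectors[sample.int(nrow(agg_vectors), k), , drop = FALSE])
  }, numeric(1))
  attr(null, "counts") <- counts
  null
}

#' Compare real and scrambled coherence distances
#'
#' Two-sided Wilcoxon rank-sum test of the real per-complex mean distances
#' against the scrambled-null distances: normal approximation with tie
#' correction, exact enumeration when both samples have n <= 10 and no ties.
#'
#' @param real numeric vector of real per-complex distances.
#' @param null numeric vector of scrambled-complex distances.
#' @return List with `p` and `statistic` (rank-sum W).
#' @export
coherence_test <- function(real, null) {
  real <- real[!is.na(real)]; null <- null[!is.na(null)]
  if (length(real) == 0 || length(null) == 0)
    stop("both samples must be non-empty")
  if (length(unique(c(real, null))) == 1)
    return(list(p = 1, statistic = length(real) * length(null) / 2))
  ties <- anyDuplicated(c(real, null)) > 0
  exact <- length(real) <= 10 && length(null) <= 10 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(real, null, exact = exact, correct = TRUE))
  list(p = wt$p.value, statistic = unname(wt$statistic))
}

#' Normalize recovery trajectories to the initial solubility loss
#'
#' For each aggregator with strictly negative solubility at t = 0, the
#' recovery time points are rescaled as `mean_s(t) / mean_s(0)`: 1 means
#' still fully aggregated, 0 fully recovered. Proteins with non-negative
#' t = 0 solubility are excluded and counted.
#'
#' @param profiles a `solubility_profiles` object restricted (by row
#'   selection or otherwise) to the proteins of interest.
#' @param ids optional protein identifiers to include.
#' @param method `"ratio"` (division by the t = 0 value, default) or
#'   `"subtract"` (difference from the t = 0 value).
#' @return Matrix proteins x recovery time points, with
#'   `attr(, "n_excluded")`.
#' @export
normalize_recovery <- function(profiles, ids = NULL,
                               method = c("ratio", "subtract")) {
  stopifnot(inherits(profiles, "solubility_profiles"))
  method <- match.arg(method)
  m <- profiles$mean_s
  if (!is.null(ids)) m <- m[ids, , drop = FALSE]
  t0key <- as.character(min(profiles$timepoints))
  rec <- setdiff(colnames(m), t0key)
  s0 <- m[, t0key]
  keep <- !is.na(s0) & s0 < 0
  out <- if (method == "ratio") m[keep, rec, drop = FALSE] / s0[keep] else
    m[keep, rec, drop = FALSE] - s0[keep]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Select display complexes (densely quantified, aggregator-dominated)
#'
#' Complexes with at least `min_quantified_frac` of members quantified and
#' at least `min_aggregator_frac` of members called aggregators, each with
#' the all-quantified-member pairwise absolute solubility-difference matrix.
#'
#' @param calls an `aggregator_calls` data.frame.
#' @param complex_db a `complex_db` data.frame.
#' @param solubility named numeric vector of per-protein solubility values
#'   (e.g. `solubility_hs` from the calls); its names define the quantified
#'   set.
#' @param min_quantified_frac threshold on quantified members / members.
#' @param min_aggregator_frac threshold on aggregator members / members.
#' @return Named list (one element per selected complex) of symmetric
#'   zero-diagonal matrices of pairwise absolute solubility differences.
#' @export
select_display_complexes <- function(calls, complex_db, solubility,
                                     min_quantified_frac = 0.75,
                                     min_aggregator_frac = 0.60) {
  agg_ids <- calls$protein_id[calls$class == "aggregator"]
  quantified <- names(solubility)[!is.na(solubility)]
  ids <- split(complex_db$protein_id, complex_db$complex_id)
  out <- list()
  for (cid in names(ids)) {
    members <- ids[[cid]]
    qm <- intersect(members, quantified)
    am <- intersect(members, agg_ids)
    if (length(qm) / length(members) < min_quantified_frac) next
    if (length(am) / length(members) < min_aggregator_frac) next
    d <- abs(outer(solubility[qm], solubility[qm], `-`))
    dimnames(d) <- list(qm, qm)
    out[[cid]] <- d
  }
  out
}
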