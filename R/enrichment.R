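## Shared categorical statistics: hypergeometric term enrichment against the
## quantified background, per-category Fisher tests, and the
## Shapiro-Wilk-gated two-group comparison.

#' Read a GMT gene-set file
#'
#' @param path GMT path (term, description, then tab-separated identifiers).
#' @return Named list of identifier vectors; descriptions in
#'   `attr(, "descriptions")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  terms <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(terms) <- vapply(parts, `[[`, character(1), 1)
  attr(terms, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, character(1), 2), names(terms))
  terms
}

#' Hypergeometric term enrichment
#'
#' Per term: upper-tail hypergeometric `P(X >= k)` with `N` = background
#' size, `K` = term members in background, `n` = foreground size, `k` = term
#' members in foreground; BH adjustment across the tested terms, with terms
#' having zero foreground overlap excluded before adjustment (flag to
#' include them).
#'
#' @param foreground character vector, a subset of `background`.
#' @param background character vector of all quantified identifiers.
#' @param term_map named list of identifier vectors (e.g. from
#'   [read_gmt()]).
#' @param include_zero_overlap keep `k = 0` terms in the adjustment.
#' @return data.frame `term`, `N`, `K`, `n`, `k`, `enrichment_ratio`,
#'   `p_raw`, `p_adj`, sorted by `p_raw`.
#' @export
hypergeom_enrichment <- function(foreground, background, term_map,
                                 include_zero_overlap = FALSE) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background))
    stop("'foreground' must be a subset of 'background'")
  N <- length(background); n <- length(foreground)
  rows <- lapply(names(term_map), function(tm) {
    members <- intersect(term_map[[tm]], background)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, foreground))
    data.frame(term = tm, N = N, K = K, n = n, k = k,
               enrichment_ratio = (k / n) / (K / N),
               p_raw = stats::phyper(k - 1, K, N - K, n,
                                     lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no terms overlap the background")
  if (!include_zero_overlap) out <- out[out$k > 0, , drop = FALSE]
  out$p_adj <- bh_adjust(out$p_raw)
  out <- out[order(out$p_raw), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-category Fisher tests of aggregator occurrence
#'
#' For each category (e.g. localization or chromosome): a two-sided Fisher
#' exact test of the 2x2 table (aggregator vs soluble) x (in category vs
#' not), the sample odds ratio (`Inf` reported as such), BH adjustment
#' across categories, and the per-class fraction table with the
#' aggregator-minus-soluble differences. Multi-label categories are allowed
#' (per-class fractions may sum above 1 across categories).
#'
#' @param calls an `aggregator_calls` data.frame.
#' @param categories data.frame with columns `protein_id` and `category`
#'   (one row per membership; a protein may appear under several
#'   categories).
#' @return data.frame `category`, counts, `frac_aggregator`, `frac_soluble`,
#'   `frac_diff`, `odds_ratio`, `p_raw`, `p_adj`; empty categories skipped
#'   and reported in `attr(, "skipped")`.
#' @export
category_fisher <- function(calls, categories) {
  stopifnot(all(c("protein_id", "category") %in% names(categories)))
  cats <- unique(categories$category)
  if (length(cats) < 2) stop("need >= 2 categories")
  is_agg <- stats::setNames(calls$class == "aggregator", calls$protein_id)
  n_agg <- sum(is_agg); n_sol <- sum(!is_agg)
  rows <- list(); skipped <- character(0)
  for (cat in cats) {
    members <- unique(categories$protein_id[categories$category == cat])
    members <- intersect(members, names(is_agg))
    if (length(members) == 0) {
      skipped <- c(skipped, cat)
      next
    }
    a <- sum(is_agg[members]); b <- n_agg - a
    c_ <- length(members) - a; d <- n_sol - c_
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    or <- (a * d) / (b * c_)
    p <- stats::fisher.test(tab)$p.value
    rows[[cat]] <- data.frame(
      category = cat, n_in_category = length(members),
      aggregators_in = a, soluble_in = c_,
      frac_aggregator = a / n_agg, frac_soluble = c_ / n_sol,
      frac_diff = a / n_agg - c_ / n_sol,
      odds_ratio = or, p_raw = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Two-group comparison under the Shapiro-Wilk gate
#'
#' Welch t-test if both groups pass [assess_normality()], Wilcoxon rank-sum
#' otherwise; plus exact distribution summaries per group (median, type-7
#' quartiles, and whiskers at the most extreme observations within 1.5
#' interquartile ranges of the quartiles -- the boxplot convention of the
#' figures).
#'
#' @param values numeric vector.
#' @param classes two-level factor/character vector aligned with `values`.
#' @return List with `test` (`"t"` or `"wilcoxon"`), `p`, and `summary`
#'   (data.frame of per-group median/quartiles/whiskers).
#' @export
group_compare <- function(values, classes) {
  ok <- !is.na(values) & !is.na(classes)
  values <- values[ok]; classes <- as.character(classes)[ok]
  lv <- unique(classes)
  if (length(lv) != 2) stop("need exactly 2 non-empty classes")
  g1 <- values[classes == lv[1]]; g2 <- values[classes == lv[2]]
  if (length(g1) < 3 || length(g2) < 3)
    stop("need >= 3 values per class")
  normal <- isTRUE(assess_normality(g1)[1]) &&
    isTRUE(assess_normality(g2)[1])
  if (normal) {
    p <- stats::t.test(g1, g2)$p.value
    test <- "t"
  } else {
    p <- suppressWarnings(stats::wilcox.test(g1, g2, exact = FALSE)$p.value)
    test <- "wilcoxon"
  }
  summ <- do.call(rbind, lapply(lv, function(l) {
    x <- values[classes == l]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(class = l, n = length(x), median = q[2], q1 = q[1],
               q3 = q[3],
               whisker_low = min(x[x >= q[1] - 1.5 * iqr]),
               whisker_high = max(x[x <= q[3] + 1.5 * iqr]),
               stringsAsFactors = FALSE)
  }))
  list(test = test, p = p, summary = summ)
}
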