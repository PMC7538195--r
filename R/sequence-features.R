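## Sequence-derived physicochemical features: summed Kyte-Doolittle
## hydropathy, isoelectric point (EMBOSS pKa set), average molecular weight,
## amino-acid composition, and the Hsp70-binding-motif scan.

# EMBOSS pKa set, pinned; printed in feature-table headers by callers
.PKA <- list(nterm = 8.6, cterm = 3.6,
             K = 10.8, R = 12.5, H = 6.5,
             D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

# average (not monoisotopic) residue masses in Da; one water (18.0153 Da)
# is added per chain
.RESIDUE_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                   C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
                   H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                   M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                   T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.0153

# Hsp70-binding motif alphabet: a 4-5 residue hydrophobic core flanked on
# both sides by a basic residue
.HSP70_CORE <- c("L", "I", "V", "F", "M", "W", "Y")
.HSP70_FLANK <- c("K", "R")

.check_canonical <- function(chars, what = "sequence") {
  bad <- which(!chars %in% .AA)
  if (length(bad) > 0)
    stop("non-canonical residue '", chars[bad[1]], "' at position ", bad[1],
         " in ", what)
  invisible(chars)
}

.split_seq <- function(sequence) {
  if (length(sequence) != 1 || is.na(sequence) || nchar(sequence) == 0)
    stop("'sequence' must be a single non-empty string")
  .check_canonical(strsplit(sequence, "")[[1]])
}

#' Summed hydropathy (gravy score)
#'
#' Sum over residues of the Kyte-Doolittle hydropathy values (R -4.5 ...
#' I +4.5). Following the convention of this analysis the score is the SUM
#' over the sequence, so it scales with length and is additive under
#' concatenation; set `normalize = TRUE` for the conventional
#' length-normalized mean.
#'
#' @param sequences character vector of amino-acid sequences (canonical
#'   one-letter alphabet).
#' @param normalize divide by sequence length.
#' @return Numeric vector of scores.
#' @export
gravy_score <- function(sequences, normalize = FALSE) {
  vapply(sequences, function(s) {
    ch <- .split_seq(s)
    g <- sum(.GRAVY[ch])
    if (normalize) g / length(ch) else g
  }, numeric(1), USE.NAMES = !is.null(names(sequences)))
}

## net charge at a given pH (Henderson-Hasselbalch); strictly decreasing
.net_charge <- function(pH, counts) {
  pos <- 1 / (1 + 10^(pH - .PKA$nterm)) +
    counts["K"] / (1 + 10^(pH - .PKA$K)) +
    counts["R"] / (1 + 10^(pH - .PKA$R)) +
    counts["H"] / (1 + 10^(pH - .PKA$H))
  neg <- 1 / (1 + 10^(.PKA$cterm - pH)) +
    counts["D"] / (1 + 10^(.PKA$D - pH)) +
    counts["E"] / (1 + 10^(.PKA$E - pH)) +
    counts["C"] / (1 + 10^(.PKA$C - pH)) +
    counts["Y"] / (1 + 10^(.PKA$Y - pH))
  unname(pos - neg)
}

#' Isoelectric point
#'
#' The unique pH at which the net charge of the chain (N-terminus,
#' C-terminus, and the side chains of D, E, C, Y, H, K, R under the EMBOSS
#' pKa set) is zero, found by bisection on `[0, 14]` to a tolerance of 1e-4.
#'
#' @param sequences character vector of canonical sequences.
#' @param tol bisection tolerance in pH units.
#' @return Numeric vector of pI values.
#' @export
isoelectric_point <- function(sequences, tol = 1e-4) {
  vapply(sequences, function(s) {
    ch <- .split_seq(s)
    counts <- vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                     function(a) sum(ch == a), numeric(1))
    lo <- 0; hi <- 14
    # q is strictly decreasing in pH, so the root is unique
    stopifnot(.net_charge(lo, counts) > 0, .net_charge(hi, counts) < 0)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (.net_charge(mid, counts) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1), USE.NAMES = !is.null(names(sequences)))
}

#' Average molecular weight
#'
#' Sum of average residue masses plus one water (18.0153 Da).
#'
#' @param sequences character vector of canonical sequences.
#' @return Numeric vector of masses in Da.
#' @export
molecular_weight <- function(sequences) {
  vapply(sequences, function(s) {
    ch <- .split_seq(s)
    sum(.RESIDUE_MASS[ch]) + .WATER_MASS
  }, numeric(1), USE.NAMES = !is.null(names(sequences)))
}

#' Per-class amino-acid composition and its hydrophobicity coupling
#'
#' For each amino acid: the median fraction per class, the difference
#' (aggregator - soluble), and the Pearson correlation of the 20 differences
#' against the per-residue hydropathy values.
#'
#' @param sequences named character vector of sequences.
#' @param classes character vector (`"aggregator"` / `"soluble"`) aligned
#'   with `sequences`; >= 2 sequences per class.
#' @return List with `median_fractions` (2 x 20 matrix), `difference`
#'   (named vector, aggregator - soluble), `gravy_values`, and
#'   `correlation` (`NA` with a message attribute when all differences are
#'   zero).
#' @export
aa_composition <- function(sequences, classes) {
  stopifnot(length(sequences) == length(classes))
  if (any(table(factor(classes,
                       levels = c("aggregator", "soluble"))) < 2))
    stop("need >= 2 sequences per class")
  frac <- t(vapply(sequences, function(s) {
    ch <- .split_seq(s)
    tabulate(factor(ch, levels = .AA), nbins = 20) / length(ch)
  }, numeric(20)))
  colnames(frac) <- .AA
  med <- rbind(
    aggregator = apply(frac[classes == "aggregator", , drop = FALSE], 2,
                       stats::median),
    soluble = apply(frac[classes == "soluble", , drop = FALSE], 2,
                    stats::median))
  diff <- med["aggregator", ] - med["soluble", ]
  correlation <- if (stats::sd(diff) == 0) NA_real_ else
    stats::cor(diff, .GRAVY[colnames(med)])
  list(median_fractions = med, difference = diff,
       gravy_values = .GRAVY[colnames(med)], correlation = correlation)
}

#' Scan for Hsp70-binding motifs
#'
#' A match is a maximal run of 4 or 5 consecutive residues from the
#' hydrophobic core set \{L, I, V, F, M, W, Y\} immediately preceded AND
#' followed by a basic residue (K or R). Because the flanking residues are
#' never part of the core set, a basic-bounded run is automatically maximal
#' and counts once regardless of internal window overlaps.
#'
#' @param sequence a single canonical sequence.
#' @return List with `count` and `spans` (matrix with columns `start`,
#'   `end`, 1-based inclusive).
#' @export
scan_hsp70_motifs <- function(sequence) {
  ch <- .split_seq(sequence)
  core <- ch %in% .HSP70_CORE
  r <- rle(core)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths %in% c(4, 5))
  spans <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  for (i in hit) {
    s <- starts[i]; e <- ends[i]
    if (s > 1 && e < length(ch) &&
        ch[s - 1] %in% .HSP70_FLANK && ch[e + 1] %in% .HSP70_FLANK)
      spans <- rbind(spans, c(start = s, end = e))
  }
  list(count = nrow(spans), spans = spans)
}

#' Compute the full sequence-feature table
#'
#' @param x named character vector of sequences, or the path to a FASTA
#'   file (read with Biostrings).
#' @param normalize_gravy use the length-normalized gravy mean instead of
#'   the sum.
#' @return data.frame with `protein_id`, `gravy`, `pI`, `mw`,
#'   `hsp70_motif_count`, `length`, and one `frac_<aa>` column per amino
#'   acid. The pKa set used for pI is recorded in `attr(, "pka_set")`.
#' @export
sequence_features <- function(x, normalize_gravy = FALSE) {
  if (length(x) == 1 && !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x) &&
      file.exists(x)) {
    aa <- Biostrings::readAAStringSet(x)
    x <- stats::setNames(as.character(aa), sub("\\s.*", "", names(aa)))
  }
  if (is.null(names(x))) names(x) <- sprintf("seq%04d", seq_along(x))
  frac <- t(vapply(x, function(s) {
    ch <- .split_seq(s)
    tabulate(factor(ch, levels = .AA), nbins = 20) / length(ch)
  }, numeric(20)))
  colnames(frac) <- paste0("frac_", .AA)
  out <- data.frame(
    protein_id = names(x),
    gravy = unname(gravy_score(x, normalize = normalize_gravy)),
    pI = unname(isoelectric_point(x)),
    mw = unname(molecular_weight(x)),
    hsp70_motif_count = vapply(x, function(s) scan_hsp70_motifs(s)$count,
                               numeric(1)),
    length = nchar(x),
    frac, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "pka_set") <- unlist(.PKA)
  out
}
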