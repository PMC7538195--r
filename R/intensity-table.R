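#' Protein-by-channel intensity table
#'
#' The universal quantitative container of the pipeline: a numeric matrix of
#' protein-level reporter intensities (one row per protein, one column per
#' TMT channel) together with the per-channel experimental coordinates and,
#' optionally, per-replicate unique-peptide support.
#'
#' @param values numeric matrix, proteins x channels. Rownames are protein
#'   identifiers (unique), colnames are channel identifiers matching
#'   `channel_meta$channel_id`. On the `"raw"` scale values must be
#'   non-negative; `NA` marks a missing quantification.
#' @param channel_meta data.frame with one row per channel and at least the
#'   column `channel_id`; recognised coordinate columns are `condition`
#'   (`"heat"`, `"mock"`, `"preshock"`), `time_h`, `silac` (`"light"`/
#'   `"heavy"`), `replicate`, `batch`, `lysis` (`"NP40"`/`"SDS"`) and
#'   `temperature_C`.
#' @param peptide_support optional integer matrix, proteins x replicates, of
#'   unique-peptide counts backing each protein in each biological replicate.
#' @param scale one of `"raw"`, `"log2"`, `"glog2"`.
#'
#' @return An object of class `intensity_table`: a list with elements
#'   `values`, `channel_meta`, `peptide_support`, `scale`.
#' @export
intensity_table <- function(values, channel_meta, peptide_support = NULL,
                            scale = c("raw", "log2", "glog2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) > 0 &&
      (is.null(rownames(values)) || anyDuplicated(rownames(values))))
    stop("'values' must have unique rownames (protein identifiers)")
  if (!is.data.frame(channel_meta) || is.null(channel_meta$channel_id))
    stop("'channel_meta' must be a data.frame with a 'channel_id' column")
  channel_meta$channel_id <- as.character(channel_meta$channel_id)
  if (is.null(colnames(values)))
    stop("'values' must have colnames (channel identifiers)")
  if (!identical(colnames(values), channel_meta$channel_id))
    stop("colnames(values) must equal channel_meta$channel_id, in order")
  if (anyDuplicated(channel_meta$channel_id))
    stop("duplicated channel identifiers")
  if (scale == "raw" && any(values < 0, na.rm = TRUE))
    stop("raw intensities must be non-negative")
  if (!is.null(peptide_support)) {
    if (!is.matrix(peptide_support) ||
        !identical(rownames(peptide_support), rownames(values)))
      stop("'peptide_support' must be a matrix with the same rownames as 'values'")
  }
  structure(
    list(values = values, channel_meta = channel_meta,
         peptide_support = peptide_support, scale = scale),
    class = "intensity_table")
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(sprintf("intensity_table: %d proteins x %d channels [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  for (col in c("condition", "silac", "lysis")) {
    if (!is.null(x$channel_meta[[col]])) {
      lv <- unique(x$channel_meta[[col]])
      cat(sprintf("  %s: %s\n", col, paste(lv, collapse = ", ")))
    }
  }
  nmiss <- sum(is.na(x$values))
  cat(sprintf("  missing cells: %d (%.1f%%)\n",
              nmiss, 100 * nmiss / length(x$values)))
  invisible(x)
}

#' @export
dim.intensity_table <- function(x) dim(x$values)

#' Subset an intensity table by channels (and optionally proteins)
#'
#' @param x an `intensity_table`.
#' @param channels logical or character selector over channels.
#' @param proteins logical or character selector over proteins.
#' @return An `intensity_table` restricted to the selection.
#' @export
subset_channels <- function(x, channels, proteins = NULL) {
  stopifnot(inherits(x, "intensity_table"))
  if (is.logical(channels)) channels <- x$channel_meta$channel_id[channels]
  keep <- match(channels, x$channel_meta$channel_id)
  if (anyNA(keep)) stop("unknown channel identifiers")
  v <- x$values[, keep, drop = FALSE]
  meta <- x$channel_meta[keep, , drop = FALSE]
  rownames(meta) <- NULL
  ps <- x$peptide_support
  if (!is.null(proteins)) {
    v <- v[proteins, , drop = FALSE]
    if (!is.null(ps)) ps <- ps[proteins, , drop = FALSE]
  }
  intensity_table(v, meta, ps, scale = x$scale)
}

#' Write an intensity table as wide TSV plus channel metadata TSV
#'
#' @param x an `intensity_table`.
#' @param prefix path prefix; writes `<prefix>_intensities.tsv` (first column
#'   `protein_id`) and `<prefix>_channels.tsv`.
#' @return Invisibly, the two file paths.
#' @export
write_intensity_table <- function(x, prefix) {
  stopifnot(inherits(x, "intensity_table"))
  fi <- paste0(prefix, "_intensities.tsv")
  fc <- paste0(prefix, "_channels.tsv")
  df <- data.frame(protein_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, fi, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$channel_meta, fc, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(intensities = fi, channels = fc))
}

#' Read an intensity table from wide TSV plus channel metadata TSV
#'
#' @param intensities path to the wide intensity TSV (column `protein_id`
#'   followed by one column per channel).
#' @param channels path to the channel metadata TSV.
#' @param scale scale of the stored values.
#' @return An `intensity_table`.
#' @export
read_intensity_table <- function(intensities, channels,
                                 scale = c("raw", "log2", "glog2")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(intensities, check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- utils::read.delim(channels, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$protein_id
  intensity_table(v, meta, scale = scale)
}

## internal: locate channels by coordinates; returns integer indices
.channels_where <- function(meta, condition = NULL, silac = NULL, lysis = NULL,
                            time_h = NULL, replicate = NULL,
                            temperature_C = NULL) {
  keep <- rep(TRUE, nrow(meta))
  pick <- function(keep, col, val) {
    if (is.null(val)) return(keep)
    if (is.null(meta[[col]])) stop("channel metadata lacks column '", col, "'")
    keep & !is.na(meta[[col]]) & meta[[col]] %in% val
  }
  keep <- pick(keep, "condition", condition)
  keep <- pick(keep, "silac", silac)
  keep <- pick(keep, "lysis", lysis)
  keep <- pick(keep, "time_h", time_h)
  keep <- pick(keep, "replicate", replicate)
  keep <- pick(keep, "temperature_C", temperature_C)
  which(keep)
}
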