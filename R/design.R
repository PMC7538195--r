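#' Experimental design of the heat-shock solubility study
#'
#' Encodes the layout the synthetic generator emulates: a two-condition
#' (44 degC heat shock vs 37 degC mock) recovery time course sampled at
#' 0, 1, 2, 3 and 5 h with light (pre-existing) and heavy (newly synthesized)
#' SILAC fractions, NP-40 (soluble) vs SDS (total) lysis, and a 12-temperature
#' melting gradient profiled in 2 mock and 3 heat-shock replicates.
#'
#' @param timepoints_h recovery sampling times in hours.
#' @param n_replicates number of biological replicates of the time course.
#' @param batches batch label per replicate (TMT run); defaults to one batch
#'   per replicate.
#' @param tpp_temperatures the melting gradient in degC, strictly increasing;
#'   the first two must lie below the 44 degC heat-shock temperature (they
#'   anchor the baseline correction of the stability score).
#' @param tpp_replicates named integer vector `c(mock = ..., heat = ...)`.
#'
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(timepoints_h = c(0, 1, 2, 3, 5),
                              n_replicates = 3,
                              batches = paste0("b", seq_len(n_replicates)),
                              tpp_temperatures = c(37.0, 37.8, 40.4, 44.0,
                                                   46.9, 49.8, 52.9, 55.5,
                                                   58.6, 62.0, 65.4, 66.3),
                              tpp_replicates = c(mock = 2, heat = 3)) {
  if (is.unsorted(timepoints_h, strictly = TRUE))
    stop("'timepoints_h' must be strictly increasing")
  if (n_replicates < 2) stop("'n_replicates' must be >= 2")
  if (length(batches) != n_replicates)
    stop("'batches' must give one label per replicate")
  if (is.unsorted(tpp_temperatures, strictly = TRUE))
    stop("'tpp_temperatures' must be strictly increasing")
  if (any(tpp_temperatures[1:2] >= 44))
    stop("the first two gradient temperatures must lie below 44 degC")
  if (!all(c("mock", "heat") %in% names(tpp_replicates)))
    stop("'tpp_replicates' must name 'mock' and 'heat' counts")
  structure(
    list(timepoints_h = timepoints_h, n_replicates = n_replicates,
         batches = as.character(batches),
         tpp_temperatures = tpp_temperatures,
         tpp_replicates = tpp_replicates),
    class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("experiment_design\n")
  cat("  time course:", paste(x$timepoints_h, collapse = ", "), "h;",
      x$n_replicates, "replicates (batches:",
      paste(x$batches, collapse = ", "), ")\n")
  cat("  melting gradient:", length(x$tpp_temperatures), "temperatures,",
      min(x$tpp_temperatures), "-", max(x$tpp_temperatures), "degC;",
      "mock x", x$tpp_replicates[["mock"]],
      ", heat x", x$tpp_replicates[["heat"]], "\n")
  invisible(x)
}
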