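# Time-series concentration datasets: observed times x species matrix with
# missing-value support. The dataset supplies the initial conditions at its
# first time point and the per-species observation means used by the
# mean-centered loss.

#' Construct a time-series dataset
#'
#' @param times Ascending numeric vector of observation times.
#' @param values Species-by-time numeric matrix (rownames = species ids);
#'   `NA` marks a missing observation. A species-named list / data.frame of
#'   per-time values is also accepted.
#' @return A `kx_dataset`: `times`, `values` (species x time), `species`,
#'   and `means` (per-species mean over non-missing observations, the
#'   normalizer of the mean-centered loss).
#' @export
time_series_dataset <- function(times, values) {
  if (is.data.frame(values)) values <- t(as.matrix(values))
  if (is.list(values)) values <- do.call(rbind, values)
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (length(times) != ncol(values))
    stop("`times` length must match the number of observation columns")
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly ascending")
  keep <- rowSums(!is.na(values)) > 0
  if (!all(keep)) {
    kx_warn("empty-species",
            sprintf("dropping species with no observations: %s",
                    paste(rownames(values)[!keep], collapse = ", ")))
    values <- values[keep, , drop = FALSE]
  }
  structure(
    list(times = as.numeric(times), values = values,
         species = rownames(values),
         means = rowMeans(values, na.rm = TRUE)),
    class = "kx_dataset")
}

#' @export
print.kx_dataset <- function(x, ...) {
  cat(sprintf("<kx_dataset> %d species x %d times [%g, %g], %d observations\n",
              length(x$species), length(x$times), min(x$times), max(x$times),
              sum(!is.na(x$values))))
  invisible(x)
}

#' Read or write a dataset as CSV
#'
#' The on-disk format is one row per time point: first column `time`,
#' remaining columns named by species id; empty cells are missing values.
#'
#' @param file Path to a CSV file.
#' @param dataset A `kx_dataset`.
#' @return `read_dataset_csv()`: a `kx_dataset`. `write_dataset_csv()`: the
#'   path, invisibly.
#' @export
read_dataset_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  if (!"time" %in% names(df)) stop("CSV must have a 'time' column")
  vals <- t(as.matrix(df[setdiff(names(df), "time")]))
  time_series_dataset(df$time, vals)
}

#' @rdname read_dataset_csv
#' @export
write_dataset_csv <- function(dataset, file) {
  df <- data.frame(time = dataset$times, t(dataset$values),
                   check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE, na = "")
  invisible(file)
}
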