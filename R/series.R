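#' Single-probe expression time course
#'
#' Container for one probe's log-ratio expression time series sampled at
#' uniform intervals. Missing observations are flagged in `missing_mask` and
#' stored as `NA` in `values`.
#'
#' @param probe_id Probe identifier (unique within a [series_set()]).
#' @param gene_id Gene symbol the probe maps to; may be `""` when unknown.
#' @param values Numeric vector of log2-ratio expression values, one per
#'   time point (`NA` where missing).
#' @param missing_mask Logical vector aligned to `values`; defaults to
#'   `is.na(values)`.
#' @param time_step Sampling interval in hours (default 1).
#' @return An object of class `ExpressionSeries`.
#' @export
#' @examples
#' s <- expression_series("p1", "GAPDH", c(0.1, NA, 0.3))
#' s$missing_mask
expression_series <- function(probe_id, gene_id, values,
                              missing_mask = is.na(values), time_step = 1) {
  values <- as.numeric(values)
  missing_mask <- as.logical(missing_mask)
  if (length(values) != length(missing_mask)) {
    stop("`values` and `missing_mask` must have identical length")
  }
  if (any(is.na(values) & !missing_mask)) {
    stop("NA values must be flagged in `missing_mask`")
  }
  values[missing_mask] <- NA_real_
  structure(
    list(probe_id = as.character(probe_id), gene_id = as.character(gene_id),
         values = values, missing_mask = missing_mask,
         time_step = as.numeric(time_step)),
    class = "ExpressionSeries"
  )
}

#' @export
print.ExpressionSeries <- function(x, ...) {
  cat(sprintf("<ExpressionSeries> probe %s (gene %s): %d points, %d missing\n",
              x$probe_id, if (nzchar(x$gene_id)) x$gene_id else "<none>",
              length(x$values), sum(x$missing_mask)))
  invisible(x)
}

#' Collection of expression time series
#'
#' Holds a probe-by-timepoint value matrix together with the probe-to-gene
#' mapping. Probe identifiers must be unique; several probes may map to the
#' same gene.
#'
#' @param values Numeric matrix, one row per probe, one column per time
#'   point. `NA` entries are treated as missing.
#' @param probe_ids Character vector of unique probe identifiers.
#' @param gene_ids Character vector of gene symbols aligned to `probe_ids`.
#' @param time_step Sampling interval in hours.
#' @return An object of class `SeriesSet`.
#' @seealso [get_series()], [read_series_matrix()]
#' @export
series_set <- function(values, probe_ids, gene_ids, time_step = 1) {
  values <- as.matrix(values)
  probe_ids <- as.character(probe_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != length(probe_ids) || length(probe_ids) != length(gene_ids)) {
    stop("row count of `values` must match length of `probe_ids` and `gene_ids`")
  }
  if (anyDuplicated(probe_ids)) {
    stop("duplicate probe_id: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  }
  dimnames(values) <- list(probe_ids, NULL)
  structure(
    list(values = values, probe_ids = probe_ids, gene_ids = gene_ids,
         time_step = as.numeric(time_step)),
    class = "SeriesSet"
  )
}

#' @export
length.SeriesSet <- function(x) nrow(x$values)

#' @export
print.SeriesSet <- function(x, ...) {
  cat(sprintf("<SeriesSet> %d probes x %d time points (%g h step), %d genes\n",
              nrow(x$values), ncol(x$values), x$time_step,
              length(unique(x$gene_ids[nzchar(x$gene_ids)]))))
  invisible(x)
}

#' Extract one series from a SeriesSet
#'
#' @param set A [series_set()].
#' @param probe Probe identifier or integer row index.
#' @return An [expression_series()].
#' @export
get_series <- function(set, probe) {
  stopifnot(inherits(set, "SeriesSet"))
  i <- if (is.character(probe)) match(probe, set$probe_ids) else as.integer(probe)
  if (is.na(i) || i < 1L || i > nrow(set$values)) {
    stop("probe not found in SeriesSet: ", probe)
  }
  expression_series(set$probe_ids[i], set$gene_ids[i], set$values[i, ],
                    time_step = set$time_step)
}

#' Probe-to-gene map of a SeriesSet
#'
#' @param set A [series_set()].
#' @return Named character vector mapping probe_id to gene_id.
#' @export
probe_gene_map <- function(set) {
  stopifnot(inherits(set, "SeriesSet"))
  stats::setNames(set$gene_ids, set$probe_ids)
}
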