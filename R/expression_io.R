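#' Read a tab-separated expression time-series matrix
#'
#' Parses a PCL-compatible matrix: the first two columns are probe id and
#' gene id, remaining columns are one expression value per time point.
#' Empty cells and `NA` tokens become missing values. A header line, a
#' `GWEIGHT` annotation column and an `EWEIGHT` annotation row (the PCL
#' dialect) are recognised and skipped when present.
#'
#' @param path Path to the file.
#' @param expected_length Required number of time points per row.
#' @param time_step Sampling interval in hours (default 1).
#' @return A [series_set()] preserving the input row order.
#' @export
read_series_matrix <- function(path, expected_length, time_step = 1) {
  if (!file.exists(path)) stop("cannot read expression matrix: ", path)
  expected_length <- as.integer(expected_length)
  stopifnot(expected_length >= 1L)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(series_set(matrix(numeric(0), 0, expected_length),
                      character(0), character(0), time_step))
  }
  fields <- lapply(lines, split_tsv_line)

  gweight_col <- NA_integer_
  has_header <- looks_like_header(fields[[1]])
  if (has_header) {
    hdr <- toupper(trimws(fields[[1]]))
    hit <- which(hdr == "GWEIGHT")
    if (length(hit)) gweight_col <- hit[1]
    fields <- fields[-1]
    line_no <- line_no[-1]
  }
  if (length(fields)) {
    ew <- vapply(fields, function(f) toupper(trimws(f[1])) == "EWEIGHT", logical(1))
    fields <- fields[!ew]
    line_no <- line_no[!ew]
  }
  if (!is.na(gweight_col)) {
    fields <- lapply(fields, function(f) if (length(f) >= gweight_col) f[-gweight_col] else f)
  }

  n <- length(fields)
  want <- 2L + expected_length
  vals <- matrix(NA_real_, n, expected_length)
  probes <- character(n)
  genes <- character(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) != want) {
      stop(sprintf("line %d: expected %d columns (2 ids + %d values), found %d",
                   line_no[i], want, expected_length, length(f)))
    }
    probes[i] <- trimws(f[1])
    genes[i] <- trimws(f[2])
    cells <- trimws(f[-(1:2)])
    miss <- cells == "" | toupper(cells) %in% c("NA", "NAN", "NULL")
    num <- suppressWarnings(as.numeric(cells))
    bad <- !miss & is.na(num)
    if (any(bad)) {
      stop(sprintf("line %d: non-numeric value '%s' in column %d",
                   line_no[i], cells[which(bad)[1]], which(bad)[1] + 2L))
    }
    num[miss] <- NA_real_
    vals[i, ] <- num
  }
  series_set(vals, probes, genes, time_step)
}

# split preserving empty trailing fields (strsplit drops them)
split_tsv_line <- function(line) {
  parts <- strsplit(paste0(line, "\x01"), "\t", fixed = TRUE)[[1]]
  parts[length(parts)] <- sub("\x01$", "", parts[length(parts)])
  parts
}

looks_like_header <- function(f) {
  if (length(f) < 3L) return(FALSE)
  first <- toupper(trimws(f[1]))
  if (first %in% c("UID", "ID", "YORF", "ORF", "PROBE", "PROBE_ID", "GID", "NAME")) {
    return(TRUE)
  }
  data_cells <- trimws(f[-(1:2)])
  data_cells <- data_cells[data_cells != "" & !toupper(data_cells) %in% c("NA", "NAN")]
  length(data_cells) > 0L && any(is.na(suppressWarnings(as.numeric(data_cells))))
}

#' Read a plain-text gene list
#'
#' One gene symbol per line; blank lines are ignored, surrounding
#' whitespace is trimmed and duplicates removed.
#'
#' @param path Path to the file.
#' @return Character vector of unique gene symbols (original case kept;
#'   matching in [partition_probes()] is case-insensitive).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("cannot read gene list: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Partition probes by reference housekeeping-gene list membership
#'
#' A probe's gene is looked up (case-insensitively) in three published
#' reference HKG lists. Genes found in all three lists define the
#' standard-HKG pool, genes in exactly one or two lists the putative-HKG
#' pool, and the remainder (including probes without a gene symbol) the
#' non-HKG pool.
#'
#' @param set A [series_set()].
#' @param list1,list2,list3 Character vectors of reference gene symbols.
#' @return An object of class `ProbePartition`: a list with character
#'   vectors `standard`, `putative` and `non_hkg` of probe ids (pairwise
#'   disjoint, jointly covering the set).
#' @export
partition_probes <- function(set, list1, list2, list3) {
  stopifnot(inherits(set, "SeriesSet"))
  g <- toupper(trimws(set$gene_ids))
  l1 <- toupper(trimws(list1)); l2 <- toupper(trimws(list2)); l3 <- toupper(trimws(list3))
  hits <- (g %in% l1) + (g %in% l2) + (g %in% l3)
  hits[!nzchar(g)] <- 0L
  structure(
    list(standard = set$probe_ids[hits == 3L],
         putative = set$probe_ids[hits %in% c(1L, 2L)],
         non_hkg = set$probe_ids[hits == 0L]),
    class = "ProbePartition"
  )
}

#' @export
print.ProbePartition <- function(x, ...) {
  cat(sprintf("<ProbePartition> standard: %d, putative: %d, non-HKG: %d probes\n",
              length(x$standard), length(x$putative), length(x$non_hkg)))
  invisible(x)
}

# pool of a probe id, as a factor-ready string
probe_pool <- function(partition, probes) {
  out <- rep(NA_character_, length(probes))
  out[probes %in% partition$standard] <- "standard"
  out[probes %in% partition$putative] <- "putative"
  out[probes %in% partition$non_hkg] <- "non_hkg"
  out
}

#' Write gene-level HKG predictions to TSV
#'
#' Writes one row per gene with columns `gene_id`, `best_probe_id`,
#' `vote_count`, `ballot_percent`, `source_pool` and `selected`, sorted by
#' descending vote count. [read_predictions()] round-trips the file.
#'
#' @param result A predictions data frame as produced by [select_hkgs()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_predictions <- function(result, path) {
  cols <- c("gene_id", "best_probe_id", "vote_count", "ballot_percent",
            "source_pool", "selected")
  stopifnot(is.data.frame(result), all(cols %in% names(result)))
  out <- result[cols]
  out <- out[order(-ifelse(is.na(out$vote_count), Inf, out$vote_count),
               out$gene_id), , drop = FALSE]
  ok <- tryCatch({
    con <- file(path, "w")
    on.exit(close(con))
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) stop("cannot write predictions to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read back a predictions TSV written by [write_predictions()]
#'
#' @param path Path to the file.
#' @return Data frame with the prediction columns, types restored.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("cannot read predictions: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "integer",
                                         "numeric", "character", "logical"),
                          na.strings = "")
  df
}
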