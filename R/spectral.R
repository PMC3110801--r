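#' Discrete Fourier transform of a complete series
#'
#' The standard unnormalised forward transform
#' X_k = sum_n x_n exp(-2*pi*i*k*n/N), k = 0..N-1. For real input the
#' spectrum is conjugate-symmetric, X_{N-k} = Conj(X_k), so a length-47
#' series carries 24 independent components (k = 0..23).
#'
#' @param x Numeric vector without missing values.
#' @return Complex vector of length `length(x)`.
#' @export
dft <- function(x) {
  if (length(x) == 0L) stop("empty input")
  if (anyNA(x)) stop("dft requires a complete series")
  stats::fft(as.numeric(x))
}

#' Power-spectrum feature vector
#'
#' Returns |X_k|^2 for the independent frequency components of a real
#' series of odd length N: k = 0..(N-1)/2, i.e. 24 features for the
#' reference length 47. The DC component (k = 0) is kept; after
#' detrending it is ~0.
#'
#' @param x Numeric vector (odd length; pass `require_odd = FALSE` to get
#'   the floor(N/2)+1 components of an even-length series).
#' @param require_odd Refuse even-length input (default TRUE, matching the
#'   24-of-47 conjugate-pair structure).
#' @return Named numeric vector of non-negative powers (`k0`, `k1`, ...).
#' @export
power_features <- function(x, require_odd = TRUE) {
  n <- length(x)
  if (n == 0L) stop("empty input")
  if (require_odd && n %% 2L == 0L) {
    stop("even-length series: the conjugate-pair feature count assumes odd N")
  }
  n_keep <- if (n %% 2L == 1L) (n + 1L) %/% 2L else n %/% 2L + 1L
  pw <- Mod(dft(x))^2
  stats::setNames(pw[seq_len(n_keep)], paste0("k", seq_len(n_keep) - 1L))
}

#' Spectral feature matrix for a series set
#'
#' @param set A [series_set()] of complete (interpolated, detrended)
#'   series.
#' @param require_odd Passed to [power_features()].
#' @return Numeric matrix, one row per probe (rownames = probe ids), one
#'   column per power-spectrum component.
#' @export
featurize <- function(set, require_odd = TRUE) {
  stopifnot(inherits(set, "SeriesSet"))
  if (anyNA(set$values)) {
    bad <- set$probe_ids[apply(is.na(set$values), 1L, any)]
    stop("series with missing values cannot be featurized: ",
         paste(utils::head(bad, 3L), collapse = ", "))
  }
  p <- ncol(set$values)
  if (nrow(set$values) == 0L) {
    n_keep <- if (p %% 2L == 1L) (p + 1L) %/% 2L else p %/% 2L + 1L
    return(matrix(numeric(0), 0L, n_keep,
                  dimnames = list(NULL, paste0("k", seq_len(n_keep) - 1L))))
  }
  feats <- t(apply(set$values, 1L, power_features, require_odd = require_odd))
  rownames(feats) <- set$probe_ids
  feats
}

#' Write a feature matrix as TSV
#'
#' @param features Matrix from [featurize()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_features <- function(features, path) {
  df <- data.frame(probe_id = rownames(features), features,
                   check.names = FALSE, row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
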