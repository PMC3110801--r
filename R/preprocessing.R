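#' Missing-data triage for a time series
#'
#' Decides whether a series is usable for spectral analysis. Series with
#' adjacent (successive) missing points, with three or more missing points,
#' or with a missing endpoint are dropped; series with one or two isolated
#' interior gaps are kept for interpolation; complete series pass through.
#'
#' @param series An [expression_series()] of length >= 3.
#' @return An object of class `TriageDecision`: list with logical `keep`
#'   and `reason`, one of `complete`, `interpolate_1`, `interpolate_2`,
#'   `drop_successive`, `drop_three_or_more`, `drop_endpoint`.
#' @export
triage_missing <- function(series) {
  stopifnot(inherits(series, "ExpressionSeries"))
  m <- series$missing_mask
  p <- length(m)
  if (p < 3L) stop("series must have at least 3 points")
  idx <- which(m)
  reason <-
    if (length(idx) == 0L) "complete"
    else if (any(diff(idx) == 1L)) "drop_successive"
    else if (length(idx) >= 3L) "drop_three_or_more"
    else if (1L %in% idx || p %in% idx) "drop_endpoint"
    else if (length(idx) == 1L) "interpolate_1"
    else "interpolate_2"
  structure(list(keep = reason %in% c("complete", "interpolate_1", "interpolate_2"),
                 reason = reason),
            class = "TriageDecision")
}

triage_reasons <- c("complete", "interpolate_1", "interpolate_2",
                    "drop_successive", "drop_three_or_more", "drop_endpoint")

#' Shape-preserving piecewise cubic Hermite interpolation
#'
#' Monotone cubic Hermite interpolation with the Fritsch-Carlson/Butland
#' derivative rule (the classic `pchip` scheme): on intervals where the
#' data are monotone the interpolant is monotone and never overshoots the
#' bracketing data values.
#'
#' @param x Strictly increasing numeric vector of sample locations.
#' @param y Numeric values at `x`.
#' @param xout Locations at which to evaluate (must lie within
#'   `range(x)`; extrapolation is refused).
#' @return Numeric vector of interpolated values at `xout`.
#' @export
pchip_interpolate <- function(x, y, xout) {
  stopifnot(length(x) == length(y), length(x) >= 2L, !anyNA(x), !anyNA(y))
  if (any(diff(x) <= 0)) stop("`x` must be strictly increasing")
  if (any(xout < x[1] - 1e-12 | xout > x[length(x)] + 1e-12)) {
    stop("xout outside the data range: extrapolation is not defined")
  }
  d <- pchip_slopes(x, y)
  n <- length(x)
  h <- diff(x)
  delta <- diff(y) / h
  iv <- pmin(pmax(findInterval(xout, x), 1L), n - 1L)
  s <- xout - x[iv]
  # standard cubic Hermite form on each interval
  c2 <- (3 * delta[iv] - 2 * d[iv] - d[iv + 1L]) / h[iv]
  c3 <- (d[iv] - 2 * delta[iv] + d[iv + 1L]) / h[iv]^2
  y[iv] + s * (d[iv] + s * (c2 + s * c3))
}

# Derivative choice: harmonic weighted mean of adjacent secants where they
# agree in sign (zero otherwise); shape-preserving three-point rule with
# clipping at the ends.
pchip_slopes <- function(x, y) {
  n <- length(x)
  h <- diff(x)
  delta <- diff(y) / h
  d <- numeric(n)
  if (n == 2L) return(rep(delta, 2L))
  for (k in 2:(n - 1L)) {
    if (delta[k - 1L] * delta[k] > 0) {
      w1 <- 2 * h[k] + h[k - 1L]
      w2 <- h[k] + 2 * h[k - 1L]
      d[k] <- (w1 + w2) / (w1 / delta[k - 1L] + w2 / delta[k])
    } else {
      d[k] <- 0
    }
  }
  d[1] <- pchip_end_slope(h[1], h[2], delta[1], delta[2])
  d[n] <- pchip_end_slope(h[n - 1L], h[n - 2L], delta[n - 1L], delta[n - 2L])
  d
}

pchip_end_slope <- function(h1, h2, del1, del2) {
  d <- ((2 * h1 + h2) * del1 - h1 * del2) / (h1 + h2)
  if (sign(d) != sign(del1)) {
    d <- 0
  } else if (sign(del1) != sign(del2) && abs(d) > abs(3 * del1)) {
    d <- 3 * del1
  }
  d
}

#' Fill isolated missing points by monotone Hermite interpolation
#'
#' @param series An [expression_series()] whose [triage_missing()] decision
#'   is a keep. Endpoints must be observed.
#' @return The series with missing positions filled and the mask cleared;
#'   observed values are untouched.
#' @export
interpolate_missing <- function(series) {
  stopifnot(inherits(series, "ExpressionSeries"))
  m <- series$missing_mask
  if (!any(m)) return(series)
  p <- length(m)
  if (m[1] || m[p]) stop("missing endpoint: extrapolation is not defined")
  t <- seq_len(p)
  filled <- series$values
  filled[m] <- pchip_interpolate(t[!m], series$values[!m], t[m])
  expression_series(series$probe_id, series$gene_id, filled,
                    missing_mask = rep(FALSE, p), time_step = series$time_step)
}

#' Variation basis matrix for detrending
#'
#' The default five basis functions over the 1-based time index
#' t = 1..p are 1, t, t^2, t^3 and ln t: a cubic polynomial trend plus a
#' logarithmic term (the form a regular-singular-point series solution
#' contributes). Custom bases are supported through `degree` and
#' `log_term`.
#'
#' @param p Number of time points.
#' @param degree Polynomial degree (default 3, giving degree+1 columns).
#' @param log_term Include the ln t column (default TRUE).
#' @return A `p x q` basis matrix (default q = 5).
#' @export
variation_basis <- function(p, degree = 3L, log_term = TRUE) {
  stopifnot(p >= 2L, degree >= 0L)
  t <- seq_len(p)
  B <- outer(t, 0:degree, `^`)
  colnames(B) <- paste0("t^", 0:degree)
  if (log_term) {
    B <- cbind(B, `ln t` = log(t))
  }
  B
}

#' Least-squares detrending against the variation basis
#'
#' Projects a complete series onto the span of the basis functions and
#' returns the residual (the approximately first-order-stationary series
#' used for Fourier analysis) together with the fitted coefficients. The
#' fit minimises the total squared error; the solve uses a QR
#' factorisation of the column-scaled basis for conditioning (t^3 and ln t
#' are wildly different in magnitude over 47 points).
#'
#' @param series An [expression_series()] without missing values, or a
#'   plain numeric vector.
#' @param basis Basis matrix from [variation_basis()]; defaults to the
#'   five-function basis for the series length.
#' @return An object of class `DetrendResult`: list with `residual`,
#'   `coefficients` (one per basis column, on the original basis scale)
#'   and `fitted`.
#' @export
detrend <- function(series, basis = NULL) {
  y <- if (inherits(series, "ExpressionSeries")) series$values else as.numeric(series)
  if (anyNA(y)) stop("detrend requires a complete series (interpolate first)")
  p <- length(y)
  if (is.null(basis)) basis <- variation_basis(p)
  stopifnot(nrow(basis) == p)
  if (p < ncol(basis)) stop("series shorter than the number of basis functions")
  scl <- sqrt(colSums(basis^2))
  if (any(scl == 0)) stop("zero basis column")
  Bs <- sweep(basis, 2L, scl, `/`)
  qrB <- qr(Bs)
  if (qrB$rank < ncol(Bs)) stop("singular normal-equations system: basis is rank deficient")
  coef_s <- qr.coef(qrB, y)
  fitted <- drop(Bs %*% coef_s)
  structure(list(residual = y - fitted,
                 coefficients = stats::setNames(coef_s / scl, colnames(basis)),
                 fitted = fitted),
            class = "DetrendResult")
}

#' Run the full pre-processing pipeline over a series set
#'
#' Applies [triage_missing()], [interpolate_missing()] and [detrend()] to
#' every series. Dropped series are excluded from the output; the triage
#' report counts every decision reason.
#'
#' @param set A [series_set()].
#' @param basis Optional basis matrix passed to [detrend()].
#' @return List with `set` (a [series_set()] of detrended residual series,
#'   input order preserved), `report` (named integer vector over all
#'   triage reasons) and `decisions` (per-probe reason, named).
#' @export
preprocess_set <- function(set, basis = NULL) {
  stopifnot(inherits(set, "SeriesSet"))
  n <- length(set)
  reasons <- character(n)
  keep <- logical(n)
  p <- ncol(set$values)
  out_vals <- set$values
  for (i in seq_len(n)) {
    s <- get_series(set, i)
    dec <- triage_missing(s)
    reasons[i] <- dec$reason
    keep[i] <- dec$keep
    if (dec$keep) {
      s <- interpolate_missing(s)
      out_vals[i, ] <- detrend(s, basis = basis)$residual
    }
  }
  report <- stats::setNames(integer(length(triage_reasons)), triage_reasons)
  tab <- table(factor(reasons, levels = triage_reasons))
  report[names(tab)] <- as.integer(tab)
  cleaned <- series_set(out_vals[keep, , drop = FALSE], set$probe_ids[keep],
                        set$gene_ids[keep], set$time_step)
  list(set = cleaned, report = report,
       decisions = stats::setNames(reasons, set$probe_ids))
}
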