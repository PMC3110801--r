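# Independent oracles used by the unit and acceptance tests. These are
# deliberately written as direct transcriptions of the defining formulas,
# sharing no code with the implementation paths they check.

# O(N^2) direct summation of X_k = sum_n x_n exp(-2*pi*i*k*n/N)
oracle_dft <- function(x) {
  n <- length(x)
  vapply(0:(n - 1L), function(k) {
    sum(x * exp(complex(real = 0, imaginary = -2 * pi * k * (0:(n - 1L)) / n)))
  }, complex(1))
}

# Monotone piecewise cubic Hermite interpolation via the Hermite basis
# polynomials, with the Fritsch-Carlson/Butland derivative choice written
# out from the defining formulas.
oracle_pchip <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  del <- diff(y) / h
  d <- numeric(n)
  for (k in seq_len(n)) {
    if (k == 1L || k == n) {
      # non-centred three-point estimate, clipped to preserve shape
      if (k == 1L) { ha <- h[1]; hb <- h[2]; da <- del[1]; db <- del[2] }
      else { ha <- h[n - 1]; hb <- h[n - 2]; da <- del[n - 1]; db <- del[n - 2] }
      dd <- ((2 * ha + hb) * da - ha * db) / (ha + hb)
      if (dd * da <= 0) dd <- 0
      else if (da * db < 0 && abs(dd) > 3 * abs(da)) dd <- 3 * da
      d[k] <- dd
    } else if (del[k - 1] * del[k] <= 0) {
      d[k] <- 0
    } else {
      w1 <- 2 * h[k] + h[k - 1]
      w2 <- h[k] + 2 * h[k - 1]
      d[k] <- (w1 + w2) / (w1 / del[k - 1] + w2 / del[k])
    }
  }
  vapply(xout, function(xo) {
    j <- max(which(x <= xo + 1e-12))
    j <- min(j, n - 1L)
    t <- (xo - x[j]) / h[j]
    h00 <- 2 * t^3 - 3 * t^2 + 1
    h10 <- t^3 - 2 * t^2 + t
    h01 <- -2 * t^3 + 3 * t^2
    h11 <- t^3 - t^2
    h00 * y[j] + h10 * h[j] * d[j] + h01 * y[j + 1] + h11 * h[j] * d[j + 1]
  }, numeric(1))
}

# Soft-margin RBF-SVM dual solved by a penalty-augmented box-constrained
# quasi-Newton maximisation (L-BFGS-B); independent of the SMO path.
oracle_svm_dual <- function(X, y, C, gamma, rho = 1e4) {
  n <- nrow(X)
  K <- exp(-gamma * as.matrix(stats::dist(X))^2)
  Q <- K * tcrossprod(y)
  negobj <- function(a) -(sum(a) - 0.5 * drop(a %*% Q %*% a)) + rho * sum(a * y)^2
  grad <- function(a) -(1 - drop(Q %*% a)) + 2 * rho * sum(a * y) * y
  fit <- stats::optim(rep(C / 2, n), negobj, grad, method = "L-BFGS-B",
                      lower = rep(0, n), upper = rep(C, n),
                      control = list(maxit = 2000, factr = 1e4))
  a <- fit$par
  free <- a > 1e-6 * C & a < C * (1 - 1e-6)
  b <- if (any(free)) {
    mean(y[free] - drop(K[free, , drop = FALSE] %*% (a * y)))
  } else 0
  list(alpha = a, b = b,
       decision = function(Xnew) {
         D2 <- outer(rowSums(Xnew^2), rowSums(X^2), `+`) - 2 * Xnew %*% t(X)
         drop(exp(-gamma * D2) %*% (a * y)) + b
       })
}

# exact triage keep-probability under iid missingness for series length p:
# keep iff <=2 missing, none adjacent, endpoints observed
oracle_keep_probability <- function(p, m) {
  interior <- p - 2L
  n_pairs <- choose(interior, 2L) - (interior - 1L)
  (1 - m)^p +
    interior * m * (1 - m)^(p - 1L) +
    n_pairs * m^2 * (1 - m)^(p - 2L)
}

make_series <- function(values, probe = "p1", gene = "G1") {
  expression_series(probe, gene, values)
}

# series of length n with missing positions `miss`
masked_series <- function(n = 47L, miss = integer(0), probe = "p1", gene = "G1") {
  v <- sin(seq_len(n) / 3) + 0.01 * seq_len(n)
  v[miss] <- NA_real_
  expression_series(probe, gene, v)
}

random_feature_clusters <- function(n_per_class, d = 24L, sep = 6, sd = 1) {
  pos <- matrix(rnorm(n_per_class * d, mean = sep / 2, sd = sd), n_per_class, d)
  neg <- matrix(rnorm(n_per_class * d, mean = -sep / 2, sd = sd), n_per_class, d)
  list(pos = pos, neg = neg)
}
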