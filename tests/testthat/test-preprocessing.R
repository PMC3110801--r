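test_that("triage routes every missingness pattern to its stated outcome", {
  cases <- list(
    list(miss = integer(0), keep = TRUE, reason = "complete"),
    list(miss = c(10L, 11L), keep = FALSE, reason = "drop_successive"),
    list(miss = c(5L, 20L, 40L), keep = FALSE, reason = "drop_three_or_more"),
    list(miss = c(5L, 20L), keep = TRUE, reason = "interpolate_2"),
    list(miss = 12L, keep = TRUE, reason = "interpolate_1"),
    list(miss = 1L, keep = FALSE, reason = "drop_endpoint"),
    list(miss = 47L, keep = FALSE, reason = "drop_endpoint"),
    # successive outranks the count rule; 3+ outranks the endpoint rule
    list(miss = c(3L, 4L, 20L), keep = FALSE, reason = "drop_successive"),
    list(miss = c(1L, 20L, 40L), keep = FALSE, reason = "drop_three_or_more"))
  for (cs in cases) {
    dec <- triage_missing(masked_series(47L, cs$miss))
    expect_equal(dec$reason, cs$reason, label = paste(cs$miss, collapse = ","))
    expect_equal(dec$keep, cs$keep)
  }
  expect_error(triage_missing(make_series(c(1, NA))), "at least 3")
})

test_that("interpolation preserves observed values and never overshoots", {
  s <- masked_series(47L, c(9L, 30L))
  out <- interpolate_missing(s)
  expect_false(any(out$missing_mask))
  expect_equal(out$values[-c(9, 30)], s$values[-c(9, 30)])

  expect_identical(interpolate_missing(masked_series(47L)), masked_series(47L))
  expect_error(interpolate_missing(masked_series(47L, 1L)), "endpoint")

  # monotone data 1,2,.,4: the filled value stays inside [2,4]
  g <- make_series(c(1, 2, NA, 4))
  filled <- interpolate_missing(g)$values[3]
  expect_gte(filled, 2)
  expect_lte(filled, 4)

  # property: random monotone series, gap value bounded by its bracket
  withr::with_seed(7, {
    for (rep in 1:25) {
      v <- cumsum(runif(15, 0, 2))
      gap <- sample(3:13, 1)
      w <- v; w[gap] <- NA
      f <- interpolate_missing(make_series(w))$values[gap]
      expect_gte(f, v[gap - 1] - 1e-12)
      expect_lte(f, v[gap + 1] + 1e-12)
    }
  })
})

test_that("interpolation matches the independent monotone-Hermite oracle", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      v <- rnorm(47)
      gaps <- sort(sample(seq(3, 45, by = 3), 2))
      w <- v; w[gaps] <- NA
      mine <- interpolate_missing(make_series(w))$values[gaps]
      ref <- oracle_pchip(setdiff(1:47, gaps), v[-gaps], gaps)
      expect_equal(mine, ref, tolerance = 1e-9)
    }
  })
})

test_that("detrend satisfies its least-squares contract", {
  t <- 1:47
  # input in the basis span -> zero residual
  d <- detrend(3 + 0.2 * t)
  expect_lt(max(abs(d$residual)), 1e-8)
  d2 <- detrend(1 - 0.5 * t + 0.01 * t^2 - 1e-4 * t^3 + 2 * log(t))
  expect_lt(max(abs(d2$residual)), 1e-6)
  expect_equal(unname(d2$coefficients), c(1, -0.5, 0.01, -1e-4, 2), tolerance = 1e-6)

  withr::with_seed(5, {
    for (rep in 1:10) {
      y <- rnorm(47, sd = 2) + 0.1 * t
      r <- detrend(y)$residual
      expect_lt(abs(mean(r)), 1e-8)                       # constant basis
      B <- variation_basis(47)
      expect_lt(max(abs(crossprod(B, r))) / sqrt(sum(y^2)) / max(sqrt(colSums(B^2))),
                1e-6)                                     # orthogonality
      expect_equal(detrend(r)$residual, r, tolerance = 1e-8)  # idempotence
    }
  })
  expect_error(detrend(c(1, NA, 3, 4, 5)), "complete")
})

test_that("detrending keeps most of a mid-band sinusoid's power", {
  t <- 1:47
  tone <- sin(2 * pi * 5 * t / 47)
  x <- tone + 0.1 * t
  resid <- detrend(x)$residual
  ratio <- power_features(resid)[["k5"]] / power_features(tone)[["k5"]]

  # oracle: project the bare sinusoid onto the basis complement directly
  # through the normal equations, then take the k = 5 power ratio
  B <- cbind(1, t, t^2, t^3, log(t))
  resid_oracle <- tone - drop(B %*% solve(crossprod(B), crossprod(B, tone)))
  pw5 <- function(v) Mod(sum(v * exp(-2i * pi * 5 * (seq_along(v) - 1) / length(v))))^2
  ratio_oracle <- pw5(resid_oracle) / pw5(tone)

  expect_equal(ratio, ratio_oracle, tolerance = 1e-8)
  # frozen oracle value: the five-basis projection absorbs ~16% of the
  # tone power (the anticipated >= 0.9 retention is not attained by this
  # basis; the oracle value is authoritative)
  expect_equal(ratio_oracle, 0.8393182, tolerance = 1e-5)
  expect_gt(ratio, 0.8)
})

test_that("preprocess_set composes triage, interpolation and detrending", {
  vals <- rbind(sin(1:47 / 4),
                replace(sin(1:47 / 4), 10:11, NA),
                replace(sin(1:47 / 4), 20, NA))
  set <- series_set(vals, c("a", "b", "c"), c("GA", "GB", "GC"))
  out <- preprocess_set(set)
  expect_equal(out$set$probe_ids, c("a", "c"))
  expect_equal(unname(out$report[c("complete", "interpolate_1", "drop_successive")]),
               c(1L, 1L, 1L))
  expect_equal(sum(out$report), 3L)
  expect_false(anyNA(out$set$values))
  # residuals really are detrended
  expect_lt(abs(mean(out$set$values[1, ])), 1e-8)

  empty <- preprocess_set(series_set(matrix(0, 0, 47), character(0), character(0)))
  expect_equal(length(empty$set), 0L)
})

test_that("triage keep-rate under iid missingness matches the closed form", {
  p <- 47L; m <- 0.03; n_rep <- 2000L
  kept <- withr::with_seed(123, {
    vapply(seq_len(n_rep), function(i) {
      mask <- runif(p) < m
      v <- rnorm(p); v[mask] <- NA
      triage_missing(expression_series("p", "g", v))$keep
    }, logical(1))
  })
  expected <- oracle_keep_probability(p, m)
  se <- sqrt(expected * (1 - expected) / n_rep)
  expect_lt(abs(mean(kept) - expected), 4 * se)
})
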