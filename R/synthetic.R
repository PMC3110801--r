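#' Configuration for the synthetic series generators
#'
#' Describes one simulated probe series: a deterministic trend over the
#' detrending basis, optional sinusoidal (cell-cycle-like) components,
#' i.i.d. Gaussian noise, and a missing-value pattern matching one triage
#' branch. Defaults mirror the reference experiment: 47 hourly points
#' spanning three cell cycles, so the default cycle frequency index is
#' k = 3.
#'
#' @param n_points Series length (default 47).
#' @param time_step Sampling interval in hours (default 1).
#' @param trend Coefficients over [variation_basis()] columns
#'   (1, t, t^2, t^3, ln t); zero-padded/truncated to 5.
#' @param periodic_components List of `list(k, amplitude, phase)` tones;
#'   `k` must lie in 1..floor(n_points/2).
#' @param noise_sd Gaussian noise SD on the log2-ratio scale (default
#'   0.3).
#' @param missing List `list(n, pattern)`; pattern one of `"none"`,
#'   `"separated"`, `"successive"`, `"endpoint"`.
#' @param seed Optional integer; when `NULL` the generator draws from the
#'   caller's RNG stream (used by the pool generators for a single seeded
#'   stream).
#' @return An object of class `GeneratorConfig`.
#' @export
generator_config <- function(n_points = 47L, time_step = 1, trend = c(0, 0, 0, 0, 0),
                             periodic_components = list(), noise_sd = 0.3,
                             missing = list(n = 0L, pattern = "none"),
                             seed = NULL) {
  n_points <- as.integer(n_points)
  stopifnot(n_points >= 5L, noise_sd >= 0)
  trend <- rep_len(c(as.numeric(trend), rep(0, 5L)), 5L)
  for (pc in periodic_components) {
    k <- pc$k
    if (is.null(k) || k < 1L || k > n_points %/% 2L) {
      stop("periodic component frequency index must lie in 1..", n_points %/% 2L)
    }
  }
  missing$n <- as.integer(missing$n %||% 0L)
  missing$pattern <- missing$pattern %||% "none"
  if (!missing$pattern %in% c("none", "separated", "successive", "endpoint")) {
    stop("unknown missing pattern: ", missing$pattern)
  }
  if (missing$pattern == "none" && missing$n > 0L) {
    stop("missing n > 0 requires a pattern")
  }
  structure(list(n_points = n_points, time_step = time_step, trend = trend,
                 periodic_components = periodic_components, noise_sd = noise_sd,
                 missing = missing, seed = seed),
            class = "GeneratorConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() misbehaves on length-1 numeric input; always index
pick_one <- function(x) x[sample.int(length(x), 1L)]

with_config_seed <- function(config, expr) {
  if (is.null(config$seed)) expr else withr::with_seed(config$seed, expr)
}

generate_series_impl <- function(config, probe_id, gene_id) {
  n <- config$n_points
  t <- seq_len(n)
  x <- drop(variation_basis(n) %*% config$trend)
  for (pc in config$periodic_components) {
    phase <- pc$phase %||% 0
    x <- x + pc$amplitude * sin(2 * pi * pc$k * t / n + phase)
  }
  if (config$noise_sd > 0) x <- x + rnorm(n, sd = config$noise_sd)
  mask <- missing_mask_for(config$missing, n)
  x[mask] <- NA_real_
  expression_series(probe_id, gene_id, x, missing_mask = mask,
                    time_step = config$time_step)
}

missing_mask_for <- function(missing, n) {
  mask <- rep(FALSE, n)
  n_miss <- missing$n
  if (missing$pattern == "none" || n_miss == 0L) return(mask)
  if (missing$pattern == "endpoint") {
    mask[1L] <- TRUE
    if (n_miss > 1L) mask[n] <- TRUE
  } else if (missing$pattern == "successive") {
    run <- max(n_miss, 2L)
    start <- pick_one(2:(n - run))
    mask[start + seq_len(run) - 1L] <- TRUE
  } else { # separated: interior, pairwise non-adjacent
    interior <- 2:(n - 1L)
    picked <- integer(0)
    while (length(picked) < n_miss) {
      cand <- pick_one(setdiff(interior, c(picked - 1L, picked, picked + 1L)))
      picked <- c(picked, cand)
    }
    mask[picked] <- TRUE
  }
  mask
}

#' Generate a steady (housekeeping-like) series
#'
#' Trend plus Gaussian noise, no periodic component: the expression
#' profile of a constitutively expressed gene.
#'
#' @param config A [generator_config()] with empty
#'   `periodic_components`.
#' @param probe_id,gene_id Identifiers for the resulting series.
#' @return An [expression_series()].
#' @export
generate_steady_series <- function(config, probe_id = "steady_1",
                                   gene_id = toupper(probe_id)) {
  stopifnot(inherits(config, "GeneratorConfig"))
  if (length(config$periodic_components) > 0L) {
    stop("steady series must have no periodic components")
  }
  with_config_seed(config, generate_series_impl(config, probe_id, gene_id))
}

#' Generate a periodic (cell-cycle-like) series
#'
#' Trend plus one or more sinusoidal tones plus Gaussian noise: the
#' profile of a cycle-regulated gene, with its power concentrated at the
#' planted frequency indices.
#'
#' @param config A [generator_config()] with at least one periodic
#'   component.
#' @param probe_id,gene_id Identifiers for the resulting series.
#' @return An [expression_series()].
#' @export
generate_periodic_series <- function(config, probe_id = "periodic_1",
                                     gene_id = toupper(probe_id)) {
  stopifnot(inherits(config, "GeneratorConfig"))
  if (length(config$periodic_components) == 0L) {
    stop("periodic series needs at least one periodic component")
  }
  with_config_seed(config, generate_series_impl(config, probe_id, gene_id))
}

#' Generate labelled probe pools with planted mislabels
#'
#' Builds a [series_set()] and [partition_probes()]-style partition whose
#' pools mirror the reference setting: the standard pool is purely steady
#' series; the putative pool mixes true housekeeping (steady) probes with
#' periodic decoys (false annotations); the non-HKG pool is mostly
#' periodic with a minority of steady "missed HKG" probes. Ground-truth
#' labels are recorded so selection can be scored.
#'
#' @param n_standard,n_putative_true,n_putative_false,n_nonhkg_true,n_nonhkg_false
#'   Pool composition counts. `putative_true` probes are steady (correct
#'   HKG annotations), `putative_false` periodic decoys; `nonhkg_true`
#'   probes are genuinely non-housekeeping (periodic) while
#'   `nonhkg_false` are steady "missed HKG" false negatives.
#' @param steady_cfg,periodic_cfg [generator_config()]s for the two
#'   series classes (their `seed` fields are ignored; one stream derives
#'   from `seed`).
#' @param seed Integer seed for the whole set.
#' @return List with `set` (a [series_set()]), `partition` (a
#'   `ProbePartition`) and `truth` (named logical: TRUE = housekeeping).
#' @export
generate_labeled_pools <- function(n_standard, n_putative_true, n_putative_false,
                                   n_nonhkg_true, n_nonhkg_false,
                                   steady_cfg = generator_config(),
                                   periodic_cfg = generator_config(
                                     periodic_components = list(list(k = 3L, amplitude = 1))),
                                   seed = 1L) {
  counts <- c(n_standard, n_putative_true, n_putative_false,
              n_nonhkg_true, n_nonhkg_false)
  stopifnot(all(counts >= 0L))
  steady_cfg$seed <- NULL
  periodic_cfg$seed <- NULL
  plan <- data.frame(
    pool = rep(c("standard", "putative", "putative", "non_hkg", "non_hkg"), counts),
    hkg = rep(c(TRUE, TRUE, FALSE, FALSE, TRUE), counts),
    stringsAsFactors = FALSE)
  n <- nrow(plan)
  probe_ids <- sprintf("%s_p%03d", toupper(substr(plan$pool, 1L, 3L)), seq_len(n))
  gene_ids <- sprintf("G%03d", seq_len(n))
  n_points <- steady_cfg$n_points
  stopifnot(periodic_cfg$n_points == n_points)
  vals <- matrix(NA_real_, n, n_points)
  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      cfg <- if (plan$hkg[i]) steady_cfg else periodic_cfg
      vals[i, ] <- generate_series_impl(cfg, probe_ids[i], gene_ids[i])$values
    }
  })
  set <- series_set(vals, probe_ids, gene_ids, steady_cfg$time_step)
  partition <- structure(
    list(standard = probe_ids[plan$pool == "standard"],
         putative = probe_ids[plan$pool == "putative"],
         non_hkg = probe_ids[plan$pool == "non_hkg"]),
    class = "ProbePartition")
  list(set = set, partition = partition,
       truth = stats::setNames(plan$hkg, probe_ids))
}

#' Generate a tissue matrix with planted CV classes
#'
#' Housekeeping-like genes get low relative variability across tissues,
#' tissue-specific genes high: value_gt ~ Normal(mu_g, (cv * mu_g)^2)
#' with per-gene means near `base_mean` on the log2 scale.
#'
#' @param n_hkg,n_specific Gene counts for the two classes.
#' @param n_tissues Number of tissue columns (>= 2).
#' @param hkg_cv,specific_cv Planted coefficients of variation (defaults
#'   0.05 and 0.5).
#' @param base_mean Centre of the per-gene means (log2 scale, default 8).
#' @param seed Integer seed.
#' @return List with `matrix` (a [tissue_matrix()]) and `truth` (named
#'   logical: TRUE = housekeeping-like).
#' @export
generate_tissue_matrix <- function(n_hkg, n_specific, n_tissues,
                                   hkg_cv = 0.05, specific_cv = 0.5,
                                   base_mean = 8, seed = 1L) {
  stopifnot(n_hkg >= 0L, n_specific >= 0L, n_tissues >= 2L,
            hkg_cv >= 0, specific_cv >= 0, base_mean > 0)
  n <- n_hkg + n_specific
  hkg <- rep(c(TRUE, FALSE), c(n_hkg, n_specific))
  gene_ids <- sprintf("%s%03d", ifelse(hkg, "HK", "TS"), seq_len(n))
  vals <- withr::with_seed(seed, {
    mu <- rnorm(n, mean = base_mean, sd = 0.05 * base_mean)
    cv <- ifelse(hkg, hkg_cv, specific_cv)
    t(vapply(seq_len(n),
             function(g) rnorm(n_tissues, mean = mu[g], sd = cv[g] * abs(mu[g])),
             numeric(n_tissues)))
  })
  list(matrix = tissue_matrix(vals, gene_ids,
                              sprintf("tissue_%02d", seq_len(n_tissues))),
       truth = stats::setNames(hkg, gene_ids))
}

#' Write a synthetic pool set to pipeline-ready files
#'
#' Emits the TSV expression matrix plus three plain-text gene lists whose
#' membership reproduces the pools: standard genes appear on all three
#' lists, putative genes on the first only, non-HKG genes on none. This
#' lets the files round-trip through [read_series_matrix()],
#' [read_gene_list()] and [partition_probes()].
#'
#' @param pools A [generate_labeled_pools()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, named character vector of the written paths.
#' @export
write_pool_files <- function(pools, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set <- pools$set
  matrix_path <- file.path(dir, "series_matrix.tsv")
  vals <- set$values
  cells <- ifelse(is.na(vals), "", format(vals, trim = TRUE, digits = 10))
  rows <- cbind(set$probe_ids, set$gene_ids, cells)
  writeLines(apply(rows, 1L, paste, collapse = "\t"), matrix_path)
  std_genes <- set$gene_ids[set$probe_ids %in% pools$partition$standard]
  put_genes <- set$gene_ids[set$probe_ids %in% pools$partition$putative]
  paths <- c(matrix = matrix_path,
             list1 = file.path(dir, "hkg_list1.txt"),
             list2 = file.path(dir, "hkg_list2.txt"),
             list3 = file.path(dir, "hkg_list3.txt"),
             truth = file.path(dir, "truth.tsv"))
  writeLines(c(std_genes, put_genes), paths["list1"])
  writeLines(std_genes, paths["list2"])
  writeLines(std_genes, paths["list3"])
  write.table(data.frame(probe_id = names(pools$truth), is_hkg = pools$truth),
              paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
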