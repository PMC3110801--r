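#' Bootstrap SVM voting over resampled negative pools
#'
#' A single train/predict round is biased by whichever negatives happen to
#' be drawn; repeating the round with freshly resampled negatives and
#' tallying per-probe votes removes that stochastic bias. Each round
#' trains on all standard-pool probes (positives) against `n_neg` probes
#' sampled without replacement from the non-HKG pool, then scores every
#' putative-pool and non-HKG-pool probe; a probe's count increments when
#' the round predicts it to be an HKG. Probes serving as negatives in a
#' round are still scored by that round's model, so every scored probe is
#' eligible in all rounds and counts share the common 0..rounds scale the
#' integer cut-offs assume.
#'
#' @param features Numeric feature matrix with probe ids as rownames.
#' @param partition A [partition_probes()] result.
#' @param rounds Number of bootstrap rounds (reference configuration:
#'   4096 = 2^12).
#' @param n_neg Negatives sampled per round (reference: 234, matching the
#'   positive-set size).
#' @param spec A [classifier_spec()].
#' @param seed Integer seed; the tally is deterministic given it.
#' @param standardize Passed to [train_classifier()].
#' @param verbose Log progress at every power-of-two round (default
#'   FALSE).
#' @return An object of class `VoteTally`: list with `rounds`, `counts`
#'   (named integer vector over all scored probes) and `eligibility`
#'   (rounds scored, here `rounds` for every probe).
#' @export
run_voting <- function(features, partition, rounds = 4096L, n_neg = 234L,
                       spec, seed, standardize = TRUE, verbose = FALSE) {
  stopifnot(inherits(partition, "ProbePartition"), inherits(spec, "ClassifierSpec"))
  features <- as.matrix(features)
  std <- intersect(partition$standard, rownames(features))
  non <- intersect(partition$non_hkg, rownames(features))
  put <- intersect(partition$putative, rownames(features))
  rounds <- as.integer(rounds)
  n_neg <- as.integer(n_neg)
  if (length(std) == 0L) stop("standard pool is empty")
  if (length(non) <= n_neg) {
    stop("non-HKG pool (", length(non), ") must exceed n_neg (", n_neg, ")")
  }
  scored <- c(put, non)
  counts <- stats::setNames(integer(length(scored)), scored)
  pos_feat <- features[std, , drop = FALSE]
  score_feat <- features[scored, , drop = FALSE]
  withr::with_seed(seed, {
    for (r in seq_len(rounds)) {
      neg <- sample(non, n_neg)
      model <- train_classifier(pos_feat, features[neg, , drop = FALSE],
                                spec, standardize = standardize)
      votes <- predict(model, score_feat)
      counts <- counts + as.integer(votes)
      if (verbose && bitwAnd(r, r - 1L) == 0L) {
        message(sprintf("round %d/%d: %d probes currently above 50%% ballot",
                        r, rounds, sum(counts > r / 2)))
      }
    }
  })
  structure(list(rounds = rounds, counts = counts,
                 eligibility = stats::setNames(rep(rounds, length(scored)), scored)),
            class = "VoteTally")
}

#' Construct a vote tally
#'
#' Assembles a `VoteTally` from counts already obtained (e.g. read back
#' from a tally TSV); [run_voting()] builds one directly.
#'
#' @param counts Named integer vector, probe_id -> vote count.
#' @param rounds Total rounds.
#' @param eligibility Named integer vector of rounds each probe was
#'   scored in; defaults to `rounds` for every probe.
#' @return An object of class `VoteTally`.
#' @export
vote_tally <- function(counts, rounds, eligibility = NULL) {
  rounds <- as.integer(rounds)
  stopifnot(rounds >= 1L, !is.null(names(counts)))
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (is.null(eligibility)) {
    eligibility <- stats::setNames(rep(rounds, length(counts)), names(counts))
  }
  if (any(counts < 0L | counts > eligibility[names(counts)] |
          eligibility > rounds)) {
    stop("need 0 <= counts <= eligibility <= rounds for every probe")
  }
  structure(list(rounds = rounds, counts = counts, eligibility = eligibility),
            class = "VoteTally")
}

#' @export
print.VoteTally <- function(x, ...) {
  cat(sprintf("<VoteTally> %d probes over %d rounds; max count %s\n",
              length(x$counts), x$rounds,
              if (length(x$counts)) max(x$counts) else "NA"))
  invisible(x)
}

#' Ballot percentage of a vote count
#'
#' 100 * count / rounds, rounded half-up to two decimals: 3328 of 4096
#' rounds is an 81.25% ballot, 4085 of 4096 is 99.73%.
#'
#' @param count Integer vote count(s), 0 <= count <= rounds.
#' @param rounds Total rounds, > 0.
#' @return Numeric percentage(s) with two-decimal resolution.
#' @export
ballot_percent <- function(count, rounds) {
  if (any(rounds <= 0)) stop("rounds must be positive")
  if (any(count < 0 | count > rounds)) stop("count must lie in [0, rounds]")
  v <- 100 * count / rounds
  floor(v * 100 + 0.5 + 1e-9) / 100
}

#' Select housekeeping genes from a vote tally
#'
#' Aggregates probe counts to genes (a gene's score is the maximum count
#' over its probes) and applies the pool-specific thresholds: putative-
#' pool genes are selected when their best count reaches
#' `putative_cutoff` (inclusive); non-HKG-pool genes only when it exceeds
#' `nonhkg_cutoff` (strict). Standard-pool genes are the training
#' positives of every round and are selected unconditionally.
#'
#' @param tally A [run_voting()] result.
#' @param partition A [partition_probes()] result covering every probe in
#'   the tally.
#' @param putative_cutoff Inclusive minimum count for putative-pool genes
#'   (reference: 3328 of 4096, the 81.25% ballot).
#' @param nonhkg_cutoff Exclusive minimum count for non-HKG-pool genes
#'   (reference: 4085 of 4096, the 99.73% ballot).
#' @param map Named character vector probe_id -> gene_id (see
#'   [probe_gene_map()]).
#' @return Data frame of class `HkgPredictions`, one row per gene:
#'   `gene_id`, `best_probe_id`, `vote_count`, `ballot_percent`,
#'   `source_pool`, `selected`. Standard-pool genes that were never
#'   scored carry `NA` counts.
#' @export
select_hkgs <- function(tally, partition, putative_cutoff, nonhkg_cutoff, map) {
  stopifnot(inherits(tally, "VoteTally"), inherits(partition, "ProbePartition"))
  if (any(c(putative_cutoff, nonhkg_cutoff) < 0) ||
      any(c(putative_cutoff, nonhkg_cutoff) > tally$rounds)) {
    stop("cutoffs must lie in [0, rounds]")
  }
  pools <- probe_pool(partition, names(tally$counts))
  if (anyNA(pools)) {
    stop("probe in tally absent from partition: ",
         paste(utils::head(names(tally$counts)[is.na(pools)], 3L), collapse = ", "))
  }
  all_probes <- c(partition$standard, partition$putative, partition$non_hkg)
  all_probes <- all_probes[all_probes %in% names(map)]
  genes <- unique(unname(map[all_probes]))
  genes <- genes[nzchar(genes)]
  rows <- lapply(genes, function(g) {
    probes <- all_probes[map[all_probes] == g]
    cnt <- tally$counts[probes]
    names(cnt) <- probes
    if (all(is.na(cnt))) {
      best_probe <- probes[1L]
      best_count <- NA_integer_
    } else {
      best_probe <- names(cnt)[which.max(cnt)]
      best_count <- as.integer(max(cnt, na.rm = TRUE))
    }
    pool <- probe_pool(partition, best_probe)
    selected <- switch(pool,
      standard = TRUE,
      putative = !is.na(best_count) && best_count >= putative_cutoff,
      non_hkg = !is.na(best_count) && best_count > nonhkg_cutoff)
    data.frame(gene_id = g, best_probe_id = best_probe,
               vote_count = best_count,
               ballot_percent = if (is.na(best_count)) NA_real_ else
                 ballot_percent(best_count, tally$rounds),
               source_pool = pool, selected = selected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), best_probe_id = character(0),
                      vote_count = integer(0), ballot_percent = numeric(0),
                      source_pool = character(0), selected = logical(0),
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("HkgPredictions", "data.frame")
  out
}

#' Histogram of vote counts within a pool
#'
#' @param tally A [run_voting()] result.
#' @param partition A [partition_probes()] result.
#' @param pool `"putative"`, `"non_hkg"` or `"all"`.
#' @param min_count Only probes with count >= `min_count` are included
#'   (the reference figures use 3000 and 4000).
#' @return Named integer vector: frequency per observed count value.
#' @export
count_histogram <- function(tally, partition, pool = c("all", "putative", "non_hkg"),
                            min_count = 0L) {
  stopifnot(inherits(tally, "VoteTally"))
  pool <- match.arg(pool)
  probes <- names(tally$counts)
  if (pool != "all") {
    keep <- switch(pool, putative = partition$putative, non_hkg = partition$non_hkg)
    probes <- intersect(probes, keep)
  }
  cnt <- tally$counts[probes]
  cnt <- cnt[cnt >= min_count]
  if (length(cnt) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(cnt)
  stats::setNames(as.integer(tab), names(tab))
}

#' Write a vote tally as TSV
#'
#' Columns: probe_id, pool, count, ballot_percent.
#'
#' @param tally A [run_voting()] result.
#' @param partition A [partition_probes()] result.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_tally <- function(tally, partition, path) {
  df <- data.frame(probe_id = names(tally$counts),
                   pool = probe_pool(partition, names(tally$counts)),
                   count = unname(tally$counts),
                   ballot_percent = ballot_percent(unname(tally$counts), tally$rounds),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$probe_id), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
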