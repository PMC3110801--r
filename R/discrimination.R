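#' HN vs NN model comparison
#'
#' Tests whether power-spectrum features carry housekeeping-gene signal.
#' Per replicate, the HN ("true") model trains on standard-HKG probes as
#' positives against freshly sampled non-HKG negatives; the NN ("control")
#' model uses two disjoint random non-HKG samples as the two classes.
#' Each replicate's data are split stratified 50/50 into train and test
#' halves; the held-out accuracy is recorded. Under the control model the
#' two classes are exchangeable, so its accuracy hovers at chance level;
#' an HN distribution well above it demonstrates class signal in the
#' spectra.
#'
#' @param features Numeric feature matrix with probe ids as rownames.
#' @param partition A [partition_probes()] result.
#' @param n_replicates Number of replicates (reference configuration:
#'   1024).
#' @param n_per_class Probes per class (reference: 234, the standard-pool
#'   size).
#' @param spec A [classifier_spec()].
#' @param seed Integer seed; the whole experiment is deterministic given
#'   it.
#' @param standardize Passed to [train_classifier()].
#' @return An object of class `ComparisonResult`: list with numeric
#'   vectors `hn_accuracies`, `nn_accuracies` (both length
#'   `n_replicates`, values in [0,1]) and `n_replicates`.
#' @export
run_model_comparison <- function(features, partition, n_replicates = 1024L,
                                 n_per_class = 234L, spec, seed,
                                 standardize = TRUE) {
  stopifnot(inherits(partition, "ProbePartition"), inherits(spec, "ClassifierSpec"))
  features <- as.matrix(features)
  std <- intersect(partition$standard, rownames(features))
  non <- intersect(partition$non_hkg, rownames(features))
  n_replicates <- as.integer(n_replicates)
  n_per_class <- as.integer(n_per_class)
  if (length(std) < n_per_class) {
    stop("standard pool too small: ", length(std), " < ", n_per_class)
  }
  if (length(non) < 2L * n_per_class) {
    stop("non-HKG pool too small: ", length(non), " < ", 2L * n_per_class)
  }
  hn <- numeric(n_replicates)
  nn <- numeric(n_replicates)
  withr::with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      pos_hn <- if (length(std) == n_per_class) std else sample(std, n_per_class)
      neg_hn <- sample(non, n_per_class)
      hn[r] <- split_train_test_accuracy(features[pos_hn, , drop = FALSE],
                                         features[neg_hn, , drop = FALSE],
                                         spec, standardize)
      both <- sample(non, 2L * n_per_class)
      pos_nn <- both[seq_len(n_per_class)]
      neg_nn <- both[n_per_class + seq_len(n_per_class)]
      nn[r] <- split_train_test_accuracy(features[pos_nn, , drop = FALSE],
                                         features[neg_nn, , drop = FALSE],
                                         spec, standardize)
    }
  })
  structure(list(hn_accuracies = hn, nn_accuracies = nn,
                 n_replicates = n_replicates),
            class = "ComparisonResult")
}

# stratified 50/50 split, train on one half, accuracy on the other
split_train_test_accuracy <- function(pos, neg, spec, standardize) {
  tr_pos <- sample(nrow(pos), nrow(pos) %/% 2L)
  tr_neg <- sample(nrow(neg), nrow(neg) %/% 2L)
  model <- train_classifier(pos[tr_pos, , drop = FALSE],
                            neg[tr_neg, , drop = FALSE],
                            spec, standardize = standardize)
  test <- rbind(pos[-tr_pos, , drop = FALSE], neg[-tr_neg, , drop = FALSE])
  truth <- c(rep(TRUE, nrow(pos) - length(tr_pos)),
             rep(FALSE, nrow(neg) - length(tr_neg)))
  mean(predict(model, test) == truth)
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf(paste0("<ComparisonResult> %d replicates\n",
                     "  HN (true model):    mean accuracy %.3f\n",
                     "  NN (control model): mean accuracy %.3f\n"),
              x$n_replicates, mean(x$hn_accuracies), mean(x$nn_accuracies)))
  invisible(x)
}

#' Write the two accuracy distributions as TSV
#'
#' @param result A [run_model_comparison()] result.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_comparison <- function(result, path) {
  stopifnot(inherits(result, "ComparisonResult"))
  df <- data.frame(replicate = seq_len(result$n_replicates),
                   hn_accuracy = result$hn_accuracies,
                   nn_accuracy = result$nn_accuracies)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
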