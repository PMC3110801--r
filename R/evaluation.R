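#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean.
#' Housekeeping genes show low CV across tissues. When the mean is within
#' `epsilon` of zero the ratio is meaningless and `NA` is returned; such
#' genes are excluded from profiles.
#'
#' @param values Numeric vector, length >= 2.
#' @param epsilon Threshold on |mean| below which CV is undefined.
#' @return CV, or `NA_real_` when undefined.
#' @export
coefficient_of_variation <- function(values, epsilon = 1e-6) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values")
  if (anyNA(values)) stop("missing values in input")
  m <- mean(values)
  if (abs(m) < epsilon) return(NA_real_)
  stats::sd(values) / m
}

#' Gene-by-tissue expression matrix
#'
#' Log2-scale expression values, genes in rows and tissues in columns.
#' Rows sharing a gene id (multiple probes for one gene) are averaged.
#'
#' @param values Numeric matrix.
#' @param gene_ids Character vector, one per row (duplicates are
#'   averaged).
#' @param tissue_ids Character vector, one per column.
#' @return An object of class `TissueMatrix` wrapping the averaged
#'   matrix.
#' @export
tissue_matrix <- function(values, gene_ids, tissue_ids = colnames(values)) {
  values <- as.matrix(values)
  gene_ids <- as.character(gene_ids)
  stopifnot(nrow(values) == length(gene_ids))
  if (is.null(tissue_ids)) tissue_ids <- paste0("tissue_", seq_len(ncol(values)))
  if (anyNA(values)) stop("tissue matrix must not contain missing values")
  if (anyDuplicated(gene_ids)) {
    values <- rowsum(values, gene_ids, reorder = FALSE) /
      as.vector(table(factor(gene_ids, levels = unique(gene_ids))))
    gene_ids <- rownames(values)
  }
  dimnames(values) <- list(gene_ids, tissue_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 tissue_ids = as.character(tissue_ids)),
            class = "TissueMatrix")
}

#' @export
print.TissueMatrix <- function(x, ...) {
  cat(sprintf("<TissueMatrix> %d genes x %d tissues\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a gene-by-tissue TSV matrix
#'
#' First column gene id, header row of tissue ids, log2 values.
#'
#' @param path Path to the file.
#' @return A [tissue_matrix()].
#' @export
read_tissue_matrix <- function(path) {
  if (!file.exists(path)) stop("cannot read tissue matrix: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  tissue_matrix(as.matrix(df[-1]), df[[1]], colnames(df)[-1])
}

#' Per-gene CV profile of a tissue matrix
#'
#' @param matrix A [tissue_matrix()] (>= 2 tissues).
#' @param epsilon Passed to [coefficient_of_variation()].
#' @return An object of class `CvProfile`: list with `cv` (named numeric
#'   over genes with defined CV) and `excluded_genes` (near-zero mean).
#' @export
cv_profile <- function(matrix, epsilon = 1e-6) {
  stopifnot(inherits(matrix, "TissueMatrix"))
  if (ncol(matrix$values) < 2L) stop("need at least 2 tissues")
  cv <- apply(matrix$values, 1L, coefficient_of_variation, epsilon = epsilon)
  structure(list(cv = cv[!is.na(cv)], excluded_genes = names(cv)[is.na(cv)]),
            class = "CvProfile")
}

#' @export
print.CvProfile <- function(x, ...) {
  cat(sprintf("<CvProfile> %d genes (median CV %.4f), %d excluded (near-zero mean)\n",
              length(x$cv), stats::median(x$cv), length(x$excluded_genes)))
  invisible(x)
}

#' Median CV of a gene set
#'
#' Median over the set's genes that have a defined CV in the profile
#' (even-count sets use the mean-of-middle-pair convention). Duplicate
#' listings in the set are ignored; genes absent from the profile are
#' counted and reported in the `"n_missing"` attribute.
#'
#' @param gene_set Character vector of gene ids.
#' @param profile A [cv_profile()] result.
#' @return Median CV (numeric scalar) with attribute `n_missing`.
#' @export
median_cv <- function(gene_set, profile) {
  stopifnot(inherits(profile, "CvProfile"))
  genes <- unique(as.character(gene_set))
  present <- genes[genes %in% names(profile$cv)]
  if (length(present) == 0L) stop("no gene in the set has a defined CV")
  out <- stats::median(profile$cv[present])
  attr(out, "n_missing") <- length(genes) - length(present)
  out
}

#' Gene conservation score from per-exon-base scores
#'
#' A transcript's score is the mean of its per-base conservation scores
#' over exons (phastCons-style probabilities in [0, 1]); the gene score
#' is the unweighted mean over its transcripts.
#'
#' @param mrna_exon_scores List with one numeric vector of per-base
#'   scores per mRNA (a single vector is accepted for one mRNA).
#' @return Gene-level conservation score in [0, 1] for [0, 1] input.
#' @export
conservation_score <- function(mrna_exon_scores) {
  if (is.numeric(mrna_exon_scores)) mrna_exon_scores <- list(mrna_exon_scores)
  if (length(mrna_exon_scores) == 0L) stop("no mRNA score vectors supplied")
  per_mrna <- vapply(mrna_exon_scores, function(s) {
    s <- as.numeric(s)
    if (length(s) == 0L || anyNA(s)) stop("each mRNA needs >= 1 non-missing base score")
    mean(s)
  }, numeric(1))
  mean(per_mrna)
}
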