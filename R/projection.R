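#' Fit principal components on primary tumors
#'
#' Selects the genes with the largest cross-sample variance (default
#' 5000, or all genes if fewer), centers each gene on its training mean
#' (no scaling) and takes the singular value decomposition, as
#' `stats::prcomp` does. Loadings follow a deterministic sign convention —
#' each loading's entry of largest magnitude is positive — so score tables
#' are reproducible across platforms. Variance-explained fractions are
#' relative to the total variance of the retained genes.
#'
#' @param x expression matrix of training (primary tumor) samples.
#' @param n_genes number of top-variance genes to retain (default 5000).
#' @param n_components leading components to keep (default
#'   `min(5, rank)`, at least 5 when the rank allows).
#' @return object of class `pca_model`: `genes`, `means`, `loadings`
#'   (genes x components), `var_explained`, `sdev`.
#' @export
fit_pca <- function(x, n_genes = 5000, n_components = 5) {
  x <- expression_matrix(x)
  if (ncol(x) < 2) stop("need >= 2 samples", call. = FALSE)
  if (n_genes < 2) stop("n_genes must be >= 2", call. = FALSE)
  v <- apply(x, 1, stats::var)
  keep <- rownames(x)[order(v, decreasing = TRUE)[seq_len(min(n_genes,
                                                              nrow(x)))]]
  xs <- x[keep, , drop = FALSE]
  pc <- stats::prcomp(t(xs), center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  k <- min(max(n_components, 1), rank, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude entry of each loading positive
  flip <- vapply(seq_len(k), function(j) {
    i <- which.max(abs(load[, j]))
    sign(load[i, j])
  }, numeric(1))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, `*`)
  total_var <- sum(apply(xs, 1, stats::var))
  structure(list(genes = keep,
                 means = pc$center,
                 loadings = load,
                 sdev = pc$sdev[seq_len(k)],
                 var_explained = pc$sdev[seq_len(k)]^2 / total_var),
            class = "pca_model")
}

#' Project samples onto a fitted PCA model
#'
#' Subtracts the TRAINING gene means and multiplies by the training
#' loadings, so new samples (e.g. liver metastases) land in the component
#' space defined by the primary tumors. Projecting the training data
#' reproduces its own scores.
#'
#' @param model a `pca_model` from [fit_pca()].
#' @param x expression matrix containing all model genes.
#' @return samples x components score matrix.
#' @export
project_pca <- function(model, x) {
  x <- expression_matrix(x)
  missing <- setdiff(model$genes, rownames(x))
  if (length(missing))
    stop("model gene(s) absent from input: ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  xs <- t(x[model$genes, , drop = FALSE])
  scores <- sweep(xs, 2, model$means) %*% model$loadings
  colnames(scores) <- colnames(model$loadings)
  scores
}

#' Correlate component scores with per-sample covariates
#'
#' Pearson correlation of every (component, covariate) pair, used e.g. to
#' relate PC scores to single-sample gene-set scores. Missing pairs are
#' dropped pairwise; a constant covariate yields NA, not an error.
#'
#' @param scores samples x components numeric matrix.
#' @param covariates samples x covariates numeric matrix or data.frame
#'   (rownames or a `sample_id` column matching the scores).
#' @return components x covariates matrix of Pearson r.
#' @export
correlate_scores <- function(scores, covariates) {
  if (is.data.frame(covariates)) {
    if ("sample_id" %in% names(covariates)) {
      rn <- covariates$sample_id
      covariates <- as.matrix(covariates[, setdiff(names(covariates),
                                                   "sample_id"),
                                         drop = FALSE])
      rownames(covariates) <- rn
    } else covariates <- as.matrix(covariates)
  }
  common <- intersect(rownames(scores), rownames(covariates))
  if (length(common) < 3)
    stop("need >= 3 paired observations", call. = FALSE)
  s <- scores[common, , drop = FALSE]
  cv <- covariates[common, , drop = FALSE]
  r <- suppressWarnings(stats::cor(s, cv, use = "pairwise.complete.obs",
                                   method = "pearson"))
  r
}
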