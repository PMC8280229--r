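#' Estimate the per-sample liver-background proportion
#'
#' Bulk profiles of liver metastases carry an additive expression signal
#' from surrounding hepatocytes. The background score of sample *i* is
#' `p_i = sum_j z_ij * g_j`, where `z` is the gene-wise (row) mean-centered
#' expression matrix and `g_j` indicates membership of gene *j* in the
#' hepatocyte marker panel; the proportion is the min–max normalization
#' `P_i = (p_i - p_min) / (p_max - p_min)` across the cohort, so `min(P) = 0`
#' and `max(P) = 1`. When all `p_i` coincide the estimate is degenerate and
#' `P` is set to 0 for every sample.
#'
#' @param x expression matrix, genes x samples (log2 scale).
#' @param markers character vector of hepatocyte marker gene ids.
#' @return object of class `background_estimate`: list with `p` (raw
#'   scores), `P` (proportions in \[0,1\]), `p_min`, `p_max`, `degenerate`,
#'   `markers_used`.
#' @export
estimate_background <- function(x, markers) {
  x <- expression_matrix(x)
  if (ncol(x) < 2)
    stop("need at least 2 samples (min-max normalization undefined)",
         call. = FALSE)
  if (!length(markers)) stop("marker list is empty", call. = FALSE)
  found <- intersect(markers, rownames(x))
  if (!length(found))
    stop("no marker genes present in the matrix; missing: ",
         paste(utils::head(markers, 10), collapse = ", "), call. = FALSE)
  if (length(found) < length(markers) / 2)
    warning(sprintf("only %d of %d marker genes found in the matrix",
                    length(found), length(markers)), call. = FALSE)
  z <- x - rowMeans(x)
  p <- colSums(z[found, , drop = FALSE])
  p_min <- min(p); p_max <- max(p)
  degenerate <- (p_max - p_min) == 0
  P <- if (degenerate) stats::setNames(rep(0, length(p)), names(p))
       else (p - p_min) / (p_max - p_min)
  structure(list(p = p, P = P, p_min = p_min, p_max = p_max,
                 degenerate = degenerate, markers_used = found),
            class = "background_estimate")
}

#' Regress the liver background out of an expression matrix
#'
#' For every gene, ordinary least squares of its expression across samples
#' on the background proportion `P` (with intercept); the residuals replace
#' the expression values. A single global scalar is then added to the whole
#' matrix so that its minimum is exactly 0. The default shift is
#' `max(0, -min(residuals))`; `literal_shift = TRUE` adds
#' `abs(min(residuals))` unconditionally, which inflates an all-positive
#' residual matrix but reproduces the historical behaviour bit-for-bit.
#'
#' @param x expression matrix the estimate was computed on.
#' @param est a [estimate_background()] result for the same samples.
#' @param literal_shift use the unconditional `abs(min)` shift.
#' @return expression matrix of shifted residuals, same shape and ids as
#'   `x`, minimum value 0.
#' @export
regress_out_background <- function(x, est, literal_shift = FALSE) {
  x <- expression_matrix(x)
  if (!inherits(est, "background_estimate"))
    stop("est must come from estimate_background()", call. = FALSE)
  if (est$degenerate)
    stop("degenerate background estimate (all samples identical); ",
         "skip the adjustment instead", call. = FALSE)
  if (!identical(names(est$P), colnames(x)))
    stop("estimate and matrix cover different samples", call. = FALSE)
  design <- cbind(intercept = 1, P = est$P)
  fit <- stats::lm.fit(design, t(x))
  resid <- t(fit$residuals)
  mn <- min(resid)
  shift <- if (literal_shift) abs(mn) else max(0, -mn)
  out <- resid + shift
  dimnames(out) <- dimnames(x)
  out
}

#' Flag tumor samples dominated by liver signal
#'
#' A tumor sample is discarded when its raw background score `p_i` reaches
#' the 10th percentile of scores observed in pure normal-liver reference
#' samples — i.e. it looks at least as liver-like as the bottom of the
#' normal-liver distribution. Percentiles use linear interpolation between
#' order statistics (quantile type 7), package-wide.
#'
#' @param x expression matrix of tumor samples.
#' @param est [estimate_background()] result for `x`.
#' @param normal_liver_scores numeric vector of raw `p` scores from normal
#'   liver reference samples (>= 2 values).
#' @param probs reference percentile defining the threshold (default 0.10).
#' @return list with `kept`, `discarded` (sample id vectors) and
#'   `threshold`.
#' @export
filter_contaminated_samples <- function(x, est, normal_liver_scores,
                                        probs = 0.10) {
  if (!inherits(est, "background_estimate"))
    stop("est must come from estimate_background()", call. = FALSE)
  if (length(normal_liver_scores) < 2)
    stop("need >= 2 normal-liver reference scores", call. = FALSE)
  thr <- stats::quantile(normal_liver_scores, probs = probs, type = 7,
                         names = FALSE)
  discard <- est$p >= thr
  list(kept = names(est$p)[!discard],
       discarded = names(est$p)[discard],
       threshold = thr)
}
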