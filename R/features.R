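#' Select cancer-cell-intrinsic classifier features
#'
#' Heuristic feature selection on microenvironment-free reference profiles
#' (cell lines / organoids), enriching for robustly expressed, variable
#' genes. Two filters, applied sequentially:
#'
#' 1. keep gene g if its maximum expression over samples is strictly above
#'    the first tertile (33.33rd percentile) of the pooled value
#'    distribution of the whole matrix — drops never-expressed genes;
#' 2. among survivors, keep g if its 10th–90th inter-percentile range
#'    (IPR) across samples reaches the 90th percentile of the gene-wise
#'    IPR distribution — keeps roughly the top 10% most variable genes,
#'    ties at the cutoff included.
#'
#' All percentiles use linear interpolation (quantile type 7).
#'
#' @param ref expression matrix of reference profiles (genes x samples,
#'   >= 3 samples).
#' @param ipr_top fraction of filter-(i) survivors retained by IPR
#'   (default 0.10).
#' @return object of class `feature_set`: list with `genes`, the pooled
#'   `tertile_cutoff` and the `ipr_cutoff` used.
#' @export
select_intrinsic_features <- function(ref, ipr_top = 0.10) {
  ref <- expression_matrix(ref)
  if (ncol(ref) < 3)
    stop("need >= 3 reference samples for percentile-based selection",
         call. = FALSE)
  tertile <- stats::quantile(as.vector(ref), probs = 1 / 3, type = 7,
                             names = FALSE)
  pass1 <- apply(ref, 1, max) > tertile
  if (!any(pass1))
    stop("no features: no gene exceeds the pooled first tertile",
         call. = FALSE)
  sub <- ref[pass1, , drop = FALSE]
  q <- apply(sub, 1, stats::quantile, probs = c(0.10, 0.90), type = 7,
             names = FALSE)
  ipr <- q[2, ] - q[1, ]
  ipr_cut <- stats::quantile(ipr, probs = 1 - ipr_top, type = 7,
                             names = FALSE)
  genes <- rownames(sub)[ipr >= ipr_cut]
  if (!length(genes)) stop("no features pass the IPR filter", call. = FALSE)
  structure(list(genes = genes, tertile_cutoff = tertile,
                 ipr_cutoff = ipr_cut),
            class = "feature_set")
}

as_feature_genes <- function(features) {
  if (inherits(features, "feature_set")) features$genes
  else as.character(features)
}
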