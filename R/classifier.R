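CMS_CLASSES <- c("CMS1", "CMS2", "CMS3", "CMS4")

# per-class training statistics shared by train_nsc and tune_loocv
nsc_stats <- function(xs, labels, min_per_class = 2) {
  classes <- sort(unique(labels))
  n <- ncol(xs)
  counts <- table(factor(labels, levels = classes))
  if (any(counts < min_per_class))
    stop("every class needs >= 2 samples; offending: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  overall <- rowMeans(xs)
  centroids <- vapply(classes, function(k)
    rowMeans(xs[, labels == k, drop = FALSE]), numeric(nrow(xs)))
  # pooled within-class variance, denominator n - K
  ssw <- rowSums(vapply(classes, function(k) {
    xc <- xs[, labels == k, drop = FALSE] - centroids[, k]
    rowSums(xc^2)
  }, numeric(nrow(xs))))
  s <- sqrt(ssw / (n - length(classes)))
  s0 <- stats::median(s)
  m <- sqrt(1 / as.numeric(counts) - 1 / n)
  names(m) <- classes
  list(classes = classes, n = n, counts = as.numeric(counts),
       overall = overall, centroids = centroids, s = s, s0 = s0, m = m,
       priors = stats::setNames(as.numeric(counts) / n, classes))
}

# soft-threshold centroids toward the overall centroid; works directly in
# expression units so zero-dispersion genes cannot produce Inf * 0
nsc_shrink <- function(st, t) {
  diff <- st$centroids - st$overall
  if (is.infinite(t))                          # full shrinkage limit
    return(st$centroids - diff)
  denom <- outer(st$s + st$s0, st$m)           # genes x classes
  shrunk <- sign(diff) * pmax(abs(diff) - t * denom, 0)
  st$overall + shrunk
}

#' Train a nearest-shrunken-centroids (PAM) subtype classifier
#'
#' Class centroids are shrunk toward the overall centroid by
#' soft-thresholding the standardized deviations
#' `d_kj = (xbar_kj - xbar_j) / (m_k (s_j + s0))`, where `s_j` is the
#' pooled within-class standard deviation, `s0 = median(s_j)` stabilizes
#' near-constant genes and `m_k = sqrt(1/n_k - 1/n)`. At `t = 0` shrunken
#' centroids equal the raw class means; above the largest `|d_kj|` every
#' centroid collapses onto the overall centroid and prediction reduces to
#' the class priors.
#'
#' @param x expression matrix, genes x samples (background-adjusted for
#'   liver metastases).
#' @param labels per-sample class labels (no NA); names, when present,
#'   must match the sample ids.
#' @param features a [select_intrinsic_features()] result or character
#'   vector of predictor gene ids; all must be present in `x`.
#' @param t shrinkage threshold (>= 0).
#' @param cutoff posterior confidence cutoff `c` for prediction
#'   (default 0.5).
#' @return object of class `nsc_model`.
#' @export
train_nsc <- function(x, labels, features, t = 1.5, cutoff = 0.5) {
  x <- expression_matrix(x)
  genes <- as_feature_genes(features)
  missing <- setdiff(genes, rownames(x))
  if (length(missing))
    stop("feature gene(s) absent from the matrix: ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  labels <- as.character(labels)
  if (anyNA(labels)) stop("training labels must be confident (no NA)",
                          call. = FALSE)
  if (length(labels) != ncol(x))
    stop("one label per sample required", call. = FALSE)
  if (t < 0) stop("shrinkage t must be >= 0", call. = FALSE)
  st <- nsc_stats(x[genes, , drop = FALSE], labels)
  denom <- outer(st$s + st$s0, st$m)
  d <- (st$centroids - st$overall) / denom
  d[denom == 0] <- 0
  structure(list(classes = st$classes,
                 genes = genes,
                 overall_centroid = st$overall,
                 centroids = st$centroids,
                 shrunken_centroids = nsc_shrink(st, t),
                 s = st$s, s0 = st$s0,
                 priors = st$priors,
                 t = t, cutoff = cutoff,
                 max_abs_d = max(abs(d))),
            class = "nsc_model")
}

nsc_discriminant <- function(model, xs) {
  disp <- (model$s + model$s0)^2
  if (any(disp == 0))
    stop("zero-dispersion feature(s); cannot score", call. = FALSE)
  delta <- vapply(model$classes, function(k) {
    colSums((xs - model$shrunken_centroids[, k])^2 / disp) -
      2 * log(model$priors[k])
  }, numeric(ncol(xs)))
  matrix(delta, ncol = length(model$classes),
         dimnames = list(colnames(xs), model$classes))
}

softmax_posterior <- function(delta) {
  half <- -delta / 2
  half <- half - apply(half, 1, max)           # invariant to delta shifts
  p <- exp(half)
  p / rowSums(p)
}

format_calls <- function(posterior, cutoff) {
  nearest <- colnames(posterior)[max.col(posterior, ties.method = "first")]
  maxp <- apply(posterior, 1, max)
  out <- data.frame(sample_id = rownames(posterior), posterior,
                    nearest = nearest,
                    call = ifelse(maxp >= cutoff, nearest, NA_character_),
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out
}

#' Predict subtypes with a trained NSC model
#'
#' The discriminant of class k for sample s is
#' `delta_k(s) = sum_j (x_js - xbar'_kj)^2 / (s_j + s0)^2 - 2 log pi_k`;
#' posteriors are `softmax(-delta/2)`. The confident `call` is the nearest
#' class when its posterior reaches the cutoff, else `NA` (the `nearest`
#' column is never NA).
#'
#' @param model an `nsc_model` from [train_nsc()].
#' @param x expression matrix containing all model features.
#' @param cutoff posterior confidence cutoff; defaults to the model's.
#' @return data.frame: `sample_id`, one posterior column per class,
#'   `nearest`, `call`.
#' @export
predict_nsc <- function(model, x, cutoff = model$cutoff) {
  x <- expression_matrix(x)
  missing <- setdiff(model$genes, rownames(x))
  if (length(missing))
    stop("model feature(s) absent from input: ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  xs <- x[model$genes, , drop = FALSE]
  delta <- nsc_discriminant(model, xs)
  format_calls(softmax_posterior(delta), cutoff)
}

#' Tune the shrinkage threshold by leave-one-out cross-validation
#'
#' Each sample is predicted by a model refit on the remaining n-1 samples;
#' accuracy at each grid value is the fraction of held-out samples whose
#' nearest (ungated) class matches the label. The chosen `t` maximizes
#' accuracy, ties broken toward the largest `t` (sparsest model).
#'
#' @param x,labels,features as in [train_nsc()].
#' @param t_grid non-negative thresholds; default 30 linearly spaced
#'   points from 0 to the largest `|d_kj|` of the unshrunken fit.
#' @return object of class `tuning_curve`: list with `t_grid`, `accuracy`,
#'   `chosen_t`.
#' @export
tune_loocv <- function(x, labels, features, t_grid = NULL) {
  x <- expression_matrix(x)
  genes <- as_feature_genes(features)
  missing <- setdiff(genes, rownames(x))
  if (length(missing))
    stop("feature gene(s) absent from the matrix: ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  labels <- as.character(labels)
  xs <- x[genes, , drop = FALSE]
  if (is.null(t_grid)) {
    full <- train_nsc(x, labels, genes, t = 0)
    t_grid <- seq(0, full$max_abs_d, length.out = 30)
  }
  if (!length(t_grid) || any(t_grid < 0))
    stop("t_grid must be non-empty and non-negative", call. = FALSE)
  n <- ncol(xs)
  hits <- matrix(0L, nrow = length(t_grid), ncol = n)
  for (i in seq_len(n)) {
    st <- nsc_stats(xs[, -i, drop = FALSE], labels[-i], min_per_class = 1)
    disp <- (st$s + st$s0)^2
    if (any(disp == 0))
      stop("zero-dispersion feature(s) in a LOOCV fold", call. = FALSE)
    held <- xs[, i]
    for (g in seq_along(t_grid)) {
      cen <- nsc_shrink(st, t_grid[g])
      delta <- vapply(st$classes, function(k)
        sum((held - cen[, k])^2 / disp) - 2 * log(st$priors[k]),
        numeric(1))
      hits[g, i] <- as.integer(st$classes[which.min(delta)] == labels[i])
    }
  }
  acc <- rowMeans(hits)
  best <- max(acc)
  chosen <- max(t_grid[acc == best])           # ties -> largest t
  structure(list(t_grid = t_grid, accuracy = acc, chosen_t = chosen),
            class = "tuning_curve")
}

#' Solve the confidence cutoff for a target NA fraction
#'
#' Returns the cutoff `c` such that gating the given posterior calls at
#' `c` leaves approximately `target_na` of the cohort unassigned — the
#' operational rule of matching the unassigned proportion of a reference
#' classifier.
#'
#' @param calls a prediction data.frame from [predict_nsc()] (or the
#'   distilled forest).
#' @param target_na desired NA fraction in \[0, 1\].
#' @return the cutoff value.
#' @export
cutoff_for_na_fraction <- function(calls, target_na) {
  stopifnot(target_na >= 0, target_na <= 1)
  post <- as.matrix(calls[, intersect(colnames(calls), CMS_CLASSES),
                          drop = FALSE])
  if (!ncol(post))
    post <- as.matrix(calls[, setdiff(colnames(calls),
                                      c("sample_id", "nearest", "call")),
                            drop = FALSE])
  maxp <- apply(post, 1, max)
  if (target_na == 0) return(min(maxp))
  # smallest cutoff strictly above the target_na quantile of max posteriors
  q <- stats::quantile(maxp, probs = target_na, type = 7, names = FALSE)
  q + 1e-12
}

## ---- distilled random forest ------------------------------------------
## No random-forest package is assumed; a compact bagged-CART forest with
## Gini splits and sqrt(p) features per split is implemented here.

gini_best_split <- function(xcol, y_int, n_class) {
  ord <- order(xcol)
  xv <- xcol[ord]; yv <- y_int[ord]
  n <- length(yv)
  counts_left <- integer(n_class)
  counts_right <- tabulate(yv, n_class)
  best <- list(gain = -Inf, threshold = NA_real_)
  total_imp <- 1 - sum((counts_right / n)^2)
  for (i in seq_len(n - 1)) {
    k <- yv[i]
    counts_left[k] <- counts_left[k] + 1L
    counts_right[k] <- counts_right[k] - 1L
    if (xv[i] == xv[i + 1]) next
    nl <- i; nr <- n - i
    imp <- nl / n * (1 - sum((counts_left / nl)^2)) +
           nr / n * (1 - sum((counts_right / nr)^2))
    gain <- total_imp - imp
    if (gain > best$gain) {
      best$gain <- gain
      best$threshold <- (xv[i] + xv[i + 1]) / 2
    }
  }
  best
}

grow_tree <- function(xs, y_int, n_class, mtry) {
  counts <- tabulate(y_int, n_class)
  if (sum(counts > 0) == 1L || nrow(xs) < 2L)
    return(list(leaf = TRUE, counts = counts))
  feat <- sample.int(ncol(xs), min(mtry, ncol(xs)))
  best <- list(gain = 0, feature = NA_integer_, threshold = NA_real_)
  for (j in feat) {
    s <- gini_best_split(xs[, j], y_int, n_class)
    if (is.finite(s$gain) && s$gain > best$gain) {
      best$gain <- s$gain; best$feature <- j; best$threshold <- s$threshold
    }
  }
  if (is.na(best$feature))
    return(list(leaf = TRUE, counts = counts))
  left <- xs[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = grow_tree(xs[left, , drop = FALSE], y_int[left],
                        n_class, mtry),
       right = grow_tree(xs[!left, , drop = FALSE], y_int[!left],
                         n_class, mtry))
}

tree_vote <- function(node, xrow) {
  while (!node$leaf)
    node <- if (xrow[node$feature] <= node$threshold) node$left
            else node$right
  which.max(node$counts)
}

#' Distill the NSC classifier into a background-free random forest
#'
#' Trains a bagged-CART random forest on the RAW (unadjusted) expression
#' of the feature genes against the confident labels produced by
#' [predict_nsc()] on background-adjusted data. The forest absorbs the
#' liver-background axis into its splits, so it can be applied directly
#' to metastasis profiles without marker lists or normal-liver references.
#' NA-labeled samples are excluded from training. Deterministic given
#' `seed`.
#'
#' @param labels per-sample labels (typically the `call` column of a
#'   [predict_nsc()] result; NA allowed, excluded).
#' @param x_raw unadjusted expression matrix for the same samples.
#' @param features predictor genes, as in [train_nsc()].
#' @param n_trees number of trees (default 500).
#' @param seed mandatory RNG seed.
#' @param cutoff posterior (vote-fraction) confidence cutoff.
#' @return object of class `rf_model`.
#' @export
distill_random_forest <- function(labels, x_raw, features, n_trees = 500,
                                  seed, cutoff = 0.5) {
  if (missing(seed)) stop("seed is mandatory for the forest", call. = FALSE)
  x_raw <- expression_matrix(x_raw)
  genes <- as_feature_genes(features)
  missing_g <- setdiff(genes, rownames(x_raw))
  if (length(missing_g))
    stop("feature gene(s) absent from the matrix: ",
         paste(utils::head(missing_g, 10), collapse = ", "), call. = FALSE)
  labels <- as.character(labels)
  keep <- !is.na(labels)
  if (length(unique(labels[keep])) < 2)
    stop("need >= 2 distinct confident labels to distill", call. = FALSE)
  classes <- sort(unique(labels[keep]))
  xs <- t(x_raw[genes, keep, drop = FALSE])    # samples x features
  y_int <- match(labels[keep], classes)
  mtry <- max(1L, floor(sqrt(length(genes))))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  trees <- vector("list", n_trees)
  n <- nrow(xs)
  for (b in seq_len(n_trees)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- grow_tree(xs[idx, , drop = FALSE], y_int[idx],
                            length(classes), mtry)
  }
  structure(list(classes = classes, genes = genes, trees = trees,
                 n_trees = n_trees, mtry = mtry, seed = seed,
                 cutoff = cutoff),
            class = "rf_model")
}

#' Predict subtypes with a distilled random forest
#'
#' Posterior = per-class tree-vote fractions, gated at the cutoff exactly
#' like [predict_nsc()].
#'
#' @param model an `rf_model` from [distill_random_forest()].
#' @param x expression matrix (raw scale; no background adjustment
#'   needed).
#' @param cutoff confidence cutoff; defaults to the model's.
#' @return data.frame in the [predict_nsc()] format.
#' @export
predict_rf <- function(model, x, cutoff = model$cutoff) {
  x <- expression_matrix(x)
  missing_g <- setdiff(model$genes, rownames(x))
  if (length(missing_g))
    stop("model feature(s) absent from input: ",
         paste(utils::head(missing_g, 10), collapse = ", "), call. = FALSE)
  xs <- t(x[model$genes, , drop = FALSE])
  votes <- matrix(0, nrow = nrow(xs), ncol = length(model$classes),
                  dimnames = list(rownames(xs), model$classes))
  for (tr in model$trees)
    for (i in seq_len(nrow(xs))) {
      k <- tree_vote(tr, xs[i, ])
      votes[i, k] <- votes[i, k] + 1
    }
  format_calls(votes / length(model$trees), cutoff)
}
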