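#' Odds ratio with 95% confidence interval for a 2x2 table
#'
#' The table is `(a, b)` in the exposed row and `(c, d)` in the unexposed
#' row (e.g. exposure = PC1 > 0, outcome = CMS1/CMS4 membership). Two
#' estimators:
#'
#' * `conditional_mle` (default): the conditional maximum-likelihood
#'   estimate under the noncentral hypergeometric distribution with the
#'   exact conditional CI, as computed by `stats::fisher.test`.
#' * `sample`: the cross-product ratio `a*d / (b*c)` with the Woolf
#'   log-normal CI; zero cells trigger the Haldane–Anscombe 0.5
#'   correction with a warning.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param method `"conditional_mle"` or `"sample"`.
#' @param conf_level confidence level (default 0.95).
#' @return list: `estimate`, `conf_low`, `conf_high`, `method`.
#' @export
odds_ratio <- function(a, b, c, d, method = c("conditional_mle", "sample"),
                       conf_level = 0.95) {
  method <- match.arg(method)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  if (sum(cells) == 0) stop("empty table", call. = FALSE)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stop("zero margin; odds ratio undefined", call. = FALSE)
  if (method == "conditional_mle") {
    ft <- stats::fisher.test(matrix(c(a, c, b, d), nrow = 2),
                             conf.level = conf_level)
    return(list(estimate = unname(ft$estimate),
                conf_low = ft$conf.int[1], conf_high = ft$conf.int[2],
                method = method))
  }
  if (any(cells == 0)) {
    warning("zero cell; applying Haldane-Anscombe 0.5 correction",
            call. = FALSE)
    cells <- cells + 0.5
  }
  est <- cells["a"] * cells["d"] / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(estimate = unname(est),
       conf_low = unname(est * exp(-z * se)),
       conf_high = unname(est * exp(z * se)),
       method = method)
}

#' Per-subtype enrichment of metastases versus primaries
#'
#' For each class, a 2x2 table of (class k vs rest) x (metastasis vs
#' primary) is formed from CONFIDENT calls only and passed to
#' [odds_ratio()]. OR > 1 means the class is enriched among metastases.
#'
#' @param met_calls,prim_calls character vectors of confident subtype
#'   calls (NA allowed; dropped).
#' @param classes classes to report (default the four CMS groups present).
#' @param method estimator passed to [odds_ratio()].
#' @return data.frame: `class`, `n_met`, `n_prim`, `or`, `conf_low`,
#'   `conf_high`.
#' @export
proportion_shift <- function(met_calls, prim_calls, classes = NULL,
                             method = "conditional_mle") {
  met <- met_calls[!is.na(met_calls)]
  prim <- prim_calls[!is.na(prim_calls)]
  if (!length(met) || !length(prim))
    stop("need confident calls in both cohorts", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(c(met, prim)))
  rows <- lapply(classes, function(k) {
    a <- sum(met == k);  b <- sum(met != k)
    c_ <- sum(prim == k); d <- sum(prim != k)
    or <- odds_ratio(a, b, c_, d, method = method)
    data.frame(class = k, n_met = a, n_prim = c_, or = or$estimate,
               conf_low = or$conf_low, conf_high = or$conf_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
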