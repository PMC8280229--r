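#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the classification
#' method assumes: four subtype signature blocks (CMS1 MSI/immune, CMS2
#' canonical, CMS3 metabolic, CMS4 mesenchymal/EMT) on a flat log2
#' baseline, plus a hepatocyte marker block that is silent in tumor cells
#' and high in the liver profile mixed additively into metastasis
#' samples. The liver profile also moderately expresses the metabolic
#' (CMS3) block — hepatocytes are metabolic tissue — which is what makes
#' unadjusted classification of contaminated samples collapse toward
#' CMS3 and gives the background regression its purpose.
#'
#' @param seed mandatory RNG seed.
#' @param n_genes total genes (default 2000).
#' @param block_size genes per subtype block (default 50).
#' @param n_hep hepatocyte marker genes (default 50).
#' @param baseline flat log2 baseline of tumor-expressed genes (7).
#' @param hep_baseline baseline of hepatocyte genes in tumor cells (4).
#' @param liver_hep_level hepatocyte-gene level in the liver profile (12).
#' @param liver_cms3_boost liver-profile elevation of the metabolic block
#'   (4 log2 units).
#' @param effect_size subtype-block elevation in tumors (2 log2 units).
#' @param noise_sd within-class Gaussian noise sd (1).
#' @param n_primary_per_class primary tumors per subtype (60).
#' @param n_met metastasis samples (120).
#' @param met_class_weights metastatic subtype frequencies, echoing the
#'   near-90% CMS2/CMS4 predominance (0.05, 0.40, 0.05, 0.50).
#' @param w_range contamination weight range, uniform (0.2–0.5).
#' @param w_fixed optional fixed contamination weight overriding
#'   `w_range`.
#' @param lesion_switch_prob probability a lesion deviates from its
#'   patient's base subtype (0.25).
#' @param max_lesions_per_patient lesions drawn uniformly in 1..max (4).
#' @param n_normal_liver pure normal-liver reference samples (10).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             n_genes = 2000, block_size = 50, n_hep = 50,
                             baseline = 7, hep_baseline = 4,
                             liver_hep_level = 12, liver_cms3_boost = 4,
                             effect_size = 2, noise_sd = 1,
                             n_primary_per_class = 60, n_met = 120,
                             met_class_weights = c(CMS1 = 0.05, CMS2 = 0.40,
                                                   CMS3 = 0.05, CMS4 = 0.50),
                             w_range = c(0.2, 0.5), w_fixed = NULL,
                             lesion_switch_prob = 0.25,
                             max_lesions_per_patient = 4,
                             n_normal_liver = 10) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (n_genes < 4 * block_size + n_hep)
    stop("n_genes must cover 4 blocks + hepatocyte panel", call. = FALSE)
  if (!is.null(w_fixed) && (w_fixed < 0 || w_fixed > 1))
    stop("w_fixed must be in [0, 1]", call. = FALSE)
  if (any(w_range < 0) || any(w_range > 1) || w_range[1] > w_range[2])
    stop("w_range must be an increasing pair in [0, 1]", call. = FALSE)
  if (n_primary_per_class < 1 || n_met < 1)
    stop("sample counts must be positive", call. = FALSE)
  cfg <- as.list(environment())
  cfg$met_class_weights <- met_class_weights / sum(met_class_weights)
  structure(cfg, class = "synthetic_config")
}

synthetic_gene_ids <- function(cfg) {
  blocks <- lapply(CMS_CLASSES, function(k)
    sprintf("%s.%03d", k, seq_len(cfg$block_size)))
  names(blocks) <- CMS_CLASSES
  hep <- sprintf("HEP.%03d", seq_len(cfg$n_hep))
  n_bg <- cfg$n_genes - 4 * cfg$block_size - cfg$n_hep
  bg <- if (n_bg > 0) sprintf("BG.%04d", seq_len(n_bg)) else character(0)
  list(blocks = blocks, hep = hep, bg = bg,
       all = c(unlist(blocks, use.names = FALSE), hep, bg))
}

# noiseless tumor profile of one subtype
tumor_profile <- function(cfg, ids, class) {
  v <- stats::setNames(rep(cfg$baseline, cfg$n_genes), ids$all)
  v[ids$hep] <- cfg$hep_baseline
  v[ids$blocks[[class]]] <- v[ids$blocks[[class]]] + cfg$effect_size
  v
}

liver_profile <- function(cfg, ids) {
  v <- stats::setNames(rep(cfg$baseline, cfg$n_genes), ids$all)
  v[ids$hep] <- cfg$liver_hep_level
  v[ids$blocks$CMS3] <- v[ids$blocks$CMS3] + cfg$liver_cms3_boost
  v
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' The generator's 14 subtype-informative gene sets
#'
#' Synthetic stand-ins for the usual CRC/CMS signature panel (EMT,
#' TGF-beta, stromal, immune, MSI, DNA repair, WNT, MYC, cell cycle,
#' LGR5 stem, MSS, HNF4A, glycolysis, differentiation), wired to the
#' generator's subtype blocks so gene-set scores track the simulated
#' biology.
#'
#' @param cfg a [synthetic_config()].
#' @return named list of 14 gene-id vectors.
#' @export
synthetic_gene_sets <- function(cfg) {
  ids <- synthetic_gene_ids(cfg)
  b <- ids$blocks
  half <- max(3, cfg$block_size %/% 2)
  seg <- function(block, from) {
    n <- length(block)
    idx <- unique(pmin(pmax(seq(from, from + half - 1), 1), n))
    block[idx]
  }
  q <- max(1, cfg$block_size %/% 4)
  list(EMT = seg(b$CMS4, 1),
       TGFB = seg(b$CMS4, q),
       STROMAL = seg(b$CMS4, 2 * q),
       IMMUNE = seg(b$CMS1, 1),
       MSI = seg(b$CMS1, q),
       DNA_REPAIR = seg(b$CMS1, 2 * q),
       WNT = seg(b$CMS2, 1),
       MYC = seg(b$CMS2, q),
       CELL_CYCLE = seg(b$CMS2, 2 * q),
       LGR5_STEM = seg(b$CMS2, 3 * q),
       MSS = c(seg(b$CMS2, 1)[seq_len(max(2, q))],
               seg(b$CMS4, 1)[seq_len(max(2, q))]),
       HNF4A = seg(b$CMS3, 1),
       GLYCOLYSIS = seg(b$CMS3, q),
       DIFFERENTIATION = seg(b$CMS3, 2 * q))
}

#' Generate a synthetic cohort with full ground truth
#'
#' Produces primary tumors (balanced over the four subtypes), liver
#' metastases (subtype frequencies per `met_class_weights`, grouped into
#' patients and lesions, each mixed with the liver profile at its
#' contamination weight `w`) and pure normal-liver reference samples.
#' Expression is `(1 - w) * (tumor + noise) + w * liver_profile`, linear
#' in the log2 working domain. Deterministic given the config seed.
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `synthetic_cohort`: `expr` (genes x samples),
#'   `annotation` (sample/patient/lesion/type + survival fields for
#'   metastasis patients), `truth` (`sample_id`, `true_class`, `w`),
#'   `markers` (hepatocyte ids), `sets` (14 gene sets), `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ids <- synthetic_gene_ids(cfg)
  liver <- liver_profile(cfg, ids)
  with_seed(cfg$seed, {
    ## primaries: balanced classes
    prim_class <- rep(CMS_CLASSES, each = cfg$n_primary_per_class)
    n_prim <- length(prim_class)
    prim <- vapply(prim_class, function(k)
      tumor_profile(cfg, ids, k) + stats::rnorm(cfg$n_genes, 0, cfg$noise_sd),
      numeric(cfg$n_genes))
    colnames(prim) <- sprintf("P%03d", seq_len(n_prim))

    ## metastases: patient/lesion structure with subtype switching
    n_lesion_per_pat <- integer(0)
    while (sum(n_lesion_per_pat) < cfg$n_met)
      n_lesion_per_pat <- c(n_lesion_per_pat,
                            sample.int(cfg$max_lesions_per_patient, 1))
    extra <- sum(n_lesion_per_pat) - cfg$n_met
    n_lesion_per_pat[length(n_lesion_per_pat)] <-
      n_lesion_per_pat[length(n_lesion_per_pat)] - extra
    pat_base <- sample(CMS_CLASSES, length(n_lesion_per_pat),
                       replace = TRUE, prob = cfg$met_class_weights)
    met_class <- character(0); met_pat <- character(0); met_les <- character(0)
    for (p in seq_along(n_lesion_per_pat)) {
      for (l in seq_len(n_lesion_per_pat[p])) {
        cls <- if (stats::runif(1) < cfg$lesion_switch_prob)
          sample(setdiff(CMS_CLASSES, pat_base[p]), 1) else pat_base[p]
        met_class <- c(met_class, cls)
        met_pat <- c(met_pat, sprintf("pt%03d", p))
        met_les <- c(met_les, sprintf("pt%03d_L%d", p, l))
      }
    }
    w <- if (!is.null(cfg$w_fixed)) rep(cfg$w_fixed, cfg$n_met)
         else stats::runif(cfg$n_met, cfg$w_range[1], cfg$w_range[2])
    met <- vapply(seq_len(cfg$n_met), function(i) {
      tumor <- tumor_profile(cfg, ids, met_class[i]) +
        stats::rnorm(cfg$n_genes, 0, cfg$noise_sd)
      (1 - w[i]) * tumor + w[i] * liver
    }, numeric(cfg$n_genes))
    colnames(met) <- sprintf("M%03d", seq_len(cfg$n_met))

    ## normal liver references
    nl <- if (cfg$n_normal_liver > 0)
      vapply(seq_len(cfg$n_normal_liver), function(i)
        liver + stats::rnorm(cfg$n_genes, 0, cfg$noise_sd),
        numeric(cfg$n_genes)) else NULL
    if (!is.null(nl)) colnames(nl) <- sprintf("NL%02d", seq_len(cfg$n_normal_liver))

    expr <- cbind(prim, met, if (!is.null(nl)) nl)
    rownames(expr) <- ids$all

    surv_time <- round(stats::rexp(length(n_lesion_per_pat), rate = 1 / 36), 1)
    surv_event <- stats::rbinom(length(n_lesion_per_pat), 1, 0.7)
    pat_ids <- sprintf("pt%03d", seq_along(n_lesion_per_pat))

    annotation <- rbind(
      data.frame(sample_id = colnames(prim),
                 patient_id = sprintf("pp%03d", seq_len(n_prim)),
                 lesion_id = sprintf("pp%03d_T", seq_len(n_prim)),
                 sample_type = "primary",
                 treatment = NA, survival_time = NA_real_,
                 event = NA_integer_, stringsAsFactors = FALSE),
      data.frame(sample_id = colnames(met),
                 patient_id = met_pat,
                 lesion_id = met_les,
                 sample_type = "metastasis",
                 treatment = "neoadjuvant",
                 survival_time = surv_time[match(met_pat, pat_ids)],
                 event = surv_event[match(met_pat, pat_ids)],
                 stringsAsFactors = FALSE),
      if (!is.null(nl))
        data.frame(sample_id = colnames(nl),
                   patient_id = sprintf("nl%02d", seq_len(cfg$n_normal_liver)),
                   lesion_id = sprintf("nl%02d_N", seq_len(cfg$n_normal_liver)),
                   sample_type = "normal_liver",
                   treatment = NA, survival_time = NA_real_,
                   event = NA_integer_, stringsAsFactors = FALSE))
    truth <- data.frame(
      sample_id = colnames(expr),
      true_class = c(prim_class, met_class,
                     rep(NA_character_, if (is.null(nl)) 0 else ncol(nl))),
      w = c(rep(0, n_prim), w,
            rep(1, if (is.null(nl)) 0 else ncol(nl))),
      stringsAsFactors = FALSE)

    structure(list(expr = expression_matrix(expr),
                   annotation = annotation, truth = truth,
                   markers = ids$hep,
                   sets = synthetic_gene_sets(cfg),
                   config = cfg),
              class = "synthetic_cohort")
  })
}

#' Generate a microenvironment-free reference panel
#'
#' Cell-line / organoid style profiles: subtype blocks at elevated effect
#' size, no liver contamination, reduced noise — the input for
#' [select_intrinsic_features()]. Hepatocyte genes stay at their silent
#' tumor-cell baseline, so selected features never include them.
#'
#' @param cfg a [synthetic_config()].
#' @param n_per_class profiles per subtype (default 15).
#' @param effect_size block elevation (default 3).
#' @param noise_sd noise sd (default 0.5).
#' @return expression matrix (genes x samples) with true classes in
#'   attribute `true_class`.
#' @export
generate_reference_panel <- function(cfg, n_per_class = 15,
                                     effect_size = 3, noise_sd = 0.5) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ids <- synthetic_gene_ids(cfg)
  ref_cfg <- cfg
  ref_cfg$effect_size <- effect_size
  with_seed(cfg$seed + 1L, {
    cls <- rep(CMS_CLASSES, each = n_per_class)
    m <- vapply(cls, function(k)
      tumor_profile(ref_cfg, ids, k) +
        stats::rnorm(cfg$n_genes, 0, noise_sd),
      numeric(cfg$n_genes))
    colnames(m) <- sprintf("REF%03d", seq_along(cls))
    rownames(m) <- ids$all
    out <- expression_matrix(m)
    attr(out, "true_class") <- cls
    out
  })
}
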