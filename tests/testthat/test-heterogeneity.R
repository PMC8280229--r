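make_table <- function(calls, nearest = calls, patient = "p1",
                       lesion = NULL, pc = NULL) {
  n <- length(calls)
  if (is.null(lesion)) lesion <- sprintf("L%d", seq_len(n))
  tab <- data.frame(patient_id = rep_len(patient, n),
                    lesion_id = lesion,
                    sample_id = sprintf("s%d", seq_len(n)),
                    nearest = nearest, call = calls,
                    PC1 = 0, PC2 = 0, PC3 = 0, stringsAsFactors = FALSE)
  if (!is.null(pc)) tab[, c("PC1", "PC2", "PC3")] <- pc
  tab
}

test_that("heterogeneity flag follows confident lesion labels", {
  # {CMS2, CMS2, NA} -> homogeneous (NA excluded)
  h <- assess_heterogeneity(make_table(c("CMS2", "CMS2", NA),
                                       nearest = c("CMS2", "CMS2", "CMS4")))
  expect_false(h$heterogeneous)
  expect_equal(h$n_confident_lesions, 2)
  # {CMS2, CMS4} -> heterogeneous
  expect_true(assess_heterogeneity(make_table(c("CMS2", "CMS4")))$heterogeneous)
  # a single confident lesion can never be heterogeneous
  expect_false(assess_heterogeneity(make_table(c("CMS4", NA)))$heterogeneous)
})

test_that("multi-sample lesions collapse by majority with ties to NA", {
  tab <- make_table(c("CMS2", "CMS4", "CMS4", "CMS2"),
                    lesion = c("L1", "L1", "L1", "L2"))
  h <- assess_heterogeneity(tab)        # L1 majority CMS4, L2 CMS2
  expect_equal(h$n_lesions, 2)
  expect_true(h$heterogeneous)
  tie <- make_table(c("CMS2", "CMS4", "CMS2"), lesion = c("L1", "L1", "L2"))
  ht <- assess_heterogeneity(tie)       # L1 tie -> NA; only L2 confident
  expect_false(ht$heterogeneous)
  expect_equal(ht$n_confident_lesions, 1)
})

test_that("max inter-sample distance is the PC1-PC3 Euclidean maximum", {
  pc <- rbind(c(0, 0, 0), c(3, 4, 0))
  h <- assess_heterogeneity(make_table(c("CMS2", "CMS2"), pc = pc))
  expect_equal(h$max_distance, 5)       # 3-4-5 triangle
  # permutation invariance and zero iff coincident
  pc3 <- rbind(c(1, 1, 1), c(1, 1, 1), c(4, 5, 1))
  tab <- make_table(rep("CMS2", 3), pc = pc3)
  expect_equal(assess_heterogeneity(tab)$max_distance,
               assess_heterogeneity(tab[c(3, 1, 2), ])$max_distance)
  same <- make_table(rep("CMS2", 3), pc = rbind(c(2, 2, 2), c(2, 2, 2),
                                                c(2, 2, 2)))
  expect_equal(assess_heterogeneity(same)$max_distance, 0)
  # missing scores: distance NA, flag still computed
  miss <- make_table(c("CMS2", "CMS4"))
  miss$PC2 <- NA_real_
  hm <- assess_heterogeneity(miss)
  expect_true(is.na(hm$max_distance))
  expect_true(hm$heterogeneous)
})

# brute-force oracle for the worst-subtype rule, straight off the rule text
oracle_worst <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) return(NA_character_)
  if (any(labels %in% c("CMS1", "CMS3"))) return("CMS1/3")
  if (any(labels == "CMS4")) return("CMS4")
  "CMS2"
}

test_that("worst-subtype rule matches the oracle on all label multisets", {
  classes <- c("CMS1", "CMS2", "CMS3", "CMS4")
  for (size in 1:4) {
    combos <- do.call(expand.grid,
                      c(rep(list(classes), size), stringsAsFactors = FALSE))
    for (i in seq_len(nrow(combos))) {
      labs <- as.character(combos[i, ])
      got <- worst_subtype_stratify(make_table(labs), use_nearest = FALSE)
      expect_identical(got$stratum, oracle_worst(labs))
    }
  }
  # the three examples of the published rule
  expect_identical(worst_subtype_stratify(
    make_table(c("CMS2", "CMS4")), use_nearest = FALSE)$stratum, "CMS4")
  expect_identical(worst_subtype_stratify(
    make_table(c("CMS4", "CMS3")), use_nearest = FALSE)$stratum, "CMS1/3")
  expect_identical(worst_subtype_stratify(
    make_table(c("CMS2", "CMS2")), use_nearest = FALSE)$stratum, "CMS2")
})

test_that("worst semantics are monotone and NA handling follows the mode", {
  # adding a CMS2 lesion never downgrades a CMS4 or CMS1/3 stratum
  base <- c("CMS4", "CMS2")
  with_extra <- c(base, "CMS2")
  expect_identical(
    worst_subtype_stratify(make_table(base), use_nearest = FALSE)$stratum,
    worst_subtype_stratify(make_table(with_extra), use_nearest = FALSE)$stratum)
  # all calls NA: stratum NA without nearest, defined with nearest
  tab <- make_table(c(NA, NA), nearest = c("CMS3", "CMS2"))
  expect_true(is.na(worst_subtype_stratify(tab, use_nearest = FALSE)$stratum))
  expect_identical(worst_subtype_stratify(tab, use_nearest = TRUE)$stratum,
                   "CMS1/3")
})

test_that("survival export caps at 60 months and drops incomplete rows", {
  strata <- data.frame(patient_id = c("p1", "p2", "p3"),
                       stratum = c("CMS2", "CMS4", "CMS1/3"),
                       stringsAsFactors = FALSE)
  ann <- data.frame(patient_id = c("p1", "p2", "p3"),
                    survival_time = c(72, 28, NA), event = c(1L, 1L, 1L),
                    stringsAsFactors = FALSE)
  expect_warning(surv <- export_survival_table(strata, ann), "omitted")
  expect_equal(surv$time, c(60, 28))
  expect_equal(surv$event, c(0L, 1L))
  expect_identical(surv$patient_id, c("p1", "p2"))
})

test_that("heterogeneous patients show larger transcriptomic spread", {
  # 50 synthetic patients; one-sided rank test, fixed seed
  cfg <- synthetic_config(seed = 7, n_genes = 600, block_size = 30,
                          n_hep = 30, n_primary_per_class = 15,
                          n_met = 150, n_normal_liver = 4)
  co <- generate_cohort(cfg)
  ann <- co$annotation
  mets <- co$expr[, ann$sample_id[ann$sample_type == "metastasis"]]
  prim <- co$expr[, ann$sample_id[ann$sample_type == "primary"]]
  fs <- select_intrinsic_features(generate_reference_panel(cfg))
  labs <- co$truth$true_class[match(colnames(prim), co$truth$sample_id)]
  model <- train_nsc(prim, labs, fs, t = 1)
  adj <- regress_out_background(mets, estimate_background(mets, co$markers))
  calls <- predict_nsc(model, adj)
  pca <- fit_pca(prim, n_genes = 300)
  scores <- project_pca(pca, adj)
  tab <- build_patient_lesion_table(calls,
                                    ann[ann$sample_type == "metastasis", ],
                                    scores)
  het <- assess_heterogeneity(tab)
  multi <- het[het$n_lesions >= 2, ]
  expect_gte(nrow(multi), 30)
  wt <- wilcox.test(max_distance ~ heterogeneous, data = multi,
                    alternative = "less")
  expect_lt(wt$p.value, 0.05)
})
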