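#' Build the patient/lesion/sample table for heterogeneity analysis
#'
#' Joins subtype calls ([predict_nsc()] output), optional PC score rows
#' ([project_pca()] output) and the sample annotation into one table —
#' the input of [assess_heterogeneity()] and [worst_subtype_stratify()].
#'
#' @param calls prediction data.frame with `sample_id`, `nearest`, `call`.
#' @param annotation data.frame with `sample_id`, `patient_id`,
#'   `lesion_id` (see [read_sample_annotation()]).
#' @param scores optional samples x components matrix; the first three
#'   columns are taken as PC1–PC3.
#' @return data.frame with columns `patient_id`, `lesion_id`,
#'   `sample_id`, `nearest`, `call`, `PC1`, `PC2`, `PC3`.
#' @export
build_patient_lesion_table <- function(calls, annotation, scores = NULL) {
  need <- c("sample_id", "nearest", "call")
  if (!all(need %in% names(calls)))
    stop("calls must have columns sample_id, nearest, call", call. = FALSE)
  idx <- match(calls$sample_id, annotation$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from annotation: ",
         paste(utils::head(calls$sample_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  tab <- data.frame(patient_id = annotation$patient_id[idx],
                    lesion_id = annotation$lesion_id[idx],
                    sample_id = calls$sample_id,
                    nearest = calls$nearest,
                    call = calls$call,
                    PC1 = NA_real_, PC2 = NA_real_, PC3 = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(scores)) {
    si <- match(tab$sample_id, rownames(scores))
    for (j in 1:3)
      if (ncol(scores) >= j) tab[[paste0("PC", j)]] <- scores[si, j]
  }
  if (anyDuplicated(tab[, c("patient_id", "lesion_id", "sample_id")]))
    stop("duplicate (patient, lesion, sample) triple", call. = FALSE)
  tab
}

# majority label with ties -> NA; all-NA input -> NA
majority_label <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) return(NA_character_)
  tt <- table(labels)
  top <- names(tt)[tt == max(tt)]
  if (length(top) > 1) NA_character_ else top
}

# one row per lesion: confident label from confident calls, nearest label
# from nearest calls, each collapsed by majority (ties -> NA)
collapse_lesions <- function(tab) {
  key <- interaction(tab$patient_id, tab$lesion_id, drop = TRUE)
  rows <- lapply(split(tab, key), function(d)
    data.frame(patient_id = d$patient_id[1], lesion_id = d$lesion_id[1],
               n_samples = nrow(d),
               call = majority_label(d$call),
               nearest = majority_label(d$nearest),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Intra-patient inter-lesion subtype heterogeneity
#'
#' A patient is heterogeneous when at least two confidently classified
#' lesions carry different subtype labels (unclassified lesions are
#' excluded from the determination). Multiple samples of one lesion are
#' first collapsed by majority label (ties yield NA). The maximum
#' pairwise Euclidean distance in (PC1, PC2, PC3) space is computed over
#' ALL samples of the patient; NA when scores are missing.
#'
#' @param table a [build_patient_lesion_table()] data.frame.
#' @return data.frame, one row per patient: `patient_id`, `n_samples`,
#'   `n_lesions`, `n_confident_lesions`, `n_distinct_subtypes`,
#'   `heterogeneous`, `max_distance`.
#' @export
assess_heterogeneity <- function(table) {
  lesions <- collapse_lesions(table)
  rows <- lapply(split(seq_len(nrow(table)), table$patient_id),
                 function(ix) {
    d <- table[ix, , drop = FALSE]
    les <- lesions[lesions$patient_id == d$patient_id[1], , drop = FALSE]
    conf <- les$call[!is.na(les$call)]
    pc <- as.matrix(d[, c("PC1", "PC2", "PC3")])
    maxd <- if (nrow(pc) >= 2 && !anyNA(pc))
      max(stats::dist(pc)) else if (nrow(pc) < 2) 0 else NA_real_
    data.frame(patient_id = d$patient_id[1],
               n_samples = nrow(d),
               n_lesions = nrow(les),
               n_confident_lesions = length(conf),
               n_distinct_subtypes = length(unique(conf)),
               heterogeneous = length(conf) >= 2 &&
                 length(unique(conf)) >= 2,
               max_distance = maxd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Worst-subtype patient stratification
#'
#' Patient-level stratification by the poorest-prognosis subtype present
#' among the patient's lesions: if any lesion is CMS1 or CMS3, the
#' patient is `CMS1/3`; otherwise if any lesion is CMS4, the patient is
#' `CMS4`; otherwise (all CMS2) `CMS2`. With `use_nearest = TRUE` each
#' lesion contributes its nearest (not necessarily confident) subtype, so
#' no patient is left unstratified — the mode used for survival analysis.
#'
#' @param table a [build_patient_lesion_table()] data.frame.
#' @param use_nearest use nearest labels instead of confident calls.
#' @return data.frame: `patient_id`, `stratum` in
#'   \{`CMS1/3`, `CMS4`, `CMS2`, NA\}.
#' @export
worst_subtype_stratify <- function(table, use_nearest = TRUE) {
  lesions <- collapse_lesions(table)
  lab <- if (use_nearest) lesions$nearest else lesions$call
  rows <- lapply(split(lab, lesions$patient_id), function(l) {
    l <- l[!is.na(l)]
    if (!length(l)) return(NA_character_)
    if (any(l %in% c("CMS1", "CMS3"))) "CMS1/3"
    else if (any(l == "CMS4")) "CMS4"
    else "CMS2"
  })
  data.frame(patient_id = names(rows),
             stratum = unlist(rows, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Export a per-patient survival table for worst-subtype strata
#'
#' Joins strata with per-patient survival annotation and applies 5-year
#' administrative censoring: times beyond `cap_months` are set to the cap
#' with the event indicator cleared. Patients lacking survival data are
#' omitted with a warning. The output feeds any standard survival package
#' (e.g. `survival::coxph(Surv(time, event) ~ stratum)`).
#'
#' @param strata a [worst_subtype_stratify()] data.frame.
#' @param annotation sample annotation with `patient_id`,
#'   `survival_time` (months from start of treatment), `event`.
#' @param cap_months censoring horizon (default 60).
#' @param path optional TSV output path.
#' @return data.frame: `patient_id`, `stratum`, `time`, `event`.
#' @export
export_survival_table <- function(strata, annotation, cap_months = 60,
                                  path = NULL) {
  if (!all(c("survival_time", "event") %in% names(annotation)))
    stop("annotation lacks survival_time/event columns", call. = FALSE)
  ann <- unique(annotation[, c("patient_id", "survival_time", "event")])
  if (anyDuplicated(ann$patient_id))
    stop("inconsistent survival data within patient(s)", call. = FALSE)
  idx <- match(strata$patient_id, ann$patient_id)
  time <- ann$survival_time[idx]
  event <- ann$event[idx]
  drop <- is.na(time) | is.na(event)
  if (any(drop))
    warning(sum(drop), " patient(s) omitted: missing survival fields",
            call. = FALSE)
  out <- data.frame(patient_id = strata$patient_id,
                    stratum = strata$stratum,
                    time = pmin(time, cap_months),
                    event = ifelse(time > cap_months, 0L, as.integer(event)),
                    stringsAsFactors = FALSE)[!drop, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
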