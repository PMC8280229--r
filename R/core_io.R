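#' Construct and validate an expression matrix
#'
#' The package's working currency is a plain numeric matrix of log2-scale
#' expression values with genes in rows and samples in columns; row and
#' column names carry gene and sample identifiers. This validator enforces
#' the shape assumptions all downstream operations rely on.
#'
#' @param values numeric matrix, genes in rows, samples in columns; must
#'   have unique, non-missing dimnames and only finite values.
#' @return the validated matrix (invisibly identical to `values`).
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have gene rownames and sample colnames",
         call. = FALSE)
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicate gene id(s): ", paste(utils::head(dup_g, 10), collapse = ", "),
         call. = FALSE)
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(utils::head(dup_s, 10), collapse = ", "),
         call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression matrix contains non-finite values; refusing to impute",
         call. = FALSE)
  values
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' Expects UTF-8 tab-separated text with a header row of sample ids and a
#' first column of gene ids (or the transpose with
#' `orientation = "samples_in_rows"`). Values are taken as-is and assumed
#' log2 scale; no transformation is applied.
#'
#' @param path path to a TSV file.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#'   Never guessed from the data.
#' @param log2_transform apply `log2(x + 1)` for linear-scale input.
#' @return a validated expression matrix (see [expression_matrix()]).
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_in_rows",
                                                   "samples_in_rows"),
                                   log2_transform = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2)
    stop("malformed expression TSV (need id column + >=1 data column): ",
         path, call. = FALSE)
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate id(s) in ", path, ": ",
         paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- colnames(m)[!vapply(seq_len(ncol(m)),
                               function(j) is.numeric(df[[j + 1]]), logical(1))]
    stop("non-numeric cell(s) in column(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  rownames(m) <- ids
  if (orientation == "samples_in_rows") m <- t(m)
  if (log2_transform) m <- log2(m + 1)
  expression_matrix(m)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; round-trip is lossless to 1e-12
#' (values are written with full precision) and exact for identifiers.
#'
#' @param x expression matrix (genes x samples).
#' @param path output path.
#' @param id_header header for the id column.
#' @export
write_expression_matrix <- function(x, path, id_header = "gene_id") {
  x <- expression_matrix(x)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(id_header, colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1, function(v)
    paste(format(v, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Broad-dialect GMT: one set per line, fields tab-separated — set name,
#' description, then member gene ids. Descriptions are retained as an
#' attribute but unused.
#'
#' @param path path to a `.gmt` file.
#' @return named list of character vectors of gene ids, in file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- structure(list(), names = character(0))
    attr(out, "description") <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(short))
    stop("GMT parse error at line ", short[1],
         ": fewer than 3 tab-separated fields", call. = FALSE)
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  sets <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    g[nzchar(g)]
  })
  empty <- which(!vapply(sets, length, integer(1)))
  if (length(empty))
    stop("empty gene set at line ", empty[1], call. = FALSE)
  names(sets) <- nm
  attr(sets, "description") <- vapply(fields, `[[`, character(1), 2L)
  sets
}

#' Write a gene-set collection to GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description per-set description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a marker gene list
#'
#' One gene id per line; blank lines and lines starting with `#` are
#' ignored. Used for the hepatocyte / liver-specific marker panel.
#'
#' @param path path to the list file.
#' @return character vector of unique gene ids.
#' @export
read_marker_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("marker list is empty: ", path, call. = FALSE)
  if (anyDuplicated(lines))
    stop("duplicate marker id(s): ",
         paste(unique(lines[duplicated(lines)]), collapse = ", "),
         call. = FALSE)
  lines
}

#' Bundled synthetic hepatocyte marker panel
#'
#' Gene ids of the hepatocyte block used by the synthetic-cohort generator.
#' A stand-in for a curated liver-specific marker list (e.g. ALB, F9);
#' replace with a real panel for real data.
#'
#' @return character vector of marker ids.
#' @export
default_liver_markers <- function() {
  path <- system.file("extdata", "liver_markers_synthetic.txt",
                      package = "metacms")
  if (nzchar(path) && file.exists(path)) return(read_marker_list(path))
  sprintf("HEP.%03d", 1:50)
}

#' Read a sample annotation table
#'
#' TSV with columns `sample_id`, `patient_id`, `lesion_id`, `sample_type`
#' (primary | metastasis | normal_liver) and optional `treatment`,
#' `survival_time` (months), `event` (0/1).
#'
#' @param path path to the TSV.
#' @return data.frame with one row per sample.
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "patient_id", "lesion_id", "sample_type")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in annotation", call. = FALSE)
  bad <- setdiff(unique(df$sample_type),
                 c("primary", "metastasis", "normal_liver"))
  if (length(bad))
    stop("unknown sample_type value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if ("survival_time" %in% names(df) &&
      any(df$survival_time < 0, na.rm = TRUE))
    stop("negative survival_time", call. = FALSE)
  df
}

MODEL_SCHEMA_VERSION <- 1L

#' Serialize a trained model to JSON
#'
#' Writes nearest-shrunken-centroids ([train_nsc()]) and PCA
#' ([fit_pca()]) models to a single JSON file with a `schema_version`
#' field. `deserialize_model(serialize_model(m))` reproduces predictions
#' bit-identically.
#'
#' @param model an object of class `nsc_model` or `pca_model`.
#' @param path output path.
#' @export
serialize_model <- function(model, path) {
  type <- if (inherits(model, "nsc_model")) "nsc_model"
          else if (inherits(model, "pca_model")) "pca_model"
          else stop("unsupported model class: ",
                    paste(class(model), collapse = "/"), call. = FALSE)
  m <- unclass(model)
  # matrices go out as per-column lists (JSON drops dimnames)
  for (f in names(m))
    if (is.matrix(m[[f]]))
      m[[f]] <- stats::setNames(lapply(seq_len(ncol(m[[f]])),
                                       function(j) unname(m[[f]][, j])),
                                colnames(m[[f]]))
    else if (is.numeric(m[[f]])) m[[f]] <- unname(m[[f]])
  payload <- list(schema_version = MODEL_SCHEMA_VERSION,
                  model_type = type,
                  model = m)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Deserialize a model written by [serialize_model()]
#' @param path path to the JSON model file.
#' @return the restored model object.
#' @export
deserialize_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) stop("cannot load model (corrupt or truncated): ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(payload$schema_version) ||
      payload$schema_version != MODEL_SCHEMA_VERSION)
    stop("model schema_version mismatch (found ",
         if (is.null(payload$schema_version)) "none"
         else payload$schema_version,
         ", expected ", MODEL_SCHEMA_VERSION, ")", call. = FALSE)
  m <- payload$model
  rebuild <- function(cols, rows) {
    if (is.matrix(cols) || is.data.frame(cols)) cols <- as.list(as.data.frame(cols))
    mat <- do.call(cbind, lapply(cols, as.numeric))
    rownames(mat) <- rows
    mat
  }
  if (identical(payload$model_type, "nsc_model")) {
    genes <- as.character(m$genes)
    for (f in c("overall_centroid", "s"))
      m[[f]] <- stats::setNames(as.numeric(m[[f]]), genes)
    m$centroids <- rebuild(m$centroids, genes)
    m$shrunken_centroids <- rebuild(m$shrunken_centroids, genes)
    m$priors <- stats::setNames(as.numeric(m$priors),
                                as.character(m$classes))
    m$genes <- genes
    class(m) <- "nsc_model"
  } else if (identical(payload$model_type, "pca_model")) {
    genes <- as.character(m$genes)
    m$means <- stats::setNames(as.numeric(m$means), genes)
    m$loadings <- rebuild(m$loadings, genes)
    m$var_explained <- as.numeric(m$var_explained)
    m$sdev <- as.numeric(m$sdev)
    m$genes <- genes
    class(m) <- "pca_model"
  } else {
    stop("unknown model_type in file: ", path, call. = FALSE)
  }
  m
}
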