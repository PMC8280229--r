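# shared fixtures: small deterministic matrices and a downsized cohort

rand_expr <- function(n_genes, n_samples, seed = 1, mean = 7, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean, sd), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  m
}

# small 4-class training matrix with clean block structure
toy_labeled <- function(n_per_class = 8, n_block = 5, n_noise = 20,
                        effect = 3, sd = 0.5, seed = 7) {
  set.seed(seed)
  classes <- c("CMS1", "CMS2", "CMS3", "CMS4")
  labels <- rep(classes, each = n_per_class)
  n_genes <- 4 * n_block + n_noise
  genes <- c(sprintf("%s.b%02d", rep(classes, each = n_block),
                     rep(seq_len(n_block), 4)),
             sprintf("noise%02d", seq_len(n_noise)))
  x <- matrix(rnorm(n_genes * length(labels), 7, sd), nrow = n_genes,
              dimnames = list(genes, sprintf("t%02d", seq_along(labels))))
  for (k in seq_along(classes)) {
    rows <- ((k - 1) * n_block + 1):(k * n_block)
    x[rows, labels == classes[k]] <- x[rows, labels == classes[k]] + effect
  }
  list(x = x, labels = labels, genes = genes)
}

# downsized synthetic cohort shared by slower tests
small_cohort_config <- function(seed = 42, ...) {
  synthetic_config(seed = seed, n_genes = 600, block_size = 30, n_hep = 30,
                   n_primary_per_class = 15, n_met = 60,
                   n_normal_liver = 6, ...)
}
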