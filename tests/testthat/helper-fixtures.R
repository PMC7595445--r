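# fixtures built in code

toy_vcf_path <- function() {
  system.file("extdata", "toy.vcf", package = "invertype")
}

# variant table straight from a genotype matrix (samples x snps)
make_table <- function(genotypes, pos = NULL, chrom = "chr") {
  genotypes <- as.matrix(genotypes)
  m <- ncol(genotypes)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  variant_table(
    chrom,
    tibble::tibble(pos = as.integer(pos), ref = rep("A", m),
                   alt = rep("C", m)),
    genotypes,
    sprintf("S%03d", seq_len(nrow(genotypes))))
}

# PCA-result shim holding given score columns (for association tests that
# need a controlled predictor)
make_pca <- function(scores, sample_ids = NULL) {
  scores <- as.matrix(scores)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  ids <- sample_ids %||% sprintf("S%03d", seq_len(nrow(scores)))
  rownames(scores) <- ids
  structure(
    list(scores = scores,
         explained_variance_ratio = rep(NA_real_, ncol(scores)),
         n_components = ncol(scores), sample_ids = ids),
    class = "invertype_pca")
}

make_labels <- function(cluster, sample_ids = NULL) {
  ids <- sample_ids %||% sprintf("S%03d", seq_along(cluster))
  invertype:::new_cluster_labels(
    tibble::tibble(sample_id = ids, cluster = as.integer(cluster)),
    k = length(unique(cluster)))
}

`%||%` <- rlang::`%||%`

# exact penalized multinomial log-likelihood, maximized with stats::optim:
# the independent oracle for the Newton fitter
oracle_max_penloglik <- function(x, y, lambda = 1e-3) {
  X <- cbind(1, as.matrix(x))
  classes <- sort(unique(y))
  G <- length(classes)
  yi <- match(y, classes) - 1L
  negll <- function(theta) {
    B <- matrix(theta, ncol = G - 1)
    eta <- cbind(X %*% B, 0)
    ll <- sum(eta[cbind(seq_along(yi), yi + 1L)] - log(rowSums(exp(eta))))
    -(ll - 0.5 * lambda * sum(B[-1, , drop = FALSE]^2))
  }
  o <- stats::optim(rep(0, ncol(X) * (G - 1)), negll, method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-15))
  -o$value
}

oracle_lrt_stat <- function(x, y, lambda = 1e-3) {
  counts <- table(y)
  ll_null <- sum(counts * log(counts / length(y)))
  2 * (oracle_max_penloglik(x, y, lambda) - ll_null)
}
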