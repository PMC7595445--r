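#' Principal component analysis of a genotype feature matrix
#'
#' Columns are mean-centered (never scaled: the one-hot features share a
#' 0/1 scale) and decomposed exactly through the eigendecomposition of the
#' centered sample Gram matrix, which keeps the computation
#' `O(n_samples^2 x n_features)` and sparse-friendly no matter how many
#' SNPs the arm carries. Scores are ordered by decreasing explained
#' variance. The per-PC sign is fixed by making the largest-magnitude SNP
#' loading of each component positive, so results are reproducible without
#' any randomness.
#'
#' @param features a `feature_matrix` from [encode_features()], or any
#'   numeric matrix with one row per sample.
#' @param n_components number of components to retain (default 10), at most
#'   `min(n_samples - 1, n_features)`.
#' @return an object of class `invertype_pca`: list with `scores`
#'   (`n_samples x n_components`, columns `PC1..`), the per-component
#'   `explained_variance_ratio`, `n_components`, and `sample_ids`.
#' @examples
#' vt <- simulate_dataset(simulation_params(n_samples = 40, n_snps = 200,
#'                                          seed = 1))$table
#' pca <- fit_pca(encode_features(vt), n_components = 4)
#' tidy(pca)
#' @export
fit_pca <- function(features, n_components = 10) {
  if (inherits(features, "feature_matrix")) {
    X <- features$values
    sample_ids <- features$sample_ids
  } else {
    X <- features
    sample_ids <- rownames(features) %||% as.character(seq_len(nrow(features)))
  }
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) abort("PCA requires at least 2 samples")
  cap <- min(n - 1L, p)
  if (n_components > cap) {
    abort(paste0("n_components = ", n_components,
                 " exceeds the rank bound min(n_samples - 1, n_features) = ",
                 cap))
  }
  m <- Matrix::colMeans(X)
  K <- as.matrix(Matrix::tcrossprod(X))
  Xm <- as.numeric(X %*% m)
  Kc <- K - outer(Xm, rep(1, n)) - outer(rep(1, n), Xm) + sum(m^2)
  eig <- eigen(Kc, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  total <- sum(diag(Kc))
  tol <- 1e-12 * max(total, 1)
  ratios <- if (total > tol) pmin(ev / total, 1) else rep(0, n)
  k <- seq_len(n_components)
  scores <- matrix(0, nrow = n, ncol = n_components,
                   dimnames = list(sample_ids, paste0("PC", k)))
  for (j in k) {
    if (ev[j] <= tol) next
    u <- eig$vectors[, j]
    # loading direction for the sign convention
    v <- as.numeric(Matrix::crossprod(X, u)) - m * sum(u)
    top <- which.max(abs(v))
    if (v[top] < 0) u <- -u
    scores[, j] <- u * sqrt(ev[j])
  }
  structure(
    list(scores = scores,
         explained_variance_ratio = ratios[k],
         n_components = as.integer(n_components),
         sample_ids = sample_ids),
    class = "invertype_pca")
}

#' @export
print.invertype_pca <- function(x, ...) {
  cat("<invertype_pca> ", length(x$sample_ids), " samples, ",
      x$n_components, " components\n", sep = "")
  cat("  explained variance ratio:",
      paste(signif(x$explained_variance_ratio, 3), collapse = " "), "\n")
  invisible(x)
}

#' Explained-variance report
#'
#' @param result an `invertype_pca`.
#' @return tibble with columns `pc` (1-based component index) and `ratio`
#'   (fraction of total variance), in component order.
#' @export
explained_variance_report <- function(result) {
  stopifnot(inherits(result, "invertype_pca"))
  tibble::tibble(pc = seq_len(result$n_components),
                 ratio = result$explained_variance_ratio)
}

#' @rdname explained_variance_report
#' @param x an `invertype_pca`.
#' @param ... unused.
#' @export
tidy.invertype_pca <- function(x, ...) explained_variance_report(x)

#' @export
glance.invertype_pca <- function(x, ...) {
  tibble::tibble(n_samples = length(x$sample_ids),
                 n_components = x$n_components,
                 total_variance_explained = sum(x$explained_variance_ratio))
}

#' PC coordinates as a tibble
#'
#' @param result an `invertype_pca`.
#' @param components PC indices to include (default: all fitted).
#' @return tibble: `sample_id`, `PC<i>` columns.
#' @export
pc_scores <- function(result, components = seq_len(result$n_components)) {
  check_components(result, components)
  dplyr::bind_cols(
    tibble::tibble(sample_id = result$sample_ids),
    tibble::as_tibble(result$scores[, paste0("PC", components),
                                    drop = FALSE]))
}

check_components <- function(result, components) {
  bad <- setdiff(components, seq_len(result$n_components))
  if (length(bad)) {
    abort(paste0("PC index not fitted: ", paste(bad, collapse = ", ")))
  }
  invisible(components)
}

#' Export / import PC coordinates as TSV
#'
#' @param result an `invertype_pca`.
#' @param path TSV path.
#' @param components PC indices to export.
#' @return `path` invisibly (writer); an `invertype_pca` whose
#'   `explained_variance_ratio` is `NA` (reader: the file stores scores
#'   only).
#' @export
write_coordinates <- function(result, path,
                              components = seq_len(result$n_components)) {
  readr::write_tsv(pc_scores(result, components), path)
  invisible(path)
}

#' @rdname write_coordinates
#' @export
read_coordinates <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          sample_id = readr::col_character(),
                          .default = readr::col_double()))
  pcs <- grep("^PC[0-9]+$", names(df), value = TRUE)
  scores <- as.matrix(df[, pcs])
  rownames(scores) <- df$sample_id
  structure(
    list(scores = scores,
         explained_variance_ratio = rep(NA_real_, length(pcs)),
         n_components = length(pcs),
         sample_ids = df$sample_id),
    class = "invertype_pca")
}
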