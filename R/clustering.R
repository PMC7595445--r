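# k-means karyotype clustering in PC space

# run code with a locally-seeded RNG, restoring global state afterwards
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# kmeans that tolerates fewer distinct points than centers (all-identical
# coordinates etc.): falls back to one cluster per distinct point, splitting
# the largest clusters deterministically until k are occupied.
fit_kmeans_safe <- function(X, k, nstart = 10) {
  X <- as.matrix(X)
  keys <- apply(X, 1, paste, collapse = "\r")
  n_distinct <- length(unique(keys))
  if (k == nrow(X) && n_distinct == k) {
    return(list(cluster = seq_len(k), inertia = 0))
  }
  if (n_distinct >= k) {
    km <- kmeans(X, centers = k, nstart = nstart, iter.max = 50)
    return(list(cluster = km$cluster, inertia = km$tot.withinss))
  }
  cl <- match(keys, unique(keys))
  next_id <- n_distinct
  while (next_id < k) {
    next_id <- next_id + 1L
    big <- which.max(tabulate(cl))
    idx <- which(cl == big)
    cl[idx[seq_len(ceiling(length(idx) / 2))]] <- next_id
  }
  centers <- rowsum(X, cl) / as.vector(table(cl))
  inertia <- sum((X - centers[cl, , drop = FALSE])^2)
  list(cluster = cl, inertia = inertia)
}

# renumber cluster IDs 0..k-1 by descending size; ties by smallest
# contained sample index
canonical_labels <- function(cl) {
  sizes <- table(cl)
  first_idx <- vapply(names(sizes), function(id) min(which(cl == id)), 0)
  ord <- order(-as.vector(sizes), first_idx)
  match(as.character(cl), names(sizes)[ord]) - 1L
}

#' Inertia sweep over candidate cluster counts
#'
#' Clusters the samples in PC space for each `k = 1..k_max` (10 restarts
#' per `k`, best inertia kept) and suggests `k` from the elbow of the
#' inertia curve.
#'
#' @param coords an `invertype_pca`.
#' @param pcs PC indices used as coordinates (default 1-2).
#' @param k_max largest cluster count to try (default 6).
#' @param seed RNG seed for the k-means restarts.
#' @return an object of class `cluster_sweep`: tibble with columns `k`,
#'   `inertia`; attributes `suggested_k` and `ambiguous`.
#' @export
sweep_kmeans <- function(coords, pcs = c(1, 2), k_max = 6, seed = 1) {
  check_components(coords, pcs)
  X <- coords$scores[, paste0("PC", pcs), drop = FALSE]
  if (k_max > nrow(X)) abort("k_max exceeds the number of samples")
  inertias <- local_seed(seed, vapply(seq_len(k_max), function(k) {
    fit_kmeans_safe(X, k)$inertia
  }, 0))
  elbow <- choose_elbow(inertias)
  structure(
    tibble::tibble(k = seq_len(k_max), inertia = inertias),
    suggested_k = as.integer(elbow),
    ambiguous = attr(elbow, "ambiguous"),
    class = c("cluster_sweep", class(tibble::tibble())))
}

#' @export
print.cluster_sweep <- function(x, ...) {
  cat("<cluster_sweep> suggested k =", attr(x, "suggested_k"),
      if (isTRUE(attr(x, "ambiguous"))) "(ambiguous elbow)" else "", "\n")
  NextMethod()
}

#' @export
glance.cluster_sweep <- function(x, ...) {
  tibble::tibble(suggested_k = attr(x, "suggested_k"),
                 ambiguous = attr(x, "ambiguous"),
                 k_max = max(x$k))
}

#' Cluster samples in PC space to infer karyotype groups
#'
#' Runs k-means (10 restarts, best solution kept) on the selected PC
#' coordinates. Cluster IDs are canonical: renumbered `0..k-1` by
#' descending cluster size, ties broken by the smallest contained sample
#' index, so repeated runs and permuted inputs give identical output.
#'
#' @param coords an `invertype_pca`.
#' @param k number of clusters (1 to `n_samples`).
#' @param pcs PC indices used as coordinates (default 1-2).
#' @param seed RNG seed.
#' @return an object of class `cluster_labels`: tibble with `sample_id`,
#'   `cluster`; attributes `k`, `pcs_used`, `seed`.
#' @export
cluster_samples <- function(coords, k, pcs = c(1, 2), seed = 1) {
  check_components(coords, pcs)
  X <- coords$scores[, paste0("PC", pcs), drop = FALSE]
  if (k < 1 || k > nrow(X)) abort("k must be between 1 and n_samples")
  cl <- if (k == 1) rep(1L, nrow(X)) else {
    local_seed(seed, fit_kmeans_safe(X, k)$cluster)
  }
  new_cluster_labels(
    tibble::tibble(sample_id = coords$sample_ids,
                   cluster = canonical_labels(cl)),
    k = as.integer(k), pcs_used = pcs, seed = seed)
}

new_cluster_labels <- function(df, k, pcs_used = NA, seed = NA) {
  structure(df, k = k, pcs_used = pcs_used, seed = seed,
            class = c("cluster_labels", class(tibble::tibble())))
}

#' Export / import cluster labels as TSV
#'
#' @param labels a `cluster_labels` tibble.
#' @param path TSV path.
#' @return `path` invisibly (writer); `cluster_labels` (reader).
#' @export
write_clusters <- function(labels, path) {
  readr::write_tsv(tibble::as_tibble(labels), path)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          sample_id = readr::col_character(),
                          cluster = readr::col_integer()))
  new_cluster_labels(df, k = length(unique(df$cluster)))
}
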