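# per-SNP likelihood-ratio association scans against PC coordinates or
# cluster labels

new_assoc_track <- function(df, predictor, chrom) {
  structure(df, predictor = predictor, chrom = chrom,
            n_tested = nrow(df),
            class = c("assoc_track", class(tibble::tibble())))
}

#' @export
print.assoc_track <- function(x, ...) {
  cat("<assoc_track> predictor:", attr(x, "predictor"),
      "|", nrow(x), "SNPs on", attr(x, "chrom"), "\n")
  NextMethod()
}

#' @export
glance.assoc_track <- function(x, ...) {
  tibble::tibble(predictor = attr(x, "predictor"),
                 chrom = attr(x, "chrom"),
                 n_tested = nrow(x),
                 n_degenerate = sum(x$degenerate),
                 min_p = if (nrow(x)) min(x$p_value) else NA_real_)
}

P_FLOOR <- 1e-300

check_alignment <- function(table_ids, other_ids, what) {
  if (length(table_ids) != length(other_ids) ||
      any(table_ids != other_ids)) {
    abort(paste0("sample IDs of the variant table and ", what,
                 " are not identical and aligned"))
  }
}

#' Per-SNP association test against a principal component
#'
#' For each SNP, fits a multinomial logistic model of the genotype category
#' (over the categories observed at that SNP; samples missing the call are
#' dropped from that SNP only) on the sample's coordinate along one PC,
#' with a small ridge penalty on the slopes. The likelihood-ratio statistic
#' against the intercept-only model is referred to a chi-square with
#' `G - 1` degrees of freedom (`G` = observed genotype categories). SNPs
#' with a single observed category cannot be tested and are reported with
#' `p = 1` and `degenerate = TRUE`. A contiguous run of small p-values
#' along the arm (the Manhattan-plot "step") marks an inversion captured by
#' that PC.
#'
#' @param table a [variant_table()].
#' @param coords an `invertype_pca` fitted on the same samples, same order.
#' @param pc single PC index to test against.
#' @param lambda ridge penalty on slopes (default 1e-3).
#' @return an `assoc_track`: tibble with `chrom`, `pos`, `p_value`
#'   (floored at 1e-300), `df`, `degenerate`; attribute `predictor` is
#'   `"PC<pc>"`.
#' @export
pc_snp_test <- function(table, coords, pc, lambda = 1e-3) {
  validate_variant_table(table)
  check_components(coords, pc)
  stopifnot(length(pc) == 1L)
  check_alignment(table$sample_ids, coords$sample_ids, "PCA result")
  x <- coords$scores[, paste0("PC", pc)]
  g <- table$genotypes
  res <- purrr::map(seq_len(ncol(g)), function(j) {
    gj <- g[, j]
    obs <- gj >= 0L
    gg <- gj[obs]
    cats <- unique(gg)
    if (length(cats) < 2L) {
      return(list(p = 1, df = 0L, degenerate = TRUE))
    }
    lrt <- multinom_lrt(matrix(x[obs], ncol = 1), gg,
                        df = length(cats) - 1L, lambda = lambda)
    list(p = lrt$p_value, df = lrt$df, degenerate = FALSE)
  })
  new_assoc_track(
    tibble::tibble(
      chrom = table$chrom,
      pos = table$snps$pos,
      p_value = pmax(purrr::map_dbl(res, "p"), P_FLOOR),
      df = purrr::map_int(res, ~ as.integer(.x$df)),
      degenerate = purrr::map_lgl(res, "degenerate")),
    predictor = paste0("PC", pc), chrom = table$chrom)
}

# one-hot genotype features at a single SNP, reference (most frequent)
# category dropped so the block is identifiable next to an intercept;
# constant columns dropped. Returns NULL when nothing non-constant remains.
snp_feature_block <- function(gg) {
  tab <- table(gg)
  ref <- as.integer(names(tab)[which.max(tab)])
  cats <- setdiff(sort(unique(gg)), ref)
  if (!length(cats)) return(NULL)
  X <- vapply(cats, function(cc) as.numeric(gg == cc),
              numeric(length(gg)))
  X <- as.matrix(X)
  keep <- apply(X, 2, function(col) length(unique(col)) > 1L)
  if (!any(keep)) return(NULL)
  X[, keep, drop = FALSE]
}

#' Per-SNP association test against cluster labels
#'
#' For each SNP, fits a multinomial logistic model predicting the cluster
#' label (the dependent variable) from the SNP's one-hot genotype features,
#' ridge-penalized on the slopes, with intercepts initialized at the log
#' class frequencies. Before fitting, the training set is balanced by
#' seeded resampling: every class is downsampled without replacement to
#' the smallest class size (one draw per SNP from a per-track seeded
#' stream), so unequal cluster sizes do not drive the fit while the
#' balanced set stays a set of independent observations, keeping the
#' chi-square reference for the statistic valid. The likelihood-ratio
#' statistic against the intercept-only model is referred to a chi-square
#' with `(K - 1) * F` degrees of freedom, `F` being the number of
#' identifiable, non-constant genotype features at the SNP.
#'
#' @param table a [variant_table()].
#' @param labels a `cluster_labels` tibble covering the same samples, same
#'   order, with `k >= 2`.
#' @param seed seed for the per-track resampling stream.
#' @param lambda ridge penalty on slopes (default 1e-3).
#' @return an `assoc_track`; attribute `predictor` is `"clusters k=<K>"`.
#' @export
cluster_snp_test <- function(table, labels, seed = 1, lambda = 1e-3) {
  validate_variant_table(table)
  check_alignment(table$sample_ids, labels$sample_id, "cluster labels")
  K <- length(unique(labels$cluster))
  if (K < 2L) abort("cluster-SNP tests require at least 2 clusters")
  cl <- labels$cluster
  g <- table$genotypes
  res <- local_seed(seed, purrr::map(seq_len(ncol(g)), function(j) {
    gj <- g[, j]
    obs <- gj >= 0L
    gg <- gj[obs]
    yy <- cl[obs]
    if (length(unique(gg)) < 2L || length(unique(yy)) < 2L) {
      return(list(p = 1, df = 0L, degenerate = TRUE))
    }
    # balance classes: downsample each class without replacement to the
    # smallest class size
    counts <- table(yy)
    m <- min(counts)
    take <- unlist(lapply(names(counts), function(cc) {
      idx <- which(yy == as.integer(cc))
      if (length(idx) == m) idx else idx[sample.int(length(idx), m)]
    }))
    gg_b <- gg[take]
    yy_b <- yy[take]
    X <- snp_feature_block(gg_b)
    if (is.null(X)) return(list(p = 1, df = 0L, degenerate = TRUE))
    Kb <- length(unique(yy_b))
    df <- (Kb - 1L) * ncol(X)
    lrt <- multinom_lrt(X, yy_b, df = df, lambda = lambda)
    list(p = lrt$p_value, df = df, degenerate = FALSE)
  }))
  new_assoc_track(
    tibble::tibble(
      chrom = table$chrom,
      pos = table$snps$pos,
      p_value = pmax(purrr::map_dbl(res, "p"), P_FLOOR),
      df = purrr::map_int(res, ~ as.integer(.x$df)),
      degenerate = purrr::map_lgl(res, "degenerate")),
    predictor = paste0("clusters k=", K), chrom = table$chrom)
}

#' Write / read an association track as TSV
#'
#' Lossless round trip of the per-SNP p-value track (`chrom`, `pos`,
#' `p_value`, `df`, `degenerate`) plus a `# predictor:` comment line.
#'
#' @param track an `assoc_track`.
#' @param path TSV path.
#' @return `path` invisibly (writer); an `assoc_track` (reader).
#' @export
write_track <- function(track, path) {
  readr::write_lines(paste0("# predictor: ", attr(track, "predictor")), path)
  readr::write_tsv(tibble::as_tibble(track), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  lines <- readLines(path, warn = FALSE)
  predictor <- NA_character_
  skip <- 0L
  while (skip < length(lines) && startsWith(lines[skip + 1L], "#")) {
    m <- regmatches(lines[skip + 1L],
                    regexec("^# predictor: (.*)$", lines[skip + 1L]))[[1]]
    if (length(m) == 2L) predictor <- m[2]
    skip <- skip + 1L
  }
  header_line <- skip + 1L
  if (header_line > length(lines)) abort("track file has no header")
  cols <- strsplit(lines[header_line], "\t", fixed = TRUE)[[1]]
  expected <- c("chrom", "pos", "p_value", "df", "degenerate")
  if (!identical(cols, expected)) {
    abort(paste0("malformed track header on line ", header_line))
  }
  body <- lines[-seq_len(header_line)]
  parse_row <- function(i) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    lineno <- header_line + i
    if (length(f) != 5L) {
      abort(paste0("malformed track record on line ", lineno))
    }
    pos <- suppressWarnings(as.integer(f[2]))
    p <- suppressWarnings(as.numeric(f[3]))
    df <- suppressWarnings(as.integer(f[4]))
    deg <- toupper(f[5]) %in% c("TRUE", "FALSE")
    if (is.na(pos)) abort(paste0("non-numeric pos on line ", lineno))
    if (is.na(p)) abort(paste0("non-numeric p on line ", lineno))
    if (is.na(df)) abort(paste0("non-numeric df on line ", lineno))
    if (!deg) abort(paste0("invalid degenerate flag on line ", lineno))
    tibble::tibble(chrom = f[1], pos = pos, p_value = p, df = df,
                   degenerate = toupper(f[5]) == "TRUE")
  }
  df <- if (length(body)) {
    dplyr::bind_rows(lapply(seq_along(body), parse_row))
  } else {
    tibble::tibble(chrom = character(), pos = integer(),
                   p_value = numeric(), df = integer(),
                   degenerate = logical())
  }
  new_assoc_track(df, predictor = predictor,
                  chrom = if (nrow(df)) df$chrom[1] else NA_character_)
}
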