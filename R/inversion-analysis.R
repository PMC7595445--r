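# detection, localization, genotype concordance, inversion frequency

#' Default -log10(p) threshold for step detection
#'
#' `max(8, log10(n_tested / 0.05))`: at least 8, or the Bonferroni-style
#' cutoff for the number of SNPs tested, whichever is larger.
#'
#' @param n_tested number of SNPs in the track.
#' @return numeric threshold on the -log10(p) scale.
#' @export
default_step_threshold <- function(n_tested) {
  max(8, log10(n_tested / 0.05))
}

#' Detect the step-function pattern of an inversion in a p-value track
#'
#' An inversion captured by a predictor shows up in the Manhattan plot as a
#' contiguous plateau of strongly associated SNPs. This quantifies that
#' pattern: the arm is tiled with non-overlapping windows; each window
#' scores the fraction of its SNPs with `-log10(p) >= threshold_logp`;
#' windows at or above `min_inside_fraction` qualify, and qualifying
#' windows separated by at most one sub-threshold window are joined into
#' runs. The run with the most qualifying windows is the candidate region.
#' It is called detected when it holds at least two qualifying windows,
#' SNPs exist outside its span (a plateau covering the whole arm is
#' population structure, not a step), and the above-threshold SNP fraction
#' inside the span is at least twice the fraction outside. Region bounds
#' are the first and last above-threshold SNP positions inside the run.
#'
#' @param track an `assoc_track`.
#' @param threshold_logp -log10(p) cutoff; default
#'   [default_step_threshold()] of the track size.
#' @param window_bp window width in bp (default 500000).
#' @param min_inside_fraction minimum above-threshold SNP fraction for a
#'   window to qualify (default 0.2).
#' @return a one-row `step_region` tibble: `predictor`, `chrom`,
#'   `detected`, `start_bp`, `end_bp` (NA when not detected),
#'   `inside_fraction`, `outside_fraction`, `threshold`, `window_bp`.
#' @export
detect_step_region <- function(track, threshold_logp = NULL,
                               window_bp = 500000,
                               min_inside_fraction = 0.2) {
  if (nrow(track) == 0L) abort("association track is empty")
  if (is.null(threshold_logp)) {
    threshold_logp <- default_step_threshold(nrow(track))
  }
  logp <- -log10(pmax(track$p_value, P_FLOOR))
  above <- logp >= threshold_logp
  win <- (track$pos - 1L) %/% as.integer(window_bp) + 1L
  n_win <- max(win)
  n_snps <- tabulate(win, nbins = n_win)
  n_above <- tabulate(win[above], nbins = n_win)
  frac <- ifelse(n_snps > 0, n_above / pmax(n_snps, 1L), 0)
  qual <- which(frac >= min_inside_fraction & n_snps > 0)

  not_detected <- tibble::tibble(
    predictor = attr(track, "predictor"), chrom = attr(track, "chrom"),
    detected = FALSE, start_bp = NA_integer_, end_bp = NA_integer_,
    inside_fraction = NA_real_, outside_fraction = NA_real_,
    threshold = threshold_logp, window_bp = as.integer(window_bp))
  class(not_detected) <- c("step_region", class(not_detected))

  if (length(qual) < 2L) return(not_detected)
  # join qualifying windows whose gap is at most one window
  run_id <- cumsum(c(1L, diff(qual) > 2L))
  runs <- split(qual, run_id)
  best <- runs[[which.max(vapply(runs, length, 0L))]]
  if (length(best) < 2L) return(not_detected)

  inside <- win >= min(best) & win <= max(best)
  if (!any(!inside)) return(not_detected)
  inside_fraction <- mean(above[inside])
  outside_fraction <- mean(above[!inside])
  if (!(inside_fraction > 0 &&
        inside_fraction >= 2 * outside_fraction)) {
    return(not_detected)
  }
  hit_pos <- track$pos[inside & above]
  out <- not_detected
  out$detected <- TRUE
  out$start_bp <- min(hit_pos)
  out$end_bp <- max(hit_pos)
  out$inside_fraction <- inside_fraction
  out$outside_fraction <- outside_fraction
  out
}

#' Combine per-track region calls into a detection verdict
#'
#' An inversion counts as detected when any analyzed track (any PC, or the
#' cluster labeling) shows the step pattern; overlapping calls from
#' different tracks are all reported, never merged.
#'
#' @param regions a list of `step_region` rows (or a single one).
#' @return list with `detected` (logical) and `regions` (tibble of all
#'   per-track calls).
#' @export
detection_verdict <- function(regions) {
  if (inherits(regions, "data.frame")) regions <- list(regions)
  if (!length(regions)) abort("no regions to summarize")
  all_regions <- dplyr::bind_rows(regions)
  structure(list(detected = any(all_regions$detected),
                 regions = all_regions),
            class = "detection_verdict")
}

#' @export
print.detection_verdict <- function(x, ...) {
  cat("<detection_verdict> inversion detected:", x$detected, "\n")
  hits <- dplyr::filter(x$regions, .data$detected)
  if (nrow(hits)) {
    for (i in seq_len(nrow(hits))) {
      cat("  ", hits$predictor[i], ": ", hits$chrom[i], ":",
          hits$start_bp[i], "-", hits$end_bp[i], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Write a region report as TSV
#'
#' @param verdict a `detection_verdict` (or a tibble of `step_region`
#'   rows).
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(verdict, path) {
  df <- if (inherits(verdict, "detection_verdict")) verdict$regions
        else tibble::as_tibble(verdict)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Agreement between inferred clusters and known inversion karyotypes
#'
#' Cluster IDs carry no meaning across runs, so clusters are compared to
#' karyotypes through a classifier, never by raw label matching: a
#' multinomial logistic model predicts the karyotype from one-hot cluster
#' IDs (fit and evaluated in-sample), and the score is the balanced
#' accuracy (unweighted mean of per-karyotype recall) of its predictions.
#' The score is invariant to any permutation of cluster IDs.
#'
#' @param labels a `cluster_labels` tibble (`sample_id`, `cluster`).
#' @param truth a karyotype tibble (`sample_id`, `genotype` with values
#'   among `"hom-std"`, `"het"`, `"hom-inv"`, `"unknown"`); see
#'   [read_karyotypes()]. Samples with `"unknown"` are excluded.
#' @return balanced accuracy in `[0, 1]`.
#' @export
genotype_concordance <- function(labels, truth) {
  df <- dplyr::inner_join(tibble::as_tibble(labels),
                          tibble::as_tibble(truth), by = "sample_id")
  df <- dplyr::filter(df, .data$genotype != "unknown")
  if (nrow(df) < 2L) abort("need at least 2 samples with known karyotype")
  classes <- sort(unique(df$genotype))
  if (length(classes) < 2L) {
    abort("balanced accuracy is undefined with a single karyotype class")
  }
  y <- match(df$genotype, classes) - 1L
  X <- snp_feature_block(df$cluster)
  if (is.null(X)) X <- matrix(numeric(0), nrow = nrow(df), ncol = 0)
  fit <- fit_multinom_ridge(X, y)
  pred <- predict_multinom(fit, X)
  recalls <- vapply(seq_along(classes) - 1L, function(cc) {
    mean(pred[y == cc] == cc)
  }, 0)
  mean(recalls)
}

# argmax class prediction from a fit_multinom_ridge() fit
predict_multinom <- function(fit, x) {
  X <- cbind(1, as.matrix(x))
  eta <- cbind(X %*% fit$coefficients, 0)
  fit$classes[max.col(eta, ties.method = "first")]
}

#' Inversion frequency from karyotype counts
#'
#' The inverted-orientation allele frequency of a sample set:
#' `(2 * n_hom_inv + n_het) / (2 * n_samples)`.
#'
#' @param n_het number of heterozygous samples.
#' @param n_hom_inv number of homozygous-inverted samples.
#' @param n_samples total samples karyotyped.
#' @return frequency in `[0, 1]`.
#' @examples
#' inversion_frequency(16, 134, 150)   # 0.9467
#' @export
inversion_frequency <- function(n_het, n_hom_inv, n_samples) {
  if (any(c(n_het, n_hom_inv, n_samples) < 0)) {
    abort("karyotype counts must be non-negative")
  }
  if (n_samples == 0) abort("n_samples must be positive")
  if (n_het + n_hom_inv > n_samples) {
    abort("n_het + n_hom_inv exceeds n_samples")
  }
  (2 * n_hom_inv + n_het) / (2 * n_samples)
}

KARYOTYPE_ALIASES <- c(
  "hom-std" = "hom-std", "het" = "het", "hom-inv" = "hom-inv",
  "std/std" = "hom-std", "std/inv" = "het", "inv/std" = "het",
  "inv/inv" = "hom-inv", "0" = "hom-std", "1" = "het", "2" = "hom-inv",
  "unknown" = "unknown")

#' Read / write per-sample inversion karyotype labels
#'
#' TSV with columns `sample_id` and `genotype`. Accepted genotype spellings
#' are `hom-std`/`het`/`hom-inv`, `std/std`/`std/inv`/`inv/inv`, the codes
#' `0`/`1`/`2`, and `unknown` (also used for empty/NA entries).
#'
#' @param path TSV path.
#' @return tibble with `sample_id`, `genotype` (canonical spellings).
#' @export
read_karyotypes <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("sample_id", "genotype") %in% names(df))) {
    abort("karyotype file needs columns sample_id, genotype")
  }
  raw <- tolower(trimws(df$genotype))
  raw[is.na(raw) | !nzchar(raw)] <- "unknown"
  mapped <- unname(KARYOTYPE_ALIASES[raw])
  if (anyNA(mapped)) {
    bad <- unique(raw[is.na(mapped)])
    abort(paste0("unrecognized karyotype labels: ",
                 paste(bad, collapse = ", ")))
  }
  tibble::tibble(sample_id = df$sample_id, genotype = mapped)
}

#' @rdname read_karyotypes
#' @param truth tibble with `sample_id`, `genotype`.
#' @export
write_karyotypes <- function(truth, path) {
  readr::write_tsv(tibble::as_tibble(truth)[, c("sample_id", "genotype")],
                   path)
  invisible(path)
}
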