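#' Construct a variant table
#'
#' The central container for one chromosome arm of diploid biallelic SNP
#' genotypes. Genotypes are unphased category codes: `0` homozygous
#' reference, `1` heterozygous, `2` homozygous alternate, `-1` missing.
#'
#' @param chrom single chromosome-arm name.
#' @param snps tibble/data frame with columns `pos` (1-based bp, strictly
#'   increasing), `ref`, `alt` (single-nucleotide alleles).
#' @param genotypes integer matrix, `n_samples x n_snps`, codes in
#'   `{-1, 0, 1, 2}`.
#' @param sample_ids character vector of unique, non-empty sample IDs, one
#'   per genotype row.
#' @return an object of class `variant_table`.
#' @export
variant_table <- function(chrom, snps, genotypes, sample_ids) {
  snps <- tibble::as_tibble(snps)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  rownames(genotypes) <- sample_ids
  x <- structure(
    list(chrom = chrom, snps = snps, genotypes = genotypes,
         sample_ids = sample_ids),
    class = "variant_table")
  validate_variant_table(x)
}

validate_variant_table <- function(x) {
  if (length(x$chrom) != 1L || !nzchar(x$chrom)) {
    abort("`chrom` must be a single non-empty chromosome name")
  }
  if (!all(c("pos", "ref", "alt") %in% names(x$snps))) {
    abort("`snps` must have columns pos, ref, alt")
  }
  if (nrow(x$snps) == 0L) abort("variant table contains zero SNPs")
  if (any(diff(x$snps$pos) <= 0)) {
    abort("SNP positions must be strictly increasing")
  }
  if (anyDuplicated(x$sample_ids) || any(!nzchar(x$sample_ids))) {
    abort("sample IDs must be unique and non-empty")
  }
  if (nrow(x$genotypes) != length(x$sample_ids) ||
      ncol(x$genotypes) != nrow(x$snps)) {
    abort("genotype matrix dimensions do not match samples x SNPs")
  }
  bad <- setdiff(unique(as.vector(x$genotypes)), c(-1L, 0L, 1L, 2L))
  if (length(bad)) {
    abort(paste0("invalid genotype codes: ",
                 paste(bad, collapse = ", ")))
  }
  x
}

#' @export
print.variant_table <- function(x, ...) {
  cat("<variant_table> ", x$chrom, ": ", nrow(x$snps), " SNPs x ",
      length(x$sample_ids), " samples, positions ",
      min(x$snps$pos), "-", max(x$snps$pos), "\n", sep = "")
  miss <- mean(x$genotypes == -1L)
  cat("  missing genotype rate: ", signif(miss, 3), "\n", sep = "")
  invisible(x)
}

#' @export
dim.variant_table <- function(x) dim(x$genotypes)

#' Genotype calls as a long tibble
#'
#' @param x a `variant_table`.
#' @param ... unused.
#' @return tibble with one row per sample x SNP: `sample_id`, `chrom`,
#'   `pos`, `genotype` (code, `NA` for missing).
#' @export
tidy.variant_table <- function(x, ...) {
  g <- x$genotypes
  tibble::tibble(
    sample_id = rep(x$sample_ids, times = ncol(g)),
    chrom = x$chrom,
    pos = rep(x$snps$pos, each = nrow(g)),
    genotype = ifelse(as.vector(g) == -1L, NA_integer_, as.vector(g)))
}

#' Read a sample-ID subset list
#'
#' One sample ID per line; lines starting with `#` and blank lines are
#' ignored.
#'
#' @param path text file path.
#' @return character vector of IDs.
#' @export
read_sample_list <- function(path) {
  if (!file.exists(path)) abort(paste0("sample list not found: ", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Import biallelic SNP genotypes from a VCF file
#'
#' Reads a (plain or bgzipped) VCF of diploid genotypes for a single
#' chromosome arm, keeps biallelic SNP records only (single-nucleotide REF
#' and exactly one single-nucleotide ALT), and encodes unphased genotype
#' categories. `0/1` and `1/0` (and their phased forms) both map to
#' heterozygous; any genotype containing `.` maps to missing. No minor
#' allele frequency filter is applied, so monomorphic SNPs are retained.
#'
#' @param path VCF file (`.vcf` or `.vcf.gz`).
#' @param sample_subset optional character vector of sample IDs to keep
#'   (VCF column order is preserved among retained samples), or a path to a
#'   one-ID-per-line text file.
#' @return a [variant_table()].
#' @examples
#' vcf <- system.file("extdata", "toy.vcf", package = "invertype")
#' vt <- read_vcf(vcf)
#' vt
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  if (is.character(sample_subset) && length(sample_subset) == 1L &&
      file.exists(sample_subset)) {
    sample_subset <- read_sample_list(sample_subset)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {               # single record drops to a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (nrow(fix) == 0L) abort("VCF contains no records")
  chroms <- unique(fix[, "CHROM"])
  if (length(chroms) > 1L) {
    abort(paste0("VCF spans multiple chromosomes (",
                 paste(chroms, collapse = ", "),
                 "); import one chromosome arm at a time"))
  }
  nuc <- c("A", "C", "G", "T")
  keep <- toupper(fix[, "REF"]) %in% nuc & toupper(fix[, "ALT"]) %in% nuc
  if (!any(keep)) abort("zero biallelic SNPs after filtering")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) abort("VCF has no GT field")
  gt <- gt[keep, , drop = FALSE]
  all_ids <- colnames(gt)
  if (!is.null(sample_subset)) {
    missing_ids <- setdiff(sample_subset, all_ids)
    if (length(missing_ids)) {
      abort(paste0("sample IDs not present in VCF header: ",
                   paste(missing_ids, collapse = ", ")))
    }
    gt <- gt[, all_ids %in% sample_subset, drop = FALSE]
  }
  codes <- encode_gt_strings(gt)      # snps x samples
  pos <- as.integer(fix[keep, "POS"])
  ord <- order(pos)
  pos <- pos[ord]
  codes <- codes[ord, , drop = FALSE]
  ref <- toupper(fix[keep, "REF"])[ord]
  alt <- toupper(fix[keep, "ALT"])[ord]
  dup <- duplicated(pos)
  if (any(dup)) {
    warn(paste0("dropping ", sum(dup), " records at duplicated positions"))
    pos <- pos[!dup]; ref <- ref[!dup]; alt <- alt[!dup]
    codes <- codes[!dup, , drop = FALSE]
  }
  variant_table(
    chrom = chroms,
    snps = tibble::tibble(pos = pos, ref = ref, alt = alt),
    genotypes = t(codes),
    sample_ids = colnames(gt))
}

# GT strings -> category codes; matrix in, matrix out (same shape)
encode_gt_strings <- function(gt) {
  codes <- matrix(-1L, nrow = nrow(gt), ncol = ncol(gt))
  g <- gsub("|", "/", gt, fixed = TRUE)
  codes[g %in% "0/0"] <- 0L
  codes[g %in% c("0/1", "1/0")] <- 1L
  codes[g %in% "1/1"] <- 2L
  # anything containing "." or NA stays missing
  codes
}

#' One-hot genotype feature encoding
#'
#' Expands each SNP into three indicator features (hom-ref, het, hom-alt).
#' A missing genotype yields an all-zero block, which becomes neutral after
#' the column centering done by [fit_pca()]. Features are stored sparsely,
#' so arms with millions of SNPs stay tractable.
#'
#' @param table a [variant_table()].
#' @return an object of class `feature_matrix`: list with `values` (sparse
#'   `n_samples x 3*n_snps` 0/1 matrix), `column_map` (tibble: `feature`,
#'   `snp`, `category`), `sample_ids`.
#' @export
encode_features <- function(table) {
  validate_variant_table(table)
  g <- table$genotypes                      # samples x snps
  n <- nrow(g); m <- ncol(g)
  obs <- which(g >= 0L, arr.ind = TRUE)
  rows <- obs[, 1]
  cols <- 3L * (obs[, 2] - 1L) + g[obs] + 1L
  values <- Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                                 dims = c(n, 3L * m))
  rownames(values) <- table$sample_ids
  column_map <- tibble::tibble(
    feature = seq_len(3L * m),
    snp = rep(seq_len(m), each = 3L),
    category = rep(c("hom-ref", "het", "hom-alt"), times = m))
  structure(list(values = values, column_map = column_map,
                 sample_ids = table$sample_ids),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " samples x ", ncol(x$values),
      " one-hot features (", ncol(x$values) / 3L, " SNPs)\n", sep = "")
  invisible(x)
}

#' Recover genotype codes from a one-hot feature matrix
#'
#' Inverse of [encode_features()]: each 3-column SNP block maps back to a
#' category code, all-zero blocks to missing (`-1`).
#'
#' @param features a `feature_matrix`.
#' @return integer matrix `n_samples x n_snps`.
#' @export
decode_features <- function(features) {
  v <- features$values
  m <- ncol(v) / 3L
  codes <- matrix(-1L, nrow = nrow(v), ncol = m)
  idx <- Matrix::which(v != 0, arr.ind = TRUE)
  snp <- (idx[, 2] - 1L) %/% 3L + 1L
  cat_code <- (idx[, 2] - 1L) %% 3L
  codes[cbind(idx[, 1], snp)] <- as.integer(cat_code)
  rownames(codes) <- features$sample_ids
  codes
}

#' Serialize / restore a variant table as TSV
#'
#' Plain-text serialization used inside analysis work directories: SNP
#' metadata columns followed by one integer genotype column per sample.
#'
#' @param table a [variant_table()].
#' @param path output TSV path.
#' @return `path`, invisibly (writer); a `variant_table` (reader).
#' @export
write_variant_table <- function(table, path) {
  validate_variant_table(table)
  df <- cbind(
    data.frame(chrom = table$chrom, pos = table$snps$pos,
               ref = table$snps$ref, alt = table$snps$alt),
    as.data.frame(t(table$genotypes)))
  names(df) <- c("chrom", "pos", "ref", "alt", table$sample_ids)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- setdiff(names(df), c("chrom", "pos", "ref", "alt"))
  variant_table(
    chrom = df$chrom[1],
    snps = tibble::tibble(pos = df$pos, ref = df$ref, alt = df$alt),
    genotypes = t(as.matrix(df[, ids])),
    sample_ids = ids)
}
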