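# diploid SNP genotype simulator with known inversion karyotypes and
# optional two-population Balding-Nichols structure

#' Simulation parameters
#'
#' Defines one synthetic study: a chromosome arm of biallelic SNPs, an
#' optional polymorphic inversion segregating at frequency `q` whose
#' orientations carry diverged allele frequencies inside the inverted
#' interval, and optionally two populations whose background allele
#' frequencies drift apart under a Balding-Nichols model.
#'
#' Defaults describe the positive single-population regime used throughout
#' the package's validation: 100 samples, 5,000 SNPs on a 50 Mb arm, an
#' inversion spanning 20-43 Mb at frequency 0.4 with orientation divergence
#' 0.6, no structure, no missingness.
#'
#' @param n_samples diploid samples to draw.
#' @param n_snps SNPs (at least 10), placed uniformly at random (unique,
#'   sorted) along the arm.
#' @param arm_length_bp arm length in bp.
#' @param inversion_interval `c(start, end)` in bp, or `NULL` for no
#'   inversion (negative regime).
#' @param inversion_freq frequency `q` of the inverted orientation;
#'   karyotypes are drawn from Hardy-Weinberg proportions
#'   `(1-q)^2 / 2q(1-q) / q^2`.
#' @param divergence `d` in `[0, 1]`: inside-interval SNPs get
#'   `p_inv = clip(p_std + s * d)` with a random sign `s` per SNP.
#' @param maf_range range the background allele frequency is drawn from,
#'   uniformly, per SNP.
#' @param n_populations 1 or 2.
#' @param fst Balding-Nichols drift `F` in `[0, 1)` between the two
#'   populations (outside-interval SNPs only); 0 collapses to panmixia.
#' @param pop_split fraction of samples in population 1 (two-population
#'   case).
#' @param pop2_karyotypes optional subset of
#'   `c("hom-std", "het", "hom-inv")`: karyotypes allowed in population 2
#'   (Hardy-Weinberg proportions renormalized over the subset). Emulates
#'   the confounded regime where one species lacks karyotype classes.
#' @param missing_rate independent per-call missingness probability.
#' @param seed RNG seed.
#' @return a `simulation_params` list.
#' @export
simulation_params <- function(n_samples = 100,
                              n_snps = 5000,
                              arm_length_bp = 5e7,
                              inversion_interval = c(2e7, 4.3e7),
                              inversion_freq = 0.4,
                              divergence = 0.6,
                              maf_range = c(0.05, 0.5),
                              n_populations = 1,
                              fst = 0,
                              pop_split = 0.5,
                              pop2_karyotypes = NULL,
                              missing_rate = 0,
                              seed = 1) {
  p <- list(n_samples = n_samples, n_snps = n_snps,
            arm_length_bp = arm_length_bp,
            inversion_interval = inversion_interval,
            inversion_freq = inversion_freq, divergence = divergence,
            maf_range = maf_range, n_populations = n_populations,
            fst = fst, pop_split = pop_split,
            pop2_karyotypes = pop2_karyotypes,
            missing_rate = missing_rate, seed = seed)
  validate_params(p)
  structure(p, class = "simulation_params")
}

validate_params <- function(p) {
  bad <- character(0)
  if (p$n_samples < 2) bad <- c(bad, "n_samples must be >= 2")
  if (p$n_snps < 10) bad <- c(bad, "n_snps must be >= 10")
  if (p$arm_length_bp < p$n_snps) {
    bad <- c(bad, "arm_length_bp too short for n_snps unique positions")
  }
  iv <- p$inversion_interval
  if (!is.null(iv)) {
    if (length(iv) != 2 || iv[1] >= iv[2] || iv[2] > p$arm_length_bp ||
        iv[1] < 1) {
      bad <- c(bad, "inversion_interval must satisfy 1 <= a < b <= arm_length_bp")
    }
  }
  if (p$inversion_freq < 0 || p$inversion_freq > 1) {
    bad <- c(bad, "inversion_freq must be in [0, 1]")
  }
  if (p$divergence < 0 || p$divergence > 1) {
    bad <- c(bad, "divergence must be in [0, 1]")
  }
  if (length(p$maf_range) != 2 || p$maf_range[1] > p$maf_range[2] ||
      p$maf_range[1] < 0 || p$maf_range[2] > 1) {
    bad <- c(bad, "maf_range must be an increasing pair in [0, 1]")
  }
  if (!p$n_populations %in% c(1, 2)) {
    bad <- c(bad, "n_populations must be 1 or 2")
  }
  if (p$fst < 0 || p$fst >= 1) bad <- c(bad, "fst must be in [0, 1)")
  if (p$pop_split <= 0 || p$pop_split >= 1) {
    bad <- c(bad, "pop_split must be in (0, 1)")
  }
  if (!is.null(p$pop2_karyotypes) &&
      (!all(p$pop2_karyotypes %in% c("hom-std", "het", "hom-inv")) ||
       !length(p$pop2_karyotypes))) {
    bad <- c(bad, "pop2_karyotypes must be a non-empty subset of hom-std/het/hom-inv")
  }
  if (p$missing_rate < 0 || p$missing_rate >= 1) {
    bad <- c(bad, "missing_rate must be in [0, 1)")
  }
  if (length(bad)) abort(paste(bad, collapse = "; "))
  invisible(p)
}

KARYOTYPE_LEVELS <- c("hom-std", "het", "hom-inv")

#' Simulate a diploid SNP dataset with a known inversion
#'
#' Each sample carries two haplotypes, each of standard or inverted
#' orientation; the inverted count per sample is `Binomial(2, q)`
#' (Hardy-Weinberg). Inside the inverted interval, recombination
#' suppression is encoded directly: a SNP has orientation-specific allele
#' frequencies and a sample's genotype is the sum of one allele draw per
#' haplotype (`Bernoulli(p_std)` or `Bernoulli(p_inv)` according to that
#' haplotype's orientation). Outside the interval, SNPs are neutral: a
#' single background frequency, shifted per population by a
#' Balding-Nichols beta draw when two populations are simulated. SNPs are
#' conditionally independent given the karyotype (no linkage
#' disequilibrium decay model). Genotype calls are then masked missing
#' independently at `missing_rate`.
#'
#' @param params a [simulation_params()].
#' @return an object of class `synthetic_dataset`: list with `table` (a
#'   [variant_table()], chromosome name `"sim1"`), `truth_karyotypes`
#'   (tibble `sample_id`, `genotype`), `truth_region` (`c(start, end)` or
#'   `NULL`), `population_labels` (tibble `sample_id`, `population`), and
#'   `params`.
#' @export
simulate_dataset <- function(params) {
  validate_params(params)
  p <- params
  local_seed(p$seed, {
    n <- p$n_samples
    ids <- sprintf("S%03d", seq_len(n))
    pop <- if (p$n_populations == 2) {
      n1 <- max(1L, min(n - 1L, round(n * p$pop_split)))
      rep(1:2, times = c(n1, n - n1))
    } else rep(1L, n)
    # inversion karyotype = number of inverted haplotypes per sample
    kary <- rbinom(n, 2, p$inversion_freq)
    if (!is.null(p$pop2_karyotypes) && p$n_populations == 2) {
      allowed <- match(p$pop2_karyotypes, KARYOTYPE_LEVELS) - 1L
      q <- p$inversion_freq
      hw <- c((1 - q)^2, 2 * q * (1 - q), q^2)
      probs <- hw[allowed + 1L] / sum(hw[allowed + 1L])
      idx2 <- which(pop == 2L)
      kary[idx2] <- allowed[sample.int(length(allowed), length(idx2),
                                       replace = TRUE, prob = probs)]
    }
    pos <- sort(sample.int(p$arm_length_bp, p$n_snps))
    iv <- p$inversion_interval
    inside <- if (is.null(iv)) rep(FALSE, p$n_snps) else {
      pos >= iv[1] & pos <= iv[2]
    }
    base_p <- runif(p$n_snps, p$maf_range[1], p$maf_range[2])
    geno <- matrix(0L, nrow = n, ncol = p$n_snps)
    for (j in seq_len(p$n_snps)) {
      if (inside[j]) {
        s <- sample(c(-1, 1), 1)
        p_std <- base_p[j]
        p_inv <- min(max(p_std + s * p$divergence, 0), 1)
        geno[, j] <- rbinom(n, kary, p_inv) + rbinom(n, 2L - kary, p_std)
      } else if (p$n_populations == 2 && p$fst > 0) {
        a <- base_p[j] * (1 - p$fst) / p$fst
        b <- (1 - base_p[j]) * (1 - p$fst) / p$fst
        p_pop <- rbeta(2, a, b)
        geno[, j] <- rbinom(n, 2L, p_pop[pop])
      } else {
        geno[, j] <- rbinom(n, 2L, base_p[j])
      }
    }
    if (p$missing_rate > 0) {
      geno[matrix(runif(length(geno)) < p$missing_rate,
                  nrow = n)] <- -1L
    }
    alleles <- c("A", "C", "G", "T")
    ref <- alleles[sample.int(4L, p$n_snps, replace = TRUE)]
    alt <- vapply(ref, function(r) {
      sample(setdiff(alleles, r), 1)
    }, "", USE.NAMES = FALSE)
    structure(
      list(table = variant_table("sim1",
                                 tibble::tibble(pos = pos, ref = ref,
                                                alt = alt),
                                 geno, ids),
           truth_karyotypes = tibble::tibble(
             sample_id = ids, genotype = KARYOTYPE_LEVELS[kary + 1L]),
           truth_region = iv,
           population_labels = tibble::tibble(sample_id = ids,
                                              population = pop),
           params = p),
      class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", nrow(x$table$snps), " SNPs x ",
      length(x$table$sample_ids), " samples\n", sep = "")
  if (!is.null(x$truth_region)) {
    cat("  inversion: ", x$truth_region[1], "-", x$truth_region[2],
        " bp at frequency ", x$params$inversion_freq, "\n", sep = "")
  } else cat("  no inversion (negative regime)\n")
  cat("  karyotypes:",
      paste(names(table(x$truth_karyotypes$genotype)),
            table(x$truth_karyotypes$genotype), sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

#' Write a synthetic dataset as a VCF plus truth tables
#'
#' Writes a GT-only VCF 4.2 file that [read_vcf()] reads back into the
#' identical variant table (missing calls render as `./.`), plus
#' `<stem>_karyotypes.tsv` and `<stem>_populations.tsv` with the simulated
#' ground truth.
#'
#' @param dataset a `synthetic_dataset` (or a bare [variant_table()], in
#'   which case no truth files are written).
#' @param path output VCF path (`.vcf`).
#' @return invisibly, a character vector of the files written.
#' @export
write_vcf <- function(dataset, path) {
  table <- if (inherits(dataset, "synthetic_dataset")) dataset$table
           else dataset
  validate_variant_table(table)
  gt_strings <- c("0/0", "0/1", "1/1")
  g <- table$genotypes                       # samples x snps
  gt <- matrix("./.", nrow = ncol(g), ncol = nrow(g))
  obs <- which(g >= 0L, arr.ind = TRUE)
  gt[cbind(obs[, 2], obs[, 1])] <- gt_strings[g[obs] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", table$chrom, ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", table$sample_ids), collapse = "\t"))
  body <- paste(table$chrom, table$snps$pos, ".", table$snps$ref,
                table$snps$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  written <- path
  if (inherits(dataset, "synthetic_dataset")) {
    stem <- sub("\\.vcf(\\.gz)?$", "", path)
    kary_path <- paste0(stem, "_karyotypes.tsv")
    pop_path <- paste0(stem, "_populations.tsv")
    write_karyotypes(dataset$truth_karyotypes, kary_path)
    readr::write_tsv(dataset$population_labels, pop_path)
    written <- c(written, kary_path, pop_path)
  }
  invisible(written)
}
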