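test_that("parameter validation names every offending field", {
  expect_error(simulation_params(n_snps = 5), "n_snps")
  expect_error(simulation_params(inversion_freq = 1.5), "inversion_freq")
  expect_error(simulation_params(divergence = -0.1), "divergence")
  expect_error(simulation_params(inversion_interval = c(3e7, 2e7)),
               "inversion_interval")
  expect_error(simulation_params(fst = 1), "fst")
  expect_error(simulation_params(n_populations = 3), "n_populations")
  expect_error(simulation_params(missing_rate = 1), "missing_rate")
  expect_error(simulation_params(pop2_karyotypes = "wild"),
               "pop2_karyotypes")
})

test_that("simulation is reproducible given the seed", {
  p <- simulation_params(n_samples = 20, n_snps = 50, seed = 5)
  d1 <- simulate_dataset(p)
  d2 <- simulate_dataset(p)
  expect_identical(d1$table$genotypes, d2$table$genotypes)
  expect_identical(d1$truth_karyotypes, d2$truth_karyotypes)
  d3 <- simulate_dataset(simulation_params(n_samples = 20, n_snps = 50,
                                           seed = 6))
  expect_false(identical(d1$table$genotypes, d3$table$genotypes))
})

test_that("q = 1 makes every sample homozygous inverted", {
  ds <- simulate_dataset(simulation_params(n_samples = 30, n_snps = 50,
                                           inversion_freq = 1, seed = 3))
  expect_true(all(ds$truth_karyotypes$genotype == "hom-inv"))
  k <- table(factor(ds$truth_karyotypes$genotype,
                    levels = c("hom-std", "het", "hom-inv")))
  expect_equal(inversion_frequency(k[["het"]], k[["hom-inv"]], 30), 1.0)
})

test_that("zero divergence with one population leaves no karyotype signal", {
  ds <- simulate_dataset(simulation_params(
    n_samples = 150, n_snps = 300, divergence = 0, inversion_freq = 0.5,
    maf_range = c(0.2, 0.5), seed = 17))
  # genotypes are independent of the true karyotypes: the cluster-SNP
  # test against the truth labels is calibrated uniform (MAFs kept off
  # the sparse end so the chi-square reference applies)
  truth_lab <- make_labels(
    match(ds$truth_karyotypes$genotype,
          c("hom-std", "het", "hom-inv")) - 1L,
    sample_ids = ds$table$sample_ids)
  tr <- cluster_snp_test(ds$table, truth_lab, seed = 17)
  keep <- !tr$degenerate
  expect_gt(suppressWarnings(
    stats::ks.test(tr$p_value[keep], "punif"))$p.value, 0.01)
  # and no step region is called on the leading PCs
  p <- fit_pca(encode_features(ds$table), n_components = 4)
  dets <- vapply(1:4, function(pc) {
    detect_step_region(pc_snp_test(ds$table, p, pc))$detected
  }, NA)
  expect_false(any(dets))
})

test_that("karyotype draws follow Hardy-Weinberg proportions", {
  ds <- simulate_dataset(simulation_params(n_samples = 2000, n_snps = 10,
                                           arm_length_bp = 1e6,
                                           inversion_interval = c(1, 1e6),
                                           inversion_freq = 0.3, seed = 8))
  k <- table(factor(ds$truth_karyotypes$genotype,
                    levels = c("hom-std", "het", "hom-inv"))) / 2000
  expect_equal(unname(k[["hom-inv"]]), 0.09, tolerance = 0.25)
  expect_equal(unname(k[["het"]]), 0.42, tolerance = 0.15)
})

test_that("inside-region divergence is recovered from the genotypes", {
  ds <- simulate_dataset(simulation_params(
    n_samples = 200, n_snps = 1000, divergence = 0.4,
    maf_range = c(0.4, 0.5), inversion_freq = 0.5, seed = 77))
  kary <- ds$truth_karyotypes$genotype
  inside <- ds$table$snps$pos >= 2e7 & ds$table$snps$pos <= 4.3e7
  g <- ds$table$genotypes
  f_std <- colMeans(g[kary == "hom-std", inside]) / 2
  f_inv <- colMeans(g[kary == "hom-inv", inside]) / 2
  d_hat <- abs(f_inv - f_std)
  se <- stats::sd(d_hat) / sqrt(length(d_hat))
  expect_lt(abs(mean(d_hat) - 0.4), 3 * se)
})

test_that("missingness is injected at the requested rate", {
  ds <- simulate_dataset(simulation_params(n_samples = 50, n_snps = 400,
                                           missing_rate = 0.1, seed = 9))
  expect_equal(mean(ds$table$genotypes == -1L), 0.1, tolerance = 0.15)
})

test_that("positions are unique, sorted and within the arm", {
  ds <- simulate_dataset(simulation_params(n_samples = 20, n_snps = 500,
                                           seed = 10))
  pos <- ds$table$snps$pos
  expect_true(all(diff(pos) > 0))
  expect_lte(max(pos), 5e7)
  expect_gte(min(pos), 1)
})

test_that("VCF export round-trips the table and renders missing as ./.", {
  ds <- simulate_dataset(simulation_params(n_samples = 15, n_snps = 60,
                                           missing_rate = 0.1, seed = 12))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sim.vcf")
  files <- write_vcf(ds, path)
  expect_equal(length(files), 3L)   # VCF + karyotype + population truth
  vt <- read_vcf(path)
  expect_equal(unname(vt$genotypes), unname(ds$table$genotypes))
  expect_equal(vt$snps, ds$table$snps)
  expect_equal(vt$sample_ids, ds$table$sample_ids)
  expect_true(any(grepl("\\./\\.", readLines(path))))
  truth <- read_karyotypes(file.path(dir, "sim_karyotypes.tsv"))
  expect_equal(truth$genotype, ds$truth_karyotypes$genotype)
})

test_that("an empty table cannot be exported", {
  broken <- structure(
    list(chrom = "c", snps = tibble::tibble(pos = integer(),
                                            ref = character(),
                                            alt = character()),
         genotypes = matrix(integer(), nrow = 0, ncol = 0),
         sample_ids = character()),
    class = "variant_table")
  expect_error(write_vcf(broken, tempfile(fileext = ".vcf")),
               "zero SNPs")
})

test_that("the confounded regime mixes population and karyotype clusters", {
  ds <- simulate_dataset(simulation_params(
    n_snps = 2000, n_populations = 2, fst = 0.1, inversion_freq = 0.5,
    pop2_karyotypes = c("het", "hom-inv"), seed = 5))
  expect_true(all(ds$truth_karyotypes$genotype[
    ds$population_labels$population == 2] %in% c("het", "hom-inv")))
  pca <- fit_pca(encode_features(ds$table), n_components = 4)
  sw <- sweep_kmeans(pca, seed = 5)
  expect_equal(attr(sw, "suggested_k"), 3L)
  lab <- cluster_samples(pca, k = 3, seed = 5)
  # at least one cluster mixes karyotypes or spans the population split:
  # clusters do not correspond one-to-one to the three karyotypes
  conf <- table(lab$cluster, ds$truth_karyotypes$genotype)
  expect_lt(sum(apply(conf, 1, max)), nrow(lab))
})
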