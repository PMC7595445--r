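make_track <- function(pos, p, chrom = "chr", predictor = "PC1") {
  invertype:::new_assoc_track(
    tibble::tibble(chrom = chrom, pos = as.integer(pos), p_value = p,
                   df = 2L, degenerate = FALSE),
    predictor = predictor, chrom = chrom)
}

test_that("a flat track detects nothing", {
  tr <- make_track(seq(1e5, 5e7, by = 1e5), 1)
  r <- detect_step_region(tr)
  expect_false(r$detected)
  expect_true(is.na(r$start_bp))
  expect_error(detect_step_region(make_track(integer(0), numeric(0))),
               "empty")
})

test_that("a synthetic step is called within one window of its edges", {
  pos <- seq(1e4, 5e7, by = 1e4)          # SNPs every 10 kb on a 50 Mb arm
  inside <- pos >= 2e7 & pos <= 4.3e7
  p <- ifelse(inside, 1e-20, 0.5)
  r <- detect_step_region(make_track(pos, p))
  expect_true(r$detected)
  expect_lte(abs(r$start_bp - 20000001), 500000)
  expect_lte(abs(r$end_bp - 43000000), 500000)
  expect_gte(r$inside_fraction, 2 * r$outside_fraction)
})

test_that("runs may bridge a single sub-threshold window but not two", {
  pos <- seq(1e4, 2e7, by = 1e4)
  w <- (pos - 1) %/% 5e5 + 1
  # windows 10-20 hot except a one-window gap at 15: one bridged run
  hot <- w >= 10 & w <= 20 & w != 15
  r <- detect_step_region(make_track(pos, ifelse(hot, 1e-20, 0.5)))
  expect_true(r$detected)
  expect_lte(r$start_bp, 10 * 5e5)
  expect_gte(r$end_bp, 19 * 5e5)
  # a two-window gap splits the run; the larger half is called
  hot2 <- (w >= 10 & w <= 12) | (w >= 15 & w <= 20)
  r2 <- detect_step_region(make_track(pos, ifelse(hot2, 1e-20, 0.5)))
  expect_true(r2$detected)
  expect_gte(r2$start_bp, 14 * 5e5)
})

test_that("an arm-wide plateau is structure, not a step", {
  pos <- seq(1e4, 5e7, by = 1e4)
  r <- detect_step_region(make_track(pos, 1e-20))
  expect_false(r$detected)
})

test_that("detection verdict is the disjunction over tracks", {
  pos <- seq(1e4, 5e7, by = 1e4)
  inside <- pos >= 2e7 & pos <= 4.3e7
  hit <- detect_step_region(make_track(pos, ifelse(inside, 1e-20, 0.5),
                                       predictor = "PC2"))
  miss <- detect_step_region(make_track(pos, 0.5, predictor = "PC1"))
  v <- detection_verdict(list(miss, hit))
  expect_true(v$detected)
  expect_equal(nrow(v$regions), 2L)
  expect_equal(v$regions$predictor[v$regions$detected], "PC2")
  v2 <- detection_verdict(list(miss, miss))
  expect_false(v2$detected)
  # overlapping calls from two tracks are both reported, never merged
  hit2 <- detect_step_region(make_track(pos, ifelse(inside, 1e-20, 0.5),
                                        predictor = "clusters k=3"))
  v3 <- detection_verdict(list(hit, hit2))
  expect_equal(sum(v3$regions$detected), 2L)
})

test_that("genotype concordance scores known cluster-karyotype agreements", {
  # clusters identical to genotypes
  truth <- tibble::tibble(sample_id = sprintf("S%03d", 1:90),
                          genotype = rep(c("hom-std", "het", "hom-inv"),
                                         each = 30))
  lab <- make_labels(rep(0:2, each = 30))
  expect_equal(genotype_concordance(lab, truth), 1.0)
  # a constant predictor on a 90/10 split scores 0.5
  truth2 <- tibble::tibble(sample_id = sprintf("S%03d", 1:100),
                           genotype = rep(c("hom-std", "het"),
                                          times = c(90, 10)))
  lab2 <- make_labels(rep(0L, 100))
  expect_equal(genotype_concordance(lab2, truth2), 0.5)
  # 2 of 30 samples swapped between two classes: hand-computed confusion
  swapped <- rep(0:2, each = 30)
  swapped[1] <- 1L; swapped[31] <- 0L
  lab3 <- make_labels(swapped, sample_ids = truth$sample_id)
  expect_equal(genotype_concordance(lab3, truth),
               (29 / 30 + 29 / 30 + 1) / 3)
})

test_that("concordance is invariant to cluster ID permutation", {
  truth <- tibble::tibble(sample_id = sprintf("S%03d", 1:60),
                          genotype = rep(c("hom-std", "het", "hom-inv"),
                                         each = 20))
  lab_a <- make_labels(rep(c(2L, 0L, 1L), each = 20))
  lab_b <- make_labels(rep(c(1L, 2L, 0L), each = 20))
  expect_equal(genotype_concordance(lab_a, truth),
               genotype_concordance(lab_b, truth))
})

test_that("concordance requires at least two karyotype classes", {
  truth <- tibble::tibble(sample_id = sprintf("S%03d", 1:10),
                          genotype = rep("het", 10))
  expect_error(genotype_concordance(make_labels(rep(0:1, 5)), truth),
               "single karyotype")
  truth$genotype[1:5] <- "unknown"
  expect_error(genotype_concordance(make_labels(rep(0:1, 5)), truth),
               "single karyotype")
})

test_that("inversion frequency reproduces the benchmark arithmetic", {
  expect_equal(round(100 * inversion_frequency(16, 134, 150), 1), 94.7)
  expect_equal(round(100 * inversion_frequency(15, 66, 81), 1), 90.7)
  expect_equal(round(100 * inversion_frequency(5, 16, 34), 1), 54.4)
  expect_equal(round(100 * inversion_frequency(1, 68, 69), 1), 99.3)
  expect_equal(inversion_frequency(0, 0, 25), 0)
  expect_error(inversion_frequency(-1, 0, 5), "non-negative")
  expect_error(inversion_frequency(3, 3, 5), "exceeds")
  expect_error(inversion_frequency(0, 0, 0), "positive")
})

test_that("karyotype label files accept the documented aliases", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgenotype", "a\tstd/std", "b\tinv/std",
               "c\tinv/inv", "d\t2", "e\tunknown", "f\t0"), path)
  k <- read_karyotypes(path)
  expect_equal(k$genotype, c("hom-std", "het", "hom-inv", "hom-inv",
                             "unknown", "hom-std"))
  writeLines(c("sample_id\tgenotype", "a\twhat"), path)
  expect_error(read_karyotypes(path), "unrecognized")
})
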