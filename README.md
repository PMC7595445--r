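# invertype

Detect, genotype, and localize polymorphic chromosomal inversions from
SNP genotype data.

## The problem

A paracentric inversion suppresses recombination between the inverted and
standard orientations of a chromosome segment. Orientation-private alleles
therefore accumulate inside the inverted interval, and in a sample of
diploid individuals the three inversion karyotypes (homozygous standard,
heterozygous, homozygous inverted) become separable from SNP genotypes
alone. This matters most for non-model insects — *Anopheles* malaria
vectors chief among them — whose inversion breakpoints sit in long repeats
that defeat read-alignment methods, leaving SNP-based inference as the
practical route.

`invertype` implements the PCA-based workflow used for this task:

1. **Import**: biallelic SNPs from a per-chromosome-arm VCF, one-hot
   encoded over the genotype categories {hom-ref, het, hom-alt}
   (missing calls become all-zero blocks, neutral after centering).
2. **PCA**: exact eigendecomposition of the centered feature matrix;
   inversions dominate leading components.
3. **Genotyping**: k-means over PC 1–2 coordinates; the inertia elbow
   (max distance to the first–last chord of the curve) suggests `k`;
   clusters are matched to karyotypes through a classifier and scored by
   balanced accuracy `mean_g(recall_g)`.
4. **Localization**: per-SNP ridge-penalized multinomial
   logistic-regression likelihood-ratio tests, either of genotype on a PC
   coordinate (df `G−1`) or of cluster label on the SNP's genotype
   features (df `(K−1)·F`, class-balanced by seeded downsampling). A
   contiguous plateau of `−log10 p ≥ max(8, log10(n/0.05))` along the arm
   — the Manhattan-plot "step" — is called as the inverted interval by a
   windowed inside/outside contrast rule.
5. **Frequency**: the inverted-allele frequency from karyotype counts,
   `(2·n_hom-inv + n_het) / (2·n)`.

A synthetic-data module simulates diploid genotypes with known
karyotypes (Hardy–Weinberg draws at inversion frequency `q`,
orientation-divergent allele frequencies `|p_inv − p_std| = d` inside the
interval, optional two-population Balding–Nichols drift `F`, missing
calls), so every stage is testable offline — including the regime where
population structure mimics an inversion in PC space and only the
association tests tell the difference.

## Worked example

```r
library(invertype)

ds  <- simulate_dataset(simulation_params(seed = 42))  # 100 samples, 5000 SNPs,
                                                       # inversion 20-43 Mb, q = 0.4, d = 0.6
pca <- fit_pca(encode_features(ds$table), n_components = 10)
head(tidy(pca), 3)
#> # A tibble: 3 × 2
#>      pc  ratio
#>   <int>  <dbl>
#> 1     1 0.0763
#> 2     2 0.0316
#> 3     3 0.0119

sweep <- sweep_kmeans(pca, seed = 42)
glance(sweep)$suggested_k
#> [1] 3

labels <- cluster_samples(pca, k = 3, seed = 42)
genotype_concordance(labels, ds$truth_karyotypes)
#> [1] 1

track <- pc_snp_test(ds$table, pca, pc = 1)
detect_step_region(track)[, c("predictor", "detected", "start_bp", "end_bp")]
#> # A tibble: 1 × 4
#>   predictor detected start_bp   end_bp
#>   <chr>     <lgl>       <int>    <int>
#> 1 PC1       TRUE     20003943 42955039
```

PC1 explains 7.6% of the variance against a ~1.1% noise floor; the
inertia elbow picks three clusters, which reproduce the simulated
karyotypes exactly (balanced accuracy 1.0); and the step-pattern call on
the PC1 track recovers the simulated 20–43 Mb interval to within a few
kb of the first and last diagnostic SNPs. `autoplot(pca, labels)` and
`autoplot(track)` draw the corresponding scatter and Manhattan plots.

The same workflow is scriptable from a shell via `exec/invertype`
(subcommands `import`, `simulate`, `pca-train`, `sweep-clusters`,
`output-clusters`, `pc-association`, `cluster-association`,
`detect-region`, `evaluate-genotypes`, `frequency`, ...), with every
numeric artifact a TSV in the analysis workdir.

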