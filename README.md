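# bayeswgr

Weighted Bayesian whole-genome regression for genomic prediction in
livestock, with the full supporting pipeline: SNP quality control,
deregression of estimated breeding values (EBVs), BayesB/BayesC mixture
models over a grid of prior null-marker proportions, 1-Mb-window
partitioning of posterior genetic variance for association scans, and
cross-validation on relatedness-minimizing K-means folds built from the
pedigree numerator relationship matrix (NRM). A synthetic-data
generator (pedigree, gene-dropped genotypes, spike-and-slab trait
architectures, EBV records with heterogeneous reliabilities) makes
every stage testable without proprietary evaluation data.

## Who it is for

Animal breeders and quantitative geneticists who want a transparent,
tested R implementation of the standard dairy-cattle genomic-selection
workflow — the kind of analysis usually run through GenSel-style
software — with tidyverse-friendly interfaces: data frames in, tibbles
out, `tidy()`/`glance()` on fitted objects, `autoplot()` on results.

## The model

Records are deregressed EBVs. In `incPA` mode `DEBV = EBV / r²`; in
`excPA` mode the parent-average contribution is absorbed out of the
mixed-model equations first (see the methods vignette for the algebra).
Each record gets the reliability-based weight

    w = (1 − h²) / ([c + (1 − r²)/r²] · h²),   c = 0.4 by default,

and enters the regression

    y_i = μ + Σ_j Z_ij u_j δ_j + e_i,   e_i ~ N(0, σ²_e / w_i),

where δ_j is a 0/1 inclusion indicator with prior P(δ_j = 0) = π.
BayesB gives each marker its own scaled-inverse-χ² variance; BayesC
shares one. Gibbs sampling (collapsed δ-update, GenSel lineage) runs
110,000 iterations with 10,000 burn-in and thinning by 10 in the
production schedule — exactly 10,000 retained samples. Per retained
sample, window genomic variances are partitioned so shares sum to 100%;
windows at or above 1.0% of genetic variance are flagged (a 25-fold
enrichment over the 0.04% infinitesimal expectation at 2,524 windows).

## Worked example

```r
library(bayeswgr)

ped   <- simulate_pedigree(n_founders = 200, n_generations = 2,
                           offspring_per_mating = 2, seed = 1)
geno  <- gene_drop_genotypes(ped, n_snps = 800, seed = 2, n_chr = 8,
                             spacing_bp = 100000)
trait <- simulate_trait(geno, pi = 0.99, h2 = 0.3, seed = 3)
ebv   <- simulate_ebv_records(trait, ped, rel_low = 0.4, rel_high = 0.9, seed = 4)

# inject QC failures, then filter them back out
dirty <- corrupt_for_qc(geno, frac_lowcall = 0.02, frac_lowmaf = 0.02,
                        frac_hwe = 0.02, seed = 5)
clean <- apply_qc(dirty$genotypes)
attr(qc_report(clean), "counts")
#>   criterion removed retained total
#> 1 map             0      752   800
#> 2 call_rate      16      752   800
#> 3 maf            16      752   800
#> 4 hwe            16      752   800

tp   <- trait_params("SIM", sigma_a2 = 0.3, sigma_e2 = 0.7)  # h2 = 0.3
debv <- deregress(ebv, tp, mode = "incPA")
fit  <- fit_bayes(clean, debv,
                  bayes_config("BayesC", pi = 0.99, chain_length = 3000,
                               burn_in = 1000, thin = 4, seed = 6))
glance(fit)
#>   method    pi n_animals n_snps retained      mu sigma_u2 sigma_e2
#> 1 BayesC  0.99       600    752      500 -0.0151   0.0532    0.596

wp <- window_variance_profile(fit, clean)
dplyr::arrange(tibble::as_tibble(wp), dplyr::desc(gv_percent))[1:3, ]
#>   window_id   chr    mb n_snps gv_percent significant
#> 1 5_5           5     5      9       47.0 TRUE
#> 2 6_9           6     9     10       15.4 TRUE
#> 3 5_9           5     9      9       13.6 TRUE

informative_snps(wp, fit, min_model_freq = 0.1)[1:3, ]
#>   window_id gv_percent snp_id   model_freq
#> 1 5_5            47.0  snp00451      1
#> 2 6_9            15.4  snp00592      1
#> 3 5_9            13.6  snp00499      1

A     <- build_nrm(ped)
folds <- kmeans_folds(A, k = 5, seed = 7)
cv    <- run_cv(clean, debv, folds,
                bayes_config("BayesC", pi = 0.99, chain_length = 1500,
                             burn_in = 300, thin = 3, seed = 8,
                             store_samples = FALSE))
glance(cv)
#>   mean_accuracy     se     k
#> 1         0.631 0.0593     5
```

Reading the output: QC removed exactly the 48 corrupted SNPs (16 per
failure mode) and nothing else. The three highest-GV windows — 5_5 at
47% of posterior genetic variance, 6_9 and 5_9 — are all windows that
truly carry causal loci under this seed, and their top informative SNPs
are in the model in essentially every retained sample (model frequency
1.0). Five-fold cross-validated accuracy, the correlation between
predicted molecular breeding values and the deregressed responses in
each validation fold, averages 0.631 ± 0.059.

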