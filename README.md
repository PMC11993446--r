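# gastromicro

Analysis of the intratumoral microbiome of gastric cancer from host
sequencing data, for researchers working with PathSeq-style taxonomic
profiles of tumor tissue and matched blood.

Tumor sequencing captures microbial reads at very low biomass, where
reagent and environmental contamination can swamp the genuine signal.
This package implements a blood-controlled *include-list* decontamination
and the downstream statistical analysis chain:

1. **Decontamination.** A species is *present* in a sample when it has
   ≥ 2 unambiguously mapped reads. Per species, tissue prevalence is
   compared with blood prevalence by a one-sided Fisher exact test
   (exact hypergeometric tail), with Storey q-values across the species
   family. The include-list keeps species with q < 0.05 in either cohort
   whose blood prevalence is < 20% in both, plus literature-curated
   species from the borderline band (0.05 ≤ q < 0.4) and manual
   additions such as Epstein–Barr virus.
2. **Normalisation.** Whole-genome cohorts: microbes per human cell,
   `(Σ reads_s / genome_s) / (human reads / G_eff)` with
   `G_eff = G · (purity·ploidy/2 + (1 − purity))`. Exome cohorts: the
   sum of microbial reads.
3. **Subtyping.** MSI inferred at ≥ 20 somatic coding variants/Mb;
   TCGA-style molecular subtype from the threshold hierarchy
   EBV load ≥ 10⁻³ → EBV, else SCV ≥ 20/Mb → MSI, else ploidy > 2.5 →
   CIN, else GS.
4. **Diversity.** Shannon alpha diversity; Bray–Curtis beta diversity
   with sequential (Type I) PERMANOVA in a pre-defined covariate order,
   an 85% covariate-completeness rule, and removal of empty/incomplete
   samples.
5. **Differential abundance.** MaAsLin2-style multivariable linear
   models on log2 total-sum-scaled abundance, fitted only for
   PERMANOVA-significant covariates (q < 0.25, BH within covariate).

Real cohorts of this design are controlled-access, so the package
includes a synthetic paired tumor/blood generator
(`simulate_cohort()`) with planted residents, contaminants,
negative-binomial counts, and clinicopathological effects — every stage
is testable against known ground truth.

## Worked example

```r
library(gastromicro)

sim_a <- simulate_cohort(cohort_config(cohort = "A", mode = "wgs_like", seed = 132))
sim_b <- simulate_cohort(cohort_config(cohort = "B", mode = "wes_like", seed = 133))

res_a <- prevalence_tests(sim_a$tumor, sim_a$blood)
res_b <- prevalence_tests(sim_b$tumor, sim_b$blood)
incl  <- build_include_list(res_a, res_b, manual_additions = "EBV")
filt  <- apply_include_list(sim_a$tumor_score, incl)
decontamination_report(list(A = res_a, B = res_b), incl, filtered = list(A = filt))
#> Decontamination report
#>   species universe: 300; included: 101; excluded: 200
#>   provenance: manual=1, statistical=100
#>   retained signal: A=56.4%
#>   borderline species awaiting curation: 39
```

All 100 planted tissue-resident species are recovered statistically, all
200 shared-prevalence contaminants are excluded, and the include-list
retains 56% of the original score mass — decontamination removes roughly
half the apparent microbial signal as contamination.

```r
md    <- binarize_stage(sim_a$metadata)
terms <- completeness_filter(md, c("geography", "age", "sex", "histology",
                                   "msi_status", "pT", "pN"))
terms <- terms[sapply(terms, function(tm) length(unique(na.omit(md[[tm]]))) >= 2)]
kept  <- drop_empty_samples(filt, md, terms)
pm    <- permanova_sequential(bray_curtis(kept$matrix), kept$metadata, terms,
                              n_permutations = 999, seed = 99)
tidy(pm)
#> # A tibble: 7 × 6
#>   term          df sum_of_squares      R2 statistic p.value
#> 1 age            1          0.293 0.0111      0.946   0.581
#> 2 sex            1          0.895 0.0337      2.89    0.001
#> 3 histology      3          0.861 0.0324      0.925   0.742
#> 4 msi_status     1          1.82  0.0687      5.88    0.001
#> 5 pT             1          0.427 0.0161      1.38    0.029
#> 6 pN             1          0.212 0.00801     0.685   0.968
#> 7 Residual      71         22.0   0.830      NA      NA
```

The three covariates with planted effects (sex, MSI status, pT) are
exactly the PERMANOVA-significant terms; each R² is that term's share of
the Bray–Curtis variance. Differential abundance then runs on those
covariates only:

```r
da <- differential_abundance(filt, md, select_da_covariates(pm))
glance(da)
#> # A tibble: 1 × 3
#>   n_taxa n_covariates n_significant
#> 1    100            3            22
autoplot(da)   # coefficient bars per covariate, coloured by direction
```

A complete run — simulation through differential abundance, with every
artifact written as TSV + JSON and a checksummed manifest — is one call:

```r
manifest <- run_all(run_config(out_dir = "run1", seed = 1))
```

A thin command-line wrapper with `simulate`, `decontam`, `run-all` and
`validate` subcommands is installed at `inst/cli/gastromicro.R`.

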