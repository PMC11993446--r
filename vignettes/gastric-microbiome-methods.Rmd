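---
title: "Methods: include-list decontamination and intratumoral microbiome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: include-list decontamination and intratumoral microbiome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastromicro)
```

# The problem

Tumor tissue sequenced for host genomics also captures reads from microbes
living in the tissue — but at very low biomass, where reagent and
environmental contamination can dominate the signal. `gastromicro`
implements an analysis chain for gastric-cancer cohorts profiled with a
PathSeq-style taxonomic classifier: statistical decontamination against
matched blood, abundance normalisation, molecular subtype inference,
diversity analysis with sequential PERMANOVA, and multivariable
differential abundance. Because the cohorts this kind of analysis targets
are controlled-access, the package ships a synthetic paired tumor/blood
generator with known ground truth; every stage is validated against that
truth rather than against any private dataset.

# Include-list decontamination

The central assumption: a genuinely tissue-resident species is detected
more often in tumor tissue than in matched blood from the same cohort,
whereas a reagent contaminant appears at similar prevalence in both
materials, since both pass through the same library preparation.

*Prevalence* is defined once, for both materials: a species is present in
a sample when it has at least `min_reads = 2` unambiguously mapped reads.
Score-weighted abundances are deliberately rejected here
(`compute_prevalence()` errors on a score matrix): scores spread shared
reads across taxa and would count spillover as presence.

Per species and cohort, a one-sided Fisher exact test
(`fisher_one_sided()`) asks whether tissue prevalence exceeds blood
prevalence; the p-value is the exact hypergeometric upper tail, computed
directly rather than through a normal approximation, and degenerate
tables (a zero margin) conservatively return 1. Multiplicity is handled
with Storey q-values (`estimate_qvalues()`): the smoother estimate of the
null proportion pi0 (natural spline through pi0(lambda), evaluated at
lambda = 0.95) scales the Benjamini-Hochberg step-up values. With fewer
than 100 tests the smoother is unstable, so pi0 is fixed at 1 and the
result is exactly BH; this keeps small synthetic runs stable.

The include-list (`build_include_list()`) then has three routes:

* **statistical** — q < 0.05 in *either* cohort, and blood prevalence
  below 20% of samples in *both* cohorts. The cap guards against a
  species that squeaks to significance while still being common in blood.
  A species never observed in one cohort counts as prevalence 0/n there,
  so the cap is trivially met in that cohort.
* **curated** — species whose cohort-B q lies in the curation band
  [0.05, 0.4) are eligible for manual literature curation (digestive or
  respiratory tract inhabitants); they enter only if the user supplies
  them in the curated list. The blood cap is *not* re-applied on this
  route: curation is a deliberate human override of the statistical
  evidence, and the band species are by construction low-prevalence
  borderline cases. This was a genuinely open design point; we chose the
  narrower reading and record the curated provenance so the choice is
  auditable downstream.
* **manual** — always included (the canonical example is Epstein-Barr
  virus, which is biologically expected in a subset of gastric tumors but
  too rare in blood-controlled cohorts to reach significance).

`apply_include_list()` restricts matrices to the list but *keeps*
all-zero samples, flagging them; they are only removed where an analysis
requires it. Genus tables are always recomputed by summing included
species (`aggregate_to_genus()`), never by filtering a pre-made genus
table, so genus and species levels stay consistent after decontamination.

# Abundance normalisation

Whole-genome cohorts use microbes per human cell:

$$\textrm{microbes per human cell} =
  \frac{\sum_s \textrm{reads}_s / \textrm{genome size}_s}
       {\textrm{human reads} / \textrm{human genome size}}$$

with the human genome size adjusted for tumor ploidy and purity. The
adjustment models the sample as a mixture of tumor cells (fraction
`purity`, each with `ploidy/2` diploid-genome equivalents) and normal
diploid cells:

$$G_{\textrm{eff}} = G \cdot
  \left(\textrm{purity}\cdot\frac{\textrm{ploidy}}{2}
  + (1-\textrm{purity})\right)$$

This mixture form is the standard interpretation of a ploidy/purity
adjustment; it is isolated in `effective_human_genome_size()` so it can
be swapped if a different convention is needed. Defaults: base human
genome 3.1e9 bp, EBV genome 1.718e5 bp — both configurable constants.

Exome cohorts use the plain sum of microbial reads (`total_read_sum()`):
exome capture over-represents exons, so human exome reads are not a
valid genome-wide denominator.

The analysis matrices carry the PathSeq "score" semantics (score-weighted
read mass); we treat the score as an opaque nonnegative abundance and do
not assume within-sample normalisation. The decontamination stage is the
only place where unambiguous-read semantics are mandatory.

# Molecular subtyping

Where direct MSI/subtype assays are unavailable, labels are inferred
from three thresholds (Bass-style hierarchy, `infer_tcga_subtype()`):

1. EBV load ≥ 1e-3 virions per human cell → **EBV**;
2. otherwise somatic coding variants ≥ 20 /Mb → **MSI**;
3. otherwise ploidy > 2.5 → **CIN**; else **GS**.

EBV takes precedence over hypermutation: a hypothetical EBV-positive
hypermutated sample is called EBV. The EBV and SCV boundaries are
inclusive (a sample at exactly 20 mut/Mb is MSI, per the inference rule's
definition); the ploidy boundary is exclusive (exactly 2.5 is GS), since
2.5 separates near-diploid from aneuploid and the aneuploid class should
strictly exceed it. Both boundary conventions are tested explicitly and
the hierarchy is configurable. MSI-low assay labels are grouped with MSS
(`harmonize_msi_labels()`).

# Diversity and PERMANOVA

Alpha diversity is the Shannon index on within-sample proportions
(natural log); an all-zero sample is defined as 0 and flagged. Beta
diversity is Bray-Curtis on the decontaminated score matrix, with no
rarefaction or relative-abundance transform — raw scores are the default
because the measure of interest includes load differences, and the choice
is isolated so a proportion-based variant can be slotted in.

`permanova_sequential()` implements the McArdle-Anderson decomposition:
Gower-center `-d^2/2`, then take sequential (Type I) trace increments
against the hat matrices of the growing design. Sequential sums of
squares match the convention of reporting one R² per term from a single
model in a pre-defined covariate order (geography, age, sex, histology,
MSI status, pT, pN). Covariates enter only when their completeness
strictly exceeds 85%, samples with no remaining taxa and samples missing
any retained term are removed first, and staged covariates are binarised
(pT1/2 vs pT3/4, pN0 vs node-positive, MSI vs MSS). Permutation p-values
use the unbiased estimator `(1 + #{F* ≥ F}) / (1 + n_permutations)` with
raw-label permutation (999 permutations by default) and a fixed seed, so
results are bit-reproducible. The implementation is verified against an
independent reference implementation (vegan's `adonis2`) to 1e-8 on
random instances in the test suite.

# Differential abundance

`differential_abundance()` re-implements the MaAsLin2 default recipe
rather than wrapping the tool, keeping the pipeline single-language and
unit-testable: total-sum scaling; prevalence filter at 10% of samples;
per-taxon log2 transform with a pseudocount of half that taxon's smallest
nonzero relative abundance; one multivariable linear model per taxon with
all selected covariates jointly; BH q-values across taxa within each
covariate; significance at q < 0.25. Covariates are admitted only when
the corresponding PERMANOVA term is significant at p < 0.05 — the
differential-abundance stage is gated on the global compositional test.
Coefficients are log2 effect sizes on relative abundance; a positive sign
means enrichment at the comparison level (MSI, male, pT3/4, node-positive).

# The synthetic cohort generator

`simulate_cohort()` emulates the data layout the pipeline consumes, with
known ground truth:

* **Species classes.** Resident species (default 100) have tissue
  prevalence 0.4 and blood prevalence 0.02; contaminants (default 200)
  have prevalence 0.3 in both materials. These defaults put residents
  and contaminants at realistic detection rates for low-biomass tissue
  while keeping the contaminant pool larger than the resident pool, as
  observed in blood-controlled cohorts.
* **Counts.** Given presence, unambiguous reads are
  `2 + NegBin(mu = nb_mean - 2, size = nb_dispersion)` (defaults mu = 50,
  size = 0.8). The left shift by 2 makes "present" identical to the
  two-read prevalence rule, so `expected_prevalence()` is an exact
  analytic oracle for the decontamination recovery tests. The generator
  intentionally does not model sub-threshold presence; real data will
  contain 1-read detections that the rule ignores.
* **Covariate effects.** A planted log2 fold change scales a species'
  latent abundance: presence odds and the count mean both scale by
  `2^lfc`. Scaling realized counts alone would not survive the two-read
  truncation in the downward direction, so the odds/mean formulation is
  what makes a planted fold change recoverable in principle by any
  correct method. Defaults plant a 1.5 log2 male enrichment on eight
  resident species and a 1.5 log2 pT1/2 enrichment on eight others.
* **MSI effects.** MSI tumors get all resident counts multiplied by 4
  and resident presence probability raised by 0.15 — a global
  abundance-and-richness lift, distinct from the per-species
  compositional effects above.
* **Metadata.** A latent molecular subtype is drawn at TCGA-like gastric
  frequencies (EBV 9%, MSI 22%, CIN 50%, GS 19%); SCV/Mb, EBV load and
  ploidy are generated consistent with it (MSI ⇒ ≥ 20 mut/Mb, EBV ⇒
  load ≥ 1e-3, CIN ⇒ ploidy > 2.5), so subtype inference can be scored
  against truth. The WES-like mode removes human-reads/ploidy/purity
  metadata and halves detection probabilities while quartering depth,
  imitating exome cohorts where a substantial fraction of samples lose
  all taxa after decontamination.

What the generator does **not** emulate: index-hopping between samples,
batch structure in contamination, phylogenetic correlation among taxa,
sub-threshold presence, or compositional closure of the sequencer.
Passing recovery tests on this generator therefore shows the pipeline's
statistics behave as designed under their own assumptions — it does not
certify performance on real cohorts, where contamination is batchy and
taxon abundances are correlated.

# Numerical and reproducibility choices

* Fisher p-values come from the exact hypergeometric tail; all-zero
  margins return 1 (conservative).
* Q-values use the `(m/i)·p` grouping of the BH step-up so that the
  pi0 = 1 case is bit-identical to `p.adjust(method = "BH")`.
* Ties in rank tests use midranks with tie-corrected variances; the
  Wilcoxon test is exact for combined n ≤ 20 without ties.
* PERMANOVA hat matrices are built once per design; permutations act on
  the Gower matrix, giving O(n²) per permutation.
* All randomness is seeded: `simulate_cohort()` restores the caller's
  RNG state, and the pipeline derives per-stage seeds from the master
  seed as `seed·131 + stage` so stages rerun in isolation reproduce
  their in-pipeline results.
* Test problem sizes (80 + 80 samples per cohort and 300 species for
  recovery tests; 500 replicates at n = 60 for the PERMANOVA null; 50
  replicate cohorts at n = 100 for differential-abundance calibration)
  were chosen to give the binomial checks ~1% standard errors while
  keeping the whole suite runnable in a few minutes on one core.

# Known limitations

* The ploidy/purity adjustment assumes a two-population mixture with a
  single tumor ploidy; subclonal ploidy variation is not modelled.
* The curated-route design applies no blood cap (see above); cohorts
  with contaminated curation lists would need the cap extended.
* Differential abundance uses fixed-effects linear models only; repeated
  measures or batch random effects are out of scope.
* The pipeline consumes classifier output; nothing upstream (alignment,
  host depletion, classification) is run or corrected for.
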