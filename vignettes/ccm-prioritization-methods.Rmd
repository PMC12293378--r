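---
title: "Methods: blood chromatin markers, immune signatures, and treatment-interaction survival modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blood chromatin markers, immune signatures, and treatment-interaction survival modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific setting

`ccmsurv` implements an analysis pipeline for relating **chromatin
conformation markers (CCMs)** — binary calls that a specific long-range
chromosomal juxtaposition is detectable in peripheral blood — to tumor
phenotype and overall survival (OS) in a two-arm maintenance-therapy trial
(active drug plus best supportive care, `avelumab_bsc`, versus best
supportive care alone, `bsc`). Each CCM is assayed by nested PCR at three
template concentrations (dilutions 1×, 2×, 4×), so one marker yields three
correlated binary features. The tumor phenotype of interest is a 26-gene
immune expression signature dominated by T/NK-cell genes; each patient
receives a signature score and a hi/lo class from a median split. Tumor
mutation burden (TMB, nonsynonymous SNVs per megabase) enters as an effect
modifier: the core statistical object is the marker × treatment × TMB
three-way interaction in a Cox proportional hazards model for OS.

Patient-level trial data are access-controlled, so the package is built
around a **synthetic cohort generator with known ground truth**, and the
test suite asks whether the pipeline recovers what was planted.

# The generative model

`sim_config()` / `generate_cohort()` simulate:

1. **Marker calls.** Each marker $m$ has a latent per-patient state
   $Z_{im} \sim \mathrm{Bernoulli}(\theta_m)$, with $\theta_m$ drawn
   uniformly from the configured prevalence range (default 0.15–0.75,
   spanning the "<20% to >70%" detection rates seen on real panels). The
   call at dilution $d$ thins the latent state with a detection probability
   $\delta_d$ (default 1, 0.85, 0.70): calls across dilutions are therefore
   correlated but not nested, which reproduces the sign flips across
   dilutions seen in univariate screens of real panels. The detection
   profile need not be monotone in template concentration; the generator
   deliberately asserts neither behavior.
2. **Arms and TMB.** Exactly `arm_fraction` of patients (default one half)
   are randomized to the active arm. TMB is lognormal with the median
   anchored at 7.66 mut/Mb; only the median of the real distribution is
   public, so the log-scale spread (default 0.6) is a realistic choice, not
   a reproduction.
3. **Survival.** Overall survival follows a proportional-hazards model with
   exponential baseline (rate `log(2)/18` per month, i.e. 18-month median
   untreated survival; a Weibull shape is exposed). The linear predictor is
   $$\eta_i = \beta_{trt} T_i + \beta_{tmb} z_i + \sum_m x_{im}\left(
   \beta_m + \beta_{m,trt} T_i + \beta_{m,trt,tmb} T_i z_i \right),$$
   where $T_i$ is the arm indicator, $z_i$ the standardized log TMB, and
   $x_{im}$ the **observed call at the marker's configured causal
   dilution** — so the causal feature is one the downstream screen can see.
   Censoring is independent dropout (exponential, default 0.01/month) plus
   an administrative cutoff (default 48 months), the standard
   non-informative censoring assumption of every Cox model in the pipeline.
4. **Expression.** A latent immune score (standard normal, optionally
   shifted by latent marker states) drives a gene × patient matrix on a
   log2-TPM-like scale; each gene tracks the score at a configured target
   correlation (default 0.6 for the 26 signature genes, 0 otherwise).

Separate RNG streams are used for the marker, survival, and expression
domains, so e.g. enlarging the gene panel never perturbs the survival
draws. One integer seed fully determines the cohort.

**What the generator does not emulate:** assay chemistry and probe-level
noise, linkage between markers, non-proportional hazards, informative
censoring, and covariates such as age or performance status. Passing
recovery tests therefore demonstrates correctness of the statistical
machinery under its stated assumptions, not clinical performance on real
trial data.

# Signature scoring and screening

`score_signature()` computes the per-unit score as the mean of normalized
expression over signature genes. "Normalized" is read as the per-gene
z-score across units (the conventional interpretation; `"none"` is
exposed), which makes scores invariant to affine rescaling of any gene row.
`median_split()` assigns `hi` strictly above the sample median and `lo` at
or below it; the tie convention is exposed because reasonable analyses
differ, but ties-to-lo is the default. `correlate_genes()` reports Pearson
correlations with the score, two-sided p-values from the t transform, and
Benjamini–Hochberg q-values computed per analysis table (not globally).

`univariate_screen()` performs the volcano-style Wilcoxon rank-sum screen of
each (marker, dilution) feature against the score, exact when the smaller
group has ≤ 25 patients and no ties, otherwise normal-approximate with
continuity correction; `contingency_screen()` is the two-sided Fisher exact
analogue against the hi/lo class. BH correction is applied jointly over all
(marker, dilution) features. `select_top_markers()` ranks by q, then
|mean difference|, then feature id. `reduce_panel()` stands in for
multi-algorithm ensemble feature selection with a single documented
procedure — repeated cross-validated sparse logistic classification with
selection-frequency ranking — because no public weighting exists for
combining the original ensemble's components; the input/output contract
(candidate list in, ranked reduced panel plus held-out accuracy out) is
preserved. Binary features enter unscaled ("binary weighting"): rescaling
presence/absence indicators would reweight markers by prevalence.

# The three-step prioritization

**Step 1 — count filter.** A feature is dropped if fewer than 40 patients
fall in either the present or absent category, or fewer than 15 in any of
the four arm × presence subgroups. The filter is a pure recount and is
tested against an independent brute-force recount.

**Step 2 — nested-Cox dilution cascade.** Because the same marker at
different dilutions is highly correlated, at most one dilution per marker
proceeds. For each (marker, dilution), three nested Cox models are fitted
(Efron ties, convergence tolerance 1e-8, max 100 iterations):

* M1: marker;
* M2: marker + treatment + marker:treatment;
* M3: M2 + TMB + marker:TMB + treatment:TMB + marker:treatment:TMB.

M2 and M3 include all lower-order terms (respecting marginality) even
though only the headline terms define the tiers. The Wald p-value of the
highest-order new term is extracted from each model, giving a dilutions ×
{three-way, two-way, main} grid. The dilution with the smallest three-way p
below 0.1 is selected; failing that, the two-way tier, then the main tier;
otherwise the marker is eliminated. Non-convergent fits contribute missing
p-values, which are skipped. TMB enters continuously by default
(`tmb_as = "median_split"` is exposed; published analyses do both).

**Step 3 — elastic-net Cox with CV-frequency hyperparameter choice.** The
surviving features (binary main effects only, unstandardized, no
unpenalized covariates) enter a penalized Cox model over a grid of mixing
values α (default 0.1–1.0 in steps of 0.1) and a per-α path of 50
log-spaced penalties λ down to $10^{-3}\lambda_{max}$. On each of
`n_repeats` random event-stratified 5-fold partitions, the held-out
concordance index (Harrell's C over comparable pairs) is averaged across
folds for every (α, λ). The per-repeat optimal pair is then chosen by a
**one-standard-error rule**: among pairs whose mean CV concordance is
within one standard error (across folds) of the best, the pair whose
full-data path model is sparsest wins, with remaining ties going to the
larger λ and then the larger α. The modal pair across repeats is refitted
on the full data and the nonzero-coefficient features form the selection.

The one-SE rule is a deliberate design choice. A strict argmax of mean CV
concordance is nearly flat in λ below the signal scale, so its location is
driven by cross-validation noise and the procedure returns dense models
even when no feature carries signal. The one-SE convention (standard in
`cv.glmnet` and caret) restores the intended behavior: under a pure-noise
cohort the median selection is empty or near-empty, and under planted
effects the selection concentrates on the planted markers. The strict
argmax is available as `selection_rule = "max"`.

`n_repeats` defaults to 50, a desk-scale working value; production analyses
should use 1000. An empty survivor set at any stage terminates with a
structured status rather than an error.

# Survival summaries and the gene scan

`fit_cox()` wraps `survival::coxph` and reports per-term log hazard ratios,
Wald statistics, and a convergence flag (monotone likelihoods are flagged,
never silently returned). `km_median()` reports the product-limit median
(smallest time with $\hat S(t) \le 0.5$) with a log–log transformed
confidence interval; non-estimable medians propagate as `NA` and are
written as `NE`. `subgroup_table()` produces the 2 arms × 2 TMB strata × 2
marker states table with unadjusted absent-vs-present hazard ratios per
cell; the TMB boundary convention (median into the low stratum) is a flag
because captions in the literature differ and continuous TMB rarely ties at
its median. All models are unadjusted for baseline covariates throughout.

`gene_interaction_scan()` fits, per gene, the full-hierarchy Cox model with
the gene × treatment × TMB term (gene expression and TMB continuous) and
excludes genes expressed in ≤ 50% of samples **or** with a coefficient of
variation ≤ 5% (SD/mean × 100 on the supplied expression scale). The
exclusion form with "or" is implemented because it is operationally
unambiguous; both the fraction and CV boundaries are exclusive-at-equality
by construction and are boundary-tested.

# Interval annotation

`closest_genes()` maps a marker interval to all overlapping protein-coding
genes (`within`) and the nearest non-overlapping gene on each side, with
the gap measured in bases strictly between the features and distance ties
broken by symbol. Strand is ignored: upstream/downstream are coordinate
conventions, not transcription direction — the behavior of the standard
closest-interval tooling this mirrors. `validate_ccm_span()` enforces the
plausibility window for long-range interactions, 10 kb ≤ distance < 300 kb,
with distance measured midpoint-to-midpoint (the reference point is not
standardized in the field, so the convention is recorded in the output).
`multi_coverage()` counts distinct markers per gene and the fraction of
genes covered by more than one marker. File coordinates are 1-based
inclusive (BED input is converted on read by `rtracklayer`).

# Numerical choices and degenerate inputs

* Wilcoxon exactness threshold: smaller group ≤ 25 and no ties.
* Fisher two-sided p: sum of hypergeometric probabilities ≤ observed.
* Cox ties: Efron approximation everywhere.
* Screen features with an empty group, contingency tables with a degenerate
  margin, constant genes, single regions in spot aggregation, and empty
  marker-gene maps are all flagged and excluded from downstream
  adjustment, never silently dropped.
* All-identical signature scores collapse to the tie class with a warning.
* Writers are locale-independent; `NE` is reserved for non-estimable
  medians and empty fields for other missingness.

# Problem sizes used by the test suite

The suite runs at desk scale, chosen so the whole battery completes on one
CPU in well under half an hour: calibration of the three-way Wald test uses
500 replicates of 500-patient null cohorts against a 99% binomial band
around 0.05; end-to-end recovery uses 20 cohorts of 2,000 patients with 25
markers × 3 dilutions, three planted markers (main log-HR ±0.8 plus
three-way ±1.0 at dilution 1×, prevalence 0.45), 50 CV repeats, an α grid
of {0.5, 1.0} and 30-λ paths; oracle-equivalence checks use exhaustive
enumeration (all 3-vs-3 rank splits; the full $4^9$ cascade p-grid) and
1,000 random intervals against an exhaustive gene scan. Recovery is
asserted at the marker level: dilution calls are correlated by
construction, so the argmin-p dilution is not identifiable with certainty;
a separate test with a sharply attenuated detection profile (1, 0.45,
0.25) asserts recovery at the exact generative dilution.

# Known limitations

* The elastic net models marker main effects only; a marker whose sole
  effect is a pure three-way interaction with balanced modifiers has no
  marginal prognostic signal and cannot survive step 3. The cascade ranks
  such markers, but the final selection requires marginal signal.
* Real panels may violate the thinned-latent-state dilution model (e.g.
  concentration-dependent artifacts), and real cohorts violate
  proportional hazards over long follow-up; neither is modeled.
* The BH multiplicity universe is per analysis table; joint control across
  tables is not attempted.
* The stability-selection panel reducer is a stand-in with its own
  operating characteristics; its held-out accuracy is not comparable to
  published ensemble accuracies.
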