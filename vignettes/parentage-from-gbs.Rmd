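---
title: "Parentage assignment from low-depth GBS data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parentage assignment from low-depth GBS data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbsparent)
```

## The problem

Genotyping-by-sequencing (GBS) delivers per-SNP reference/alternate read
counts at low, variable depth. At depth $k$ a true heterozygote shows only
one of its two alleles with non-negligible probability, so apparent
genotypes are biased towards homozygosity and classical exclusion-based
parentage analysis — "a true parent never opposes its offspring
homozygously" — breaks down: even true parents accumulate apparent
Mendelian mismatches. Filtering to high-depth calls throws away most of the
data. gbsparent instead models the read-sampling process and works with
*all* reads.

## Apparent genotypes and the no-call probability K

Homozygotes are assumed to be read without error (sequencing-error models
are out of scope; see Limitations). For a true heterozygote read at depth
$k$, let $K(k)$ be the probability that only reference (equivalently, only
alternate) alleles are seen, so the apparent genotype distribution is

$$P(\mathrm{AA}^* \mid \mathrm{AB}) = P(\mathrm{BB}^* \mid \mathrm{AB}) = K, \qquad
  P(\mathrm{AB}^* \mid \mathrm{AB}) = 1 - 2K.$$

Three families of $K(k)$ are supported (`read_model()`):

* **binomial** — fair independent reads, $K = 1/2^k$;
* **beta-binomial** — a per-site read probability drawn from
  $\mathrm{Beta}(\alpha,\alpha)$ before binomial sampling, capturing hidden
  clustering of the alleles recruited for sequencing (PCR "stacking",
  reagent imbalance): $K = \Gamma(k+\alpha)\,\Gamma(2\alpha) /
  (\Gamma(k+2\alpha)\,\Gamma(\alpha))$, evaluated in log-gamma space;
* **modified-p** — reads form a Markov chain: the first read is fair and
  each later read repeats the previous allele with probability $p'$, giving
  $K = \tfrac12 p'^{\,k-1}$.

All three are symmetric in the alleles and give $K(1) = 1/2$; the
beta-binomial tends to the binomial as $\alpha \to \infty$ and the
modified-p recovers it at $p' = 1/2$. Depths are looked up in a precomputed
table (cap 500, beyond which the closed form is evaluated directly); this
changes nothing numerically and matters only for speed of all-pair scans.

## Expected mismatch rates and the EMM

For a putative parent-offspring pair, an apparent mismatch is a pair of
opposing apparent homozygotes; an apparent heterozygote can never mismatch
a single parent. For a trio it is any apparent triple that would be
Mendelian-impossible read at face value: opposing homozygosity between
offspring and either parent, an apparently heterozygous offspring with both
parents apparently homozygous for the same allele, or an apparently
homozygous offspring from apparently opposite homozygous parents.

Under Hardy-Weinberg equilibrium with known reference-allele frequency $p$,
random mating and non-inbred parents, the probability of an apparent
mismatch for the *true* parent(s), conditional on the offspring's apparent
class and all members' actual depths, has closed forms implemented in
`expected_mismatch_pair()` and `expected_mismatch_trio()` (the BB\* case is
the AA\* case with $p \mapsto 1-p$). These closed forms are verified in the
test suite against exhaustive enumeration over all true-genotype
combinations and observation outcomes, to $10^{-12}$.

The **excess mismatch rate** (EMM) of a putative pair or trio is the
observed mismatch rate minus the mean of these conditional probabilities,
both computed over exactly the same SNP set (polymorphic, all members with
at least one read). Mixing the two sets would bias the EMM, which is why
`pair_mismatch_stats()`/`trio_mismatch_stats()` compute both sides jointly.
For true parentage the EMM is centred at zero *when the read model matches
the data*; for wrong parents it is clearly positive. It may legitimately be
slightly negative.

## Relatedness and the depth-corrected diagonal

Candidate parents are ranked by the frequency-standardised cross-product
estimator

$$\hat r_{ij} = \frac{\sum_s (g_{is} - 2p_s)(g_{js} - 2p_s)}
                   {\sum_s 2 p_s (1 - p_s)},$$

summed over each pair's shared non-missing polymorphic SNPs, with the
denominator over that same set (pair-specific denominators keep the
estimator unbiased under arbitrary missingness). Because the apparent
dosage is unbiased for the true dosage under any symmetric read model, the
off-diagonal does not involve $K$ at all — it is *bitwise identical* across
read-model families, and is unbiased for pedigree relatedness at any depth.

The diagonal ($1 + F$) is different: a heterozygote observed as homozygous
inflates $(g - 2p)^2$ by $2K$ in expectation. Subtracting $2K/(1-2K)$ from
every *apparent* heterozygote cell (which triggers with probability $1-2K$
per true heterozygote) removes exactly that inflation without assuming
Hardy-Weinberg proportions for the individual. At $k = 1$, $K = 1/2$: the
correction is undefined and the cell carries no heterozygosity signal, so
only cells with $k \ge 2$ enter the diagonal. Individuals with no such
cells get a flagged `NA`.

A principal-components decomposition of the resulting genomic relatedness
matrix (`grm_pca()`; the matrix is column-centred and decomposed with
`prcomp`) is the diagnostic for population structure — a dominant first
component separating subpopulations signals that per-subpopulation allele
frequencies are worth using.

## The assignment strategy

Per offspring (`assign_parentage()`):

1. rank candidate fathers by $\hat r$;
2. rank candidate mothers likewise;
3. veto a best candidate with $\hat r < 0.4$ or pair EMM $> 0.01$;
4. if the runner-up is within 0.05 of the best, resample SNPs with
   replacement (1000 replicates, frequencies held fixed) and require the
   best to stay ahead in at least 99% of replicates;
5. check the combined trio: trio EMM $\le 0.02$ and
   $r_{FM} - 2 F_O \le 0.2$.

All comparisons are inclusive at the boundary (a convention the package
fixes deliberately and tests). The trio EMM ceiling is looser than the pair
ceiling because any of three genotypes can contribute an error. The
inbreeding check is one-sided: for a true trio the offspring's inbreeding
equals half the parents' relatedness, and the damaging error mode — a close
relative of one true parent standing in for the other parent — produces a
large *positive* $r_{FM} - 2F_O$; low values are not penalised. When the
offspring's inbreeding is undefined (no $k \ge 2$ cells) the check is
skipped with a warning.

If the best pair fails a trio check, combinations of the top two candidates
per sex are searched; each member must still pass the pair-level
thresholds, and the passing combination with the lowest trio EMM is
assigned (code `A`). Decision codes: `Y` both parents assigned, `A`
alternate pair assigned, `E`/`I` trio rejected (EMM / inbreeding) with no
rescue, `F`/`M` father/mother only, `N` neither. A failed trio with both
parents individually acceptable yields `E`/`I` rather than a single-parent
fallback: the trio failure cannot identify *which* parent is wrong, so
assigning one of them anyway would be a guess. One individual topping both
candidate sets cannot form a pair with itself; offspring are never compared
against themselves. Ties in ranking are flagged and broken by candidate id
for determinism. "Best" is defined by relatedness with the EMM as a veto
(relatedness is ~10x cheaper to compute for all pairs, and EMM is only
evaluated for the top candidates per sex); `rank_by = "emm"` flips to
EMM-primary ranking with relatedness as the veto, computing pair EMMs for
every candidate — the SNP bootstrap, a relatedness-resampling device, is
not applied in that mode.

Single-sex mode (`sexes = "sire"` or `"dam"`) skips every trio-level step.
Verification mode (`mode = "verify"`) restricts each offspring's candidate
sets to its recorded parents and produces the same metrics as assignment
mode would on those single-candidate sets (tested).

## Estimating overdispersion

On real GBS data the raw mismatch rates of even clearly-true trios sit
above binomial expectations, roughly linearly — the signature of clustered
allele sampling. `fit_dispersion()` takes trios accepted under the binomial
model (the conservative choice, since binomial $K$ is smallest) and
minimises the sum of squared deviations of raw from expected trio mismatch
rates over the model parameter, using `stats::optimize` — on a log scale
over $\alpha \in [0.1, 10^6]$ for the beta-binomial, and over
$p' \in [0.5, 0.999]$ for the modified-p (brackets chosen to include
binomial-limit behaviour; an optimum at the bracket edge is flagged, and on
binomial-like data the beta-binomial objective is flat in large $\alpha$, so
only the fitted $K$ curve — not the parameter value — is meaningful there).
Only $K(k)$ changes with the parameter, so each trio's per-SNP
(frequency, depths, offspring class) data are cached once and re-scored per
candidate value. `compare_families()` fits both families and recommends the
smaller objective. Refitting with the fitted model re-centres accepted-trio
EMMs near zero, which is what licenses tighter EMM thresholds.

## The simulator

`sim_config()`/`simulate_parentage_data()` generate a two-generation herd:
unrelated founders drawn from Hardy-Weinberg proportions (optional founder
inbreeding $F$, used for the $1+F$ recovery tests; optional subpopulation
divergence via a Balding-Nichols-style Beta perturbation of founder
frequencies), offspring receiving one uniformly-chosen allele per parent,
and per-cell depths Poisson with configurable mean (depth 0 = missing).
Heterozygote reads follow the configured family; the modified-p generator
simulates the read chain sequentially and never touches the analytic
$K$, so the generator and `k_probability()` cross-check each other — a core
test of the package.

Defaults (3,000 SNPs, 20 sires, 200 dams, 300 offspring, frequencies
uniform on $[0.05, 0.95]$, depth mean 3) emulate a single-season livestock
herd genotyped by low-cost GBS. What the simulator deliberately does *not*
reproduce: linkage between SNPs (all SNPs independent), sequencing error in
homozygotes, the low-MAF-heavy frequency spectrum of real GBS panels,
per-sample depth variation, and relatedness structure among founders.
Passing tests therefore demonstrate correctness of the estimators and
decision logic under the stated model, not robustness to those real-data
features.

## Numerical and design notes

* **Known vs estimated frequencies.** The theory treats allele frequencies
  as known. The unbiasedness tests (parent-offspring $\hat r \to 0.5$,
  EMM $\to 0$, $1+\hat F \to 1$) therefore evaluate the estimators at the
  generator's true frequencies; with frequencies estimated from the sample
  itself, the estimates acquire a small finite-sample bias (relatedness
  shrinks slightly towards zero; the EMM acquires a small positive offset).
  Operational runs estimate frequencies from read counts over the relevant
  group — the same estimate is used everywhere, including the
  Hardy-Weinberg filter.
* **SNP filtering.** SNPs with Hardy-Weinberg disequilibrium (observed
  reference-homozygote frequency minus $p^2$) strictly below $-0.05$ are
  removed — at high depth these are predominantly collapsed duplicated loci
  (see `plot_fin()`). Monomorphic SNPs are discarded (`maf_min = 0`,
  exclusive), and SNPs at $p \in \{0,1\}$ are excluded from every
  relatedness and mismatch sum regardless, since they contribute degenerate
  $0/0$ terms.
* **Problem sizes.** The validation suite uses 1,000–10,000 SNPs and tens
  to hundreds of individuals — large enough that Monte-Carlo standard
  errors make the 3-SE checks meaningful, small enough to run in minutes on
  one core. The dispersion-recovery checks use the scale at which the
  approach is intended to operate (50 trios x 10,000 SNPs).
* **Determinism.** Every stochastic entry point takes a mandatory seed; the
  bootstrap derives one stream per offspring from it, so results do not
  depend on evaluation order, and reruns are byte-identical.
* **Per-subpopulation mode.** `run_pipeline(freq_mode =
  "per_subpopulation")` re-estimates frequencies within each subpopulation,
  re-applies the zero-MAF discard there, and analyses each subpopulation
  separately. On simulated diverged herds, offspring assigned in both modes
  receive the same parents — consistent with combined-vs-separate analyses
  agreeing on best matches even when the relatedness *values* differ.

## Limitations

Sequencing error (miscalled bases) is not modelled: an error in a deep
homozygote produces an apparent heterozygote, which the current model
cannot generate. No likelihood-based relationship classification is
attempted; thresholds are set by inspection of the metric distributions
(`metric_distributions()`), not inferred. Relatedness is reported relative
to the allele-frequency base population, and no rescaling transformation is
provided; with strongly structured data, per-subpopulation frequencies are
the supported remedy. The EMM thresholds shipped as defaults were chosen
for panels of tens of thousands of SNPs; with only a few thousand SNPs the
EMM standard deviation (~$0.006$ at 3,000 SNPs, depth 2) approaches the
0.01 default ceiling, and a proportion of true parents will be vetoed by
counting noise — the metric distributions should guide looser choices
there.
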