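---
title: "Penetrance estimation under family ascertainment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penetrance estimation under family ascertainment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascpen)
library(dplyr)
library(tidyr)
```

## The problem

A very rare candidate variant (the *variant of interest*, VOI) is found in
a handful of small families segregating a dominant disease. Clinicians
want its penetrance — the probability that a carrier develops disease —
both to classify the variant and to counsel relatives identified by
cascade testing. But the families were not sampled at random: they were
*ascertained* because they contained affected carriers. Unless the
sampling process is modelled, penetrance estimates computed from such
families are biased, sometimes drastically so.

`ascpen` provides the pieces needed to study and correct this bias in
sibship (nuclear-family) data: a simulator for ascertained sibships, the
counting estimators with and without the classical single-ascertainment
correction, exact enumeration of their expectations, a likelihood-based
estimator built on the LOD score with linkage disequilibrium (the
LD-MOD), and co-segregation evidence statistics (LE-LOD(max) and a
proband-conditioned Bayes factor).

## Generating model

Each simulated family has one marker-heterozygous parent (`Vv`) and one
non-carrier parent (`vv`); for a very rare variant, matings with two
carrier parents can be neglected. Each of `s` sibs independently inherits
the variant with probability 1/2. Phenotypes follow an independent-causes
model with two parameters:

* `f` — the *attributable* penetrance: the probability that the variant
  itself causes disease in a carrier;
* `gamma` — the combined penetrance of all other causes, effectively the
  population prevalence (the phenocopy rate).

A carrier is affected with probability
`beta = gamma + f - gamma * f`, a non-carrier with probability `gamma`.
Parents' phenotypes are always treated as unknown; their marker genotypes
are known to the likelihood machinery but hidden from the counting
estimators.

## Ascertainment: the k-model

Let `r` be the number of *qualifying individuals* (QIs: carrier **and**
affected) among the sibs and `t` the number of affected sibs. A sibship
enters the study with probability

```
P(ascertained | r, t) = c * (r^k + t)   for r >= 1,   0 otherwise
```

`k = 1` is classical single ascertainment (recruitment proportional to
the number of QIs), `k = 0` complete/truncate ascertainment, `k = 2`
models over-recruitment of multiplex families, and `k = -1`
under-recruitment. The `+ t` term lets recruitment respond to affected
sibs whose carrier status is not yet known. The normalizing constant `c`
is computed by brute force over the attainable pairs `1 <= r <= t <= s`
(`normalizing_constant()`); for negative `k` the maximizing cell is not
`(s, s)`, which is why enumeration rather than a closed form is used.
The simulator realizes this distribution by rejection sampling
(simulate-then-accept), which is exact for any `k` without algebra, and
then designates a proband drawn uniformly at random among the family's
QIs — the sampling story never says *which* QI brought the family in, and
a fresh uniform draw avoids birth-order artifacts.

The null-hypothesis generator (`null = TRUE`) keeps marker transmission
and the QI-based ascertainment rule but drives phenotypes from an
unlinked causal locus heterozygous in the marker-carrier parent, with the
same `f` and `gamma`. Because unlinked transmissions are independent,
which parent carries the causal allele does not affect the within-family
marker–phenotype association; placing it in the carrier parent mirrors
the scenario "the VOI is neutral but another familial cause segregates".

## Counting estimators

`f_tilde_star()` is the naive estimate: the proportion of affected
individuals among carrier sibs, proband included. Every ascertained
family contains at least one QI, so for `s = 2` the per-family proportion
is at least 1/2 — the estimator cannot fall below `1/s` no matter how
small `f` is.

`f_tilde()` applies the classical single-ascertainment correction: drop
the proband, then score the remaining carriers. Families whose only
carrier was the proband cannot be scored and are excluded (the returned
counts make this visible). The estimator is exactly unbiased at `k = 1`
with `gamma = 0` and biased under every other `k` — which is the point:
the correction is only as good as the ascertainment assumption behind it.

Both estimators average per-family proportions across families.
Pooling individuals across families is exposed via `pooled = TRUE` for
comparison, but per-family averaging is the default because it is the
variant whose expectations form the reference k-sweep
(0.60/0.50/0.43/0.38 for `f_tilde` and 0.89/0.88/0.87/0.86 for
`f_tilde_star` at `f = 0.5`, `gamma = 0`, `s = 2`, `k = 2, 1, 0, -1`),
as `expected_estimates_exact()` verifies.

`expected_estimates_exact()` is the package's own oracle: it enumerates
all per-sib configurations (by their multinomial counts, so `s` up to 12
is instant), weights each by its generating probability times
`(r^k + t) * [r >= 1]`, and renormalizes. Dropping any uniformly chosen
QI removes exactly one affected carrier, so the proband draw does not
change the `f_tilde` value of a configuration — the expectation only
needs renormalization over configurations that retain a carrier.

## The two-locus likelihood and the LD-MOD

The analysis model treats the VOI as a marker locus and posits a disease
locus with allele frequency `q`, linkage disequilibrium `D'` and
recombination `theta` relative to the marker, penetrances
`(f_DD, f_Dd, f_dd)`, and Smith's admixture parameter `alpha` (the
probability that a family is of the linked type). The default structural
model — `p = q = 0.001`, `D' = 1`, `theta = 0` — says: the variant *is*
the disease allele, if it is anything at all.

`family_likelihood()` computes
`P(sib markers, sib phenotypes | parental markers)` exactly, summing over
parental diplotypes (founder haplotype frequencies from `p`, `q`, `D'`),
Mendelian transmission with recombination, and penetrance factors for the
sibs. All LOD-type statistics then **condition on the phenotype data**:
each mixture component is used in the form
`P(markers | phenotypes, parental markers)`. This conditioning is the
"ascertainment assumption free" correction — whatever unsystematic
process selected the phenotypes, it cancels from the likelihood ratio.
The LD-LOD compares the admixed LD model against the no-linkage/no-LD
null (`theta = 0.5` **and** `D' = 0`, same penetrances); the null is
bundled this way because the alternative bundles linkage and LD, and the
null simulator generates exactly that joint null.

`maximize_ld_lod()` maximizes the LD-LOD over
`(f_DD, f_Dd, f_dd, alpha)` in the unit box. The maximized value is the
LD-MOD and the maximizing `f_Dd` is the penetrance estimate `f_hat`.
`f_hat` is reported raw — not reduced by `gamma` — because at high
phenocopy rates it genuinely covers disease among carriers from all
causes. Numerics:

* distinct family configurations are collapsed and counted first
  (`s = 2` has at most four ascertainable configurations), so the cost of
  a likelihood evaluation is independent of the number of families;
* a coarse grid (step 0.05 on `f_Dd`, `f_dd`, `alpha`) is scanned with
  `f_DD` tied to `f_Dd` — with `q = 0.001`, homozygous-carrier offspring
  have probability of order `q^2`, so `f_DD` is essentially unidentified
  and tying it costs nothing while cutting the grid by a factor of 21;
* box-constrained local refinement (`optim(method = "L-BFGS-B")`) then
  frees all four parameters from the best grid point. Grid ties resolve
  toward the smaller `f_Dd`; zero-probability likelihoods are clamped so
  the refiner never sees a non-finite objective; if refinement fails the
  best grid point is returned and flagged.

## Co-segregation evidence: LE-LOD(max) and the TBF

The LD-MOD itself overstates co-segregation evidence because
ascertainment guaranteed the variant is present. With parental marker
genotypes fixed, LD carries no information beyond the parental haplotype
coupling, so the linkage-equilibrium LOD (`le_lod()`, numerator
`D' = 0`, `theta` retained) isolates the within-family co-segregation
signal. Evaluating it at the LD-MOD's maximizing model gives
LE-LOD(max) (`le_lod_max()`), the recommended evidence statistic.

The Thompson-style Bayes factor (`tbf()`) adds a single-ascertainment
adjustment to the LD-LOD. Its published form lives in earlier work; here
it is operationalized as the standard proband-conditioning correction:
each family's likelihood ratio is divided by the same ratio computed on
the proband alone (as a one-sib family, conditional on parental
markers), making

```
tbf = ld_lod(all data) - ld_lod(probands only)
```

an exact identity and forcing the statistic to zero on one-child
sibships, where the full data are the proband data. `tbf_gen()`
evaluates it at the generating penetrances (`f_Dd = beta`,
`f_dd = gamma`, `alpha = 1`); `maximize_tbf()` maximizes it — not
because that is a good estimator, but to demonstrate that it is not:
unlike the LD-MOD, the proband-conditioned statistic does not inherit a
valid ascertainment correction for estimation, and its maximizing
`f_Dd` is badly inflated whenever phenocopies are present.

## Simulation study sizes

The replicate experiments follow the reference design: 1,000 replicates
per generating condition, `s = 2`, with dataset sizes `N` of 10–50
families for the sampling-variability and evidence-threshold studies,
`N = 20` for small-sample bias, and `N = 1000` for the large-sample
estimator contrast. For the k-sweep of the counting estimators the
replicate size is not pinned down by the enumeration (which is `N`-free);
the package uses `N = 50` as a realistic multi-centre collection and
reports the enumeration value alongside. The large-`N` contrast runs 100
replicates with configuration caching; cross-replicate means there have
Monte-Carlo standard errors a few thousandths wide, ample for the
contrast being demonstrated. Per-replicate seeds are drawn up front from
the master seed, so any cell can be reproduced in isolation.

```{r ksweep, eval = FALSE}
# exact k-sweep (instant) and its simulated counterpart
sapply(c(2, 1, 0, -1), function(k) {
  e <- expected_estimates_exact(trait_model(0.5, 0),
                                ascertainment_model(k, s = 2))
  e$expectation
})
res <- run_replicates(crossing(f = 0.5, gamma = 0, k = c(2, 1, 0, -1),
                               n_families = 50),
                      n_replicates = 1000, seed = 1)
summarize_replicates(res)
```

## What the generator does and does not emulate

The simulator realizes the stated study conditions exactly: fixed
sibship size, one carrier parent, independent-causes phenotypes, k-model
recruitment, a uniformly chosen QI proband. Real collections violate
most of these in ways the package deliberately does not model: variable
sibship sizes and deeper pedigrees (approximated only by taking `s`
large), age-dependent penetrance and censoring, phenotype
misclassification, de novo events, two-carrier matings, and recruitment
that depends on features other than `(r, t)`. Passing the simulation
checks therefore shows that the estimators behave as claimed *under the
stated ascertainment models*, not that any particular real dataset is
free of additional biases.

## Known limitations

* Likelihoods cover nuclear families only — no Elston–Stewart peeling
  over arbitrary pedigrees, no multipoint markers.
* The carrier/non-carrier representation excludes marker-homozygous
  sibs; `read_ped()` rejects them rather than silently mis-scoring.
* `f_DD` is reported but weakly identified under the default rare-allele
  structural model.
* The TBF here is one defensible operationalization of a
  proband-conditioned Bayes factor; analyses that depend on the exact
  published variant should treat it as closely related, not identical.
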