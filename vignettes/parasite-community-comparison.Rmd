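---
title: "Comparing parasite communities across ecosystems: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing parasite communities across ecosystems: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paradiv)
```

`paradiv` compares metazoan parasite communities recovered by whole-host
dissection across ecosystems. This vignette explains the statistical
machinery, the assumptions each step makes, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the design
choices taken where the methodology was genuinely open.

## The data model

A dissection dataset is three linked tables. One row per dissected **host
individual** (species, one of four host groups — crustacean, fish, mollusk,
polychaete — ecosystem, site, optional date and body length in millimetres);
one row per **parasite observation** (host individual, morphogroup, count
≥ 1; absence is the absence of a row, so uninfected hosts are ordinary host
rows with no observations); one row per **morphogroup annotation** (taxon
among the eight focal metazoan groups, life cycle `DLC`/`ILC`, life stage,
and an optional `redundancy_group` linking stages that may belong to one
biological species). A morphogroup is an operationally distinct morphotype
treated as a species-level unit; identities are opaque strings, and no
synonymy is resolved beyond the redundancy annotation — matching life stages
across partitions is taxonomic work that belongs in the data, not in code.
Every transformation appends to a provenance log, so a harmonized dataset
records the exact filter sequence that produced it.

## Harmonization

Datasets collected by different campaigns become comparable through a fixed
inclusion protocol, applied in a fixed order: restrict to the four host
groups, restrict observations to the eight focal parasite taxa, then keep
host species with at least `min_individuals = 10` dissected individuals —
counting all dissected individuals, infected or not, because uninfected
hosts inform both prevalence and the Chao2 sampling-unit count. The order is
documented even though taxon removal cannot change individual counts.
A host species' group membership must be unanimous across its records;
conflicts are validation errors, not majority votes.

Cross-species analyses run separately on fish and invertebrate partitions.
Within a partition, when two or more observed morphogroups share a
`redundancy_group` (say, an adult trematode and its metacercaria), all but
one are dropped: the adult if present, otherwise the lexicographically first
morphogroup id. The tie-break is arbitrary but deterministic — the
alternative, dropping "potentially redundant" stages by judgement, is not
reproducible. Redundancy removal looks only at morphogroups actually
observed in the partition, so a metacercaria whose adult occurs only in fish
is retained in the invertebrate partition.

## Richness within host species: Chao2

For each host species, the incidence matrix has dissected individuals as
rows and morphogroups as columns; counts are reduced to presence. With
$S_{obs}$ observed morphogroups, $Q_1$ singletons (seen in exactly one
individual) and $Q_2$ doubletons, the estimator is

$$\hat S_{bc} = S_{obs} + \frac{Q_1 (Q_1 - 1)}{2 (Q_2 + 1)}
\qquad\text{(bias-corrected, the default)}$$

$$\hat S_{classic} = S_{obs} + \frac{Q_1^2}{2 Q_2},$$

the classic form falling back to the bias-corrected term when $Q_2 = 0$
(the standard Chao convention). Both variants are exposed and recorded in
output because the literature's software implementations differ in which
they report. The small-sample factor $(m-1)/m$ is off by default and
available as an option; with it and the classic variant, the estimator
matches `vegan::specpool()`'s incidence-based Chao estimate exactly, which
the test suite uses as an independent cross-check. A host species with no
infections has $\hat S = 0$ — a valid estimate, not an error. Chao2 is a
lower-bound-type estimator: it corrects the dependence of observed richness
on the number of individuals examined but still assumes detections are
exchangeable across individuals; strongly aggregated infections inflate
$Q_1$ and the correction (the generator's `aggregation` parameter exists to
stress exactly this).

## Richness across host species: accumulation curves

With $H$ host species and parasite $i$ occupying $h_i$ of them, the expected
richness in a uniform random subset of $k$ species is

$$E[S(k)] = \sum_i \left( 1 - \binom{H - h_i}{k} \Big/ \binom{H}{k} \right),$$

the hypergeometric (sample-based rarefaction) expectation. Binomial ratios
are evaluated as `exp(lchoose(H - h, k) - lchoose(H, k))`, stable for $H$
well beyond $10^3$. An exhaustive-enumeration oracle
(`accumulation_oracle()`, guarded at $10^5$ subsets) exists solely to verify
the closed form; the suite asserts agreement to $10^{-9}$ together with
monotonicity and concavity in $k$. No extrapolation beyond $H$ is offered.
A closed-form curve variance is not implemented; on request the curve
carries a Monte-Carlo variance from resampled $k$-subsets, seeded and
labelled `monte_carlo` so it cannot be mistaken for an analytic quantity.

## The ordered ecosystem test

The scientific hypothesis is ordered — under island-biogeography reasoning,
within-host-species richness should run vent < atoll sandflat < kelp forest
— so the test encodes the ordering directly instead of an omnibus
comparison. The model is a rank ANCOVA: the midrank of the per-species Chao2
estimate is regressed by least squares on host-group reference-cell
contrasts, the midrank of mean host species length (body size is a known
driver of parasite richness), and an **ordered score** (equally spaced
integers 1, 2, 3 along the hypothesized ordering; any strictly monotone
named vector is accepted). The statistic $t_{obs}$ is the coefficient on the
score — the simplest statistic consistent with an ordered alternative; it is
invariant to the choice of reference group (asserted in tests). Both the
full-model $R^2$ and the $R^2$ without the score are reported, since either
may be the figure a reader wants.

No distributional claim is attached to the least-squares fit. Significance
comes from randomizing the assignment of species to ecosystems **within
host groups**: each permutation shuffles ecosystem labels among the species
of a group, preserving per-group label multiplicities, and refits. The
implementation uses the Frisch–Waugh reduction (the non-score design block
is fixed across permutations), making $10^4$ randomizations on a hundred
species essentially free. The one-sided p-value is the add-one estimator
$(1 + \#\{t^* \ge t_{obs}\})/(B+1)$, never exactly zero, with ties counted
as exceedances (conservative). Default $B = 9999$; the seed is mandatory,
and the null distribution is bit-reproducible from it. A full cross-group
permutation is available (`stratified = FALSE`) as a sensitivity analysis.
Species lacking a length measurement are excluded with a warning rather than
imputed — imputation would inject an untestable assumption into a
nonparametric procedure.

The permutation p-value is exact under exchangeability of species within
host groups. Two real-data caveats follow. First, per-species sample sizes
differ between ecosystems, so the Chao2 sampling distributions are not
identical even absent a true ecosystem effect; the rank transform blunts
but does not eliminate this. Second, species in one ecosystem share a
parasite pool, which correlates their richness values; see the calibration
discussion below.

## Composition tests

Two contingency analyses count **distinct morphogroups** (once per ecosystem
in which they are observed, a convention that matters only for synthetic
inputs since real morphogroups do not span ecosystems):

* **Life cycle** — a 2 × E table of direct- vs indirect-life-cycle
  morphogroup counts, built from the redundancy-filtered partition so two
  stages of one species are not double-counted.
* **Life stage** — a 5 × E table by stage category, built from the
  *unfiltered* partition: here the question is precisely which stages an
  ecosystem's hosts harbour, so all intermediate morphotypes are kept. The
  asymmetry with the life-cycle analysis is deliberate.

Stage categories are configuration, not code. Defaults: for fish hosts
{adult, cystacanth, larval nematode, metacestode, metacercaria}; for
invertebrate hosts the trematode intermediate stages (metacercaria,
sporocyst) are pooled into one category. Both defaults give five categories,
hence df = (5−1)(3−1) = 8 for a three-ecosystem comparison; the exact
invertebrate category membership is an assumption flagged as such and
freely reconfigurable.

The test is the standard Pearson χ² of homogeneity without continuity
correction (delegated to `stats::chisq.test(correct = FALSE)` behind the
package's interface). Low expected cells set a flag rather than triggering a
method switch — the analysis stays what it says it is. All-zero rows or
columns are refused with instructions to collapse; `run_full_pipeline()`
follows that instruction itself by dropping categories unobserved in every
ecosystem before testing.

## The synthetic-data generator

`sim_config()` describes a complete multi-ecosystem dissection study. Its
defaults are the study conditions the package targets: ecosystems vent,
atoll, kelp (hypothesized low → high richness); host species and individual
counts per group matching the published sampling margins (28/44/28 host
species; 2134/2637/678 individuals, distributed deterministically across
species); a 33-morphogroup per-ecosystem pool spanning all eight taxa with a
trematode-heavy composition; per-individual detection probability 0.08 (a
typical dissection prevalence); host-specificity breadth 2 (most metazoan
parasites use one or two host species per stage); species mean lengths
lognormal around per-group medians (fish 150 mm, crustaceans 40 mm,
mollusks 30 mm, polychaetes 25 mm); and a moderate ordered effect 0.4.
Plausibility constraints route stages to hosts: adult ILC helminths and
monogeneans mature in fish; encysted intermediate stages sit in prey
(invertebrates or fish); sporocysts in gastropods; rhizocephalans in
crustaceans; copepods anywhere.

Given the pool, each compatible host individual is an independent Bernoulli
detection; counts given detection are `1 + Poisson(1)` — arbitrary but
fixed, since nothing downstream consumes abundance. The ordered effect
multiplies pool sizes and detection probabilities by
$(1+\text{effect})^{s - \bar s}$ along the ecosystem ordering;
`null_scenario()` sets the effect to zero *and* copies the first ecosystem's
host structure to all ecosystems, making simulated ecosystems exchangeable
up to labels. Options exist for host-level aggregation (gamma susceptibility
multipliers), a length–richness linkage, and redundancy clusters (adult
trematodes linked to their metacercariae/sporocyst).

What the generator does **not** emulate: spatial structure among sites,
temporal trends, phylogenetic signal in host use, abundance dynamics,
between-morphogroup interactions, and observer error in morphogroup
assignment. Passing calibration and power checks on synthetic data
therefore validates the *inferential machinery* under the stated sampling
model, not the field protocol.

## Calibration and power: regimes and sizes

Two structurally different configurations drive the replicated simulation
studies, and the distinction is statistical, not cosmetic.

With a **fixed shared pool** (the realistic default), the species of one
ecosystem compete for a fixed number of morphogroup–host slots: one
species' gain is another's loss, ecosystem totals are nearly ancillary, and
the observed ordered statistic varies *less* across datasets than across
within-group relabelings. The stratified permutation test is then
conservative — a genuine property of applying a species-exchangeability
randomization to pool-structured communities, worth knowing when
interpreting non-significant results on real data.

Calibration of the machinery itself therefore uses `compact_sim_config()`:
three ecosystems × two host groups × 5 species × 12 individuals, with
**Poisson-distributed pool sizes** and **single-host specificity**. In that
regime each species' parasite assemblage is an independent thinned-Poisson
draw, species are iid within groups, and the permutation null is exact; the
suite requires the empirical rejection rate at α = 0.05 over 1000 replicate
null datasets (B = 199) to fall in the exact binomial 99% interval.
Analogously, `composition_calibration_config()` gives each life-cycle ×
ecosystem cell an independent Poisson count with expectation well above 5
(pool means 120/180, detection 0.012) — the sampling model under which the
χ² p-value is asymptotically uniform, checked by Kolmogorov–Smirnov at the
0.01 level.

Power uses the default (fixed-pool, paper-scale) configuration at ordered
effects 0.1, 0.25 and 0.5 with 60 replicates each and shared seeds across
levels: rejection must be monotone in the effect and exceed 0.9 at the
largest setting. These problem sizes — 1000 calibration replicates, 60 power
replicates, B = 199 within replicates — keep a full run in a few minutes on
one CPU while leaving the binomial confidence bands tight enough to detect
real miscalibration.

## Numerical choices and degenerate inputs

* Midranks (`rank(ties.method = "average")`) everywhere a rank transform is
  used; the rank sum identity $n(n+1)/2$ is asserted property-style.
* Least squares via QR; aliased columns surface as errors only when the
  ordered score itself is inestimable (e.g. a single ecosystem). A constant
  response yields $t_{obs} = 0$, $R^2 = 0$, p = 1 rather than an error.
* Permutation ties are counted as exceedances within a relative tolerance
  of $10^{-9}$, so floating-point noise in degenerate fits cannot turn an
  exact tie into a non-exceedance.
* All package randomness runs under a private, seeded RNG scope that
  restores the caller's stream.
* CSV round trips are byte-stable after the first write (rows sorted by
  host then morphogroup; absent values as empty cells, never 0).

## Known limitations

* The ordered statistic is one defensible choice among several (isotonic
  contrasts, Jonckheere–Terpstra-type statistics would also serve); scores
  are configurable precisely because the choice is a convention.
* The accumulation-curve variance is Monte-Carlo, not closed-form.
* Redundancy handling trusts the `redundancy_group` annotation; the package
  neither discovers nor questions stage links.
* Real dissection data violate the generator's independence assumptions to
  an unknown degree; the fixed-pool conservativeness analysis above is the
  package's own quantification of one such violation.
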