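---
title: "Combining genetic and non-genetic evidence to identify skeletal remains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining genetic and non-genetic evidence to identify skeletal remains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinlr)
```

## The problem

A centuries-old missing-person case: skeletal remains are recovered that may
belong to a named historical individual.  Several independent observations
bear on the question — the radiocarbon date of the bones, the age and sex of
the skeleton, a spinal deformity matching contemporary descriptions,
perimortem battle injuries, a mitochondrial DNA (mtDNA) match with living
matrilineal relatives, and a Y-chromosome comparison with living patrilinear
relatives.  None of these alone is decisive.  kinlr implements the Bayesian
framework that weighs them together.

Two hypotheses are contrasted: **H1**, the remains are the target
individual, and **H2**, they are not.  For each item of evidence `E_i` we
form the likelihood ratio

$$\mathrm{LR}_i \;=\; \frac{P(E_i \mid H_1)}{P(E_i \mid H_2)},$$

assume the items independent, so that the joint likelihood under each
hypothesis is the product of the item likelihoods, and convert the combined
LR into a posterior probability through Bayes' rule in odds form:

$$\frac{P(H_1 \mid E)}{P(H_2 \mid E)} \;=\;
  \Big(\prod_i \mathrm{LR}_i\Big)\,\frac{\pi}{1-\pi},$$

where $\pi$ is the prior probability of H1.  `combine_evidence()` accumulates
the product in log space (an `lr_analysis` object), `posterior_prob()` and
`not_h1_probability()` perform the conversion, and `lr_table()` reports the
canonical evidence subsets (all; non-genetic; genetic; genetic without the
Y item).

Throughout, an assumption is called *conservative* if it reduces the LR;
each `evidence_item()` carries a `conservative` annotation recording the
direction of its bias.  That annotation is documentation, never computation.

## The genetic likelihoods

### mtDNA

Haplotypes are sets of differences from the rCRS over explicitly declared
control-region ranges (`mt_ranges("16093-16320 73-188")`), compared only on
the intersection of their declared ranges.  For an observed perfect match
between the remains and a matrilineal relative separated by $m$ meioses:

* under H1 the match requires no mutation in $m$ transmissions:
  $P = (1-\mu)^m$ with $\mu$ the per-meiosis control-region mutation
  probability.  The default $\mu = 10/327$ comes from a pedigree study that
  observed 10 control-region mutations in 327 transmissions; it is *high*
  relative to most published estimates, which is conservative here.
* under H2 the match requires a random member of the population to carry the
  haplotype: the match probability.  `match_probability(k, n)` uses the
  deliberately conservative convention
  $(k + \text{relative} + \text{pseudocount})/(n + \text{relative})$: the
  sampled matching relative is added to both counts and one pseudocount to
  the numerator, so a zero-match search of a database of 1,831 yields
  2/1,832 rather than 0.

`mtdna_lr()` is their ratio.  A second matching relative, assessed
conditionally on the first relative's sequence, contributes equally under
both hypotheses and cancels (`second_relative_lr()` returns exactly 1); this
holds whether the second relative matches perfectly or carries a single
difference accrued on its own branch.

Two numerical notes.  First, the published no-mutation probability of 0.52
for a 19-meiosis separation does not equal $(1 - 10/327)^{19} = 0.554$ (it
equals the 21-meiosis value, 0.521, to two decimals); the exact derivation
behind 0.52 is not recoverable from the published account.  kinlr implements
the stated closed form; where the canonical case fixture needs the published
number it uses 0.52 as a reported constant (`p_no_mutation = 0.52`).
Second, the source database is described both as 1,832 samples and as "0
matches among 1,823"; the fixture uses $n = 1831$ plus the relative, which
reproduces the printed 2/1,832 exactly.

### Y chromosome

Y-STR haplotypes (default panel: the 23-locus PowerPlex Y23 layout, DYS385
as a two-allele multiset) are compared locus by locus.  A haplogroup
discordant with the modal clade among claimed patrilinear relatives cannot
arise by STR mutation on the genealogical time scale and marks a
false-paternity event; `partition_patriline()` excludes such individuals
first, then screens the remainder by minimum pairwise mismatch count
(default threshold: 10% of compared loci, rounded up — an explicit
heuristic allowing stepwise mutation over long genealogies).

When the remains' Y does *not* match the patriline, the evidence LR is the
false-paternity exposure

$$\mathrm{LR}_Y = 1 - (1-r)^m,$$

the probability of at least one broken link among the $m$ recorded
father–son links under per-link rate $r$: under H1 a non-match requires at
least one such event, while the haplotype's population frequency is common
to both hypotheses and cancels.  The published account does not print its
$r$; kinlr's fixtures use $r = 0.009$, which reproduces the printed
exposure 0.16 at $m = 19$ and sits below the ~1–2% range usually quoted
(conservative in this direction, because $\mathrm{LR}_Y < 1$ is evidence
*against* H1 and a smaller $r$ makes it smaller).  The account also
describes one further false-paternity event below the most recent common
patrilinear ancestor; read as $m = 20$, the exposure becomes
$1 - 0.991^{20} = 0.165$, whose product with the mtDNA LR matches the
printed genetic aggregate more closely.  Both readings are available by
setting `m`; the fixtures use $m = 19$.

### The scoliosis construction

The historical description ("one shoulder higher than the other") admits
three explanations with population rates $s$ (scoliosis), $e$ (Erb's
palsy), $sp$ (Sprengel's deformity).  Under H1 the probability of finding
scoliosis given the description is the share $s/(s+e+sp)$, multiplied by the
probability $p_{\mathrm{rec}}$ that the description is correct; under H2 it
is the population probability $p_{\mathrm{pop}}$ of the skeletal finding:
`scoliosis_lr()`.  The three rates and $p_{\mathrm{pop}}$ live in external
reference data not shipped here; the worked example back-derives
$p_{\mathrm{pop}}$ from the published LR 212 and numerator
$0.90 \times 0.95 = 0.855$, and is labelled as derived in the fixture notes.

### Fixed items

The radiocarbon (1.84), age/sex (5.25) and wound (42) LRs rest on
calibration curves and reference data outside this package's scope; they
enter as `fixed_lr` items, exactly as externally computed likelihood ratios.

## Pedigree arithmetic

`matriline()`/`patriline()` walk the recorded uniparental chains;
`meioses_between()` counts parent–child transmissions through the most
recent common uniparental ancestor (the convention implicit in cousin
naming; with generation counts $g_a \le g_b$ below that ancestor,
`cousin_terms()` gives degree $g_a - 1$, removal $g_b - g_a$, total meioses
$g_a + g_b$).  Individuals sharing a matrilineal founder — everyone expected
to carry the same inherited mtDNA absent mutation — are returned by
`matrilineal_network()`, the computational core of ruling out contemporary
relatives as alternative sources of a match.  Unknown-parent entries follow
the PED `"0"` convention; "unrelated on this lineage" is reported as `NA`,
distinct from validation errors, which are classed conditions.

## What the simulator emulates

`sim_config()` fixes the study conditions; its defaults are the framework's
operating point: $r = 0.009$ per link, $\mu = 10/327$ per meiosis, Y-STR
stepwise rate $2\times10^{-3}$ per locus per meiosis (a typical forensic
value; direction $\pm 1$ repeat equiprobable), database size 1,831 over the
two control-region ranges, and case lineages of 19 meioses / 19 links.

* **Pedigrees** (`simulate_pedigree()`): `generations` counts generation
  levels including the founders (`generations = 1` is founders only).  A
  daughter chain and a son chain are guaranteed to reach the deepest level,
  so uniparental queries always have a full-depth line; collateral couples
  reproduce with Poisson offspring under a per-level cap.
* **Transmission** (`transmit_markers()`): at most one mtDNA mutation per
  meiosis (Bernoulli $\mu$; a uniformly chosen in-range position changes to
  a uniformly chosen different base) — the simplest model whose
  perfect-transmission probability is exactly $(1-\mu)^m$, the closed form
  the package computes.  Back mutation at a previously hit position can
  restore a perfect match; at the default rates this inflates the
  perfect-match fraction by well under one Monte-Carlo standard error at
  the replicate sizes used.  A false paternity redirects inheritance to a
  random male from the population spectrum, which usually changes the
  haplogroup label — mirroring how such events are detected in practice.
* **Populations** (`population_spectrum()`, `sample_database()`): haplotype
  frequencies follow a truncated stick-breaking (GEM) spectrum with
  concentration `db_alpha`; small values give one dominant haplotype, large
  values many rare ones.  True frequencies are retained in the truth record
  so estimators can be scored against ground truth.
* **Cases** (`make_case()`): under H1 the skeleton's profiles are copied
  from the target individual after transmission; under H2 they are drawn
  from the unrelated population.  Bundles round-trip through plain-text
  files (`write_case_bundle()`/`read_case_bundle()`) and are byte-identical
  under a fixed seed.

When `run_case()` scores a synthetic bundle it needs likelihoods for *all*
outcomes, not only the observed-match ones the published analysis required:
a mtDNA mismatch is scored with the complementary binary-outcome
likelihoods $1-(1-\mu)^m$ versus $1 - p_{\text{match}}$, and a matching Y
is scored as the neutral LR 1 — conservative, since a Y match is evidence
for H1 whose strength the framework deliberately declines to model.  These
two extensions are this package's own design choices.

### What passing simulations do and do not show

The generator realises the *assumed* models: independent per-link false
paternity, at most one mtDNA mutation per meiosis, independent stepwise STR
mutation, a well-mixed population with stable haplotype frequencies.  Tests
that recover $1-(1-r)^m$ and $(1-\mu)^m$ from simulation therefore validate
the implementation, not the assumptions.  Real data add what the simulator
omits: sequencing and typing error, DNA damage, heteroplasmy, population
structure and database ascertainment, non-independence of evidence items,
and uncertainty in the genealogies themselves.

A note on the conservatism of the pseudocount rule: for a haplotype with
true frequency $f \le 2/(n+1)$ the default estimate $(k+2)/(n+1)$ can never
fall below $f$, and simulations in that rare-haplotype regime (the regime an
identification case is about) show conservatism in well over 95% of
replicates.  For *common* haplotypes the estimate is essentially unbiased,
so the one-sided guarantee deliberately lapses — there is nothing to
protect against when $k$ is large.

## Numerical and interface choices

* LR products in log space; `sum(log(lr))` of an empty set is 0, so the
  empty evidence subset has the neutral LR 1 and returns the prior.
* `not_h1_probability()` computes $(1-\pi)/(\mathrm{LR}\,\pi + 1 - \pi)$
  directly, keeping precision when the posterior is within $10^{-7}$ of 1.
* Reporting rounds LRs to 3 significant figures and prints posteriors with
  enough digits to distinguish them from 1; full precision goes to the TSV.
* Indel tokens (`315.1C`, `249DEL`) are opaque strings compared by
  equality; heteroplasmy/ambiguity codes other than `N` are rejected rather
  than silently interpreted.  The reference sequence is always an input,
  never embedded.
* Ties in `partition_patriline()`'s modal-clade vote resolve to the first
  clade in table order; the function is intended for panels where the
  claimed patriline holds a clear majority.
* Every simulator entry point takes a seed, uses one local RNG stream, and
  restores the caller's RNG state; seeds are recorded in all outputs.

Problem sizes used by the shipped tests were chosen to keep the full suite
in the minutes range on one core while leaving Monte-Carlo standard errors
well below the effect sizes under test: 10,000 replicates for the
closed-form recovery checks (3 SE ≈ 1.1 percentage points on the
false-paternity fraction), 2,000 for the rate-recovery check, 300
populations of 1,831 for estimator conservatism, and 80 cases for the
discrimination/calibration study.

## Limitations

* Independence of evidence items is assumed, never modelled.
* No haplogroup prediction, phylogenetic placement, read mapping or variant
  calling: haplotypes and haplogroup labels enter as data.
* The Y evidence model covers the observed-non-match contract (plus the
  neutral-match extension above); it does not model partial matches beyond
  the mismatch count heuristic.
* General kinship coefficients, GEDCOM input and radiocarbon calibration
  are out of scope.
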