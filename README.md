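# kinlr

Likelihood-ratio identification of skeletal remains from kinship and
uniparental genetic markers.

## What it is for

Cold missing-person and historical identification cases ask one question:
are these remains the named individual (**H1**) or not (**H2**)?  The
available observations — radiocarbon dates, skeletal age and sex, diagnostic
pathology, perimortem injuries, a mitochondrial DNA comparison with living
matrilineal relatives, a Y-chromosome comparison with living patrilinear
relatives — are individually inconclusive.  kinlr is for forensic
statisticians and genetic genealogists who need to weigh them jointly and
defensibly.

Each evidence item contributes a likelihood ratio
LR = P(E | H1) / P(E | H2).  Independent items multiply, and the combined LR
converts a prior probability π into a posterior through the odds form of
Bayes' rule:

    posterior odds = LR_combined × π / (1 − π)

The genetic LRs are built from first principles:

* **mtDNA** — haplotypes as differences from the rCRS over declared
  control-region ranges; a perfect match across *m* meioses has likelihood
  (1 − μ)^m under H1 (μ = per-meiosis mutation probability) and, under H2,
  a deliberately conservative match probability
  (k + relative + pseudocount) / (n + relative) from k matches in a
  database of n (so a zero-match search of 1,831 gives 2/1,832, never 0).
* **Y chromosome** — for an observed non-match with the patriline, the LR is
  the false-paternity exposure 1 − (1 − r)^m over the m recorded father–son
  links (the haplotype's population frequency cancels between hypotheses).
* **Pedigree arithmetic** — matriline/patriline queries, meiosis counts
  through the most recent common uniparental ancestor, cousin terminology,
  and matrilineal kinship networks (everyone expected to share an inherited
  mtDNA type).

A seeded forward simulator (`sim_config()`, `simulate_pedigree()`,
`transmit_markers()`, `sample_database()`, `make_case()`) generates complete
synthetic cases with known ground truth — pedigrees, marker transmission
with false-paternity and mutation events, population haplotype databases —
so the whole pipeline is testable without any external data.

## Worked example

The canonical case ships as an evidence configuration with six items: four
non-genetic likelihood ratios taken as externally computed inputs
(radiocarbon 1.84, age/sex 5.25, scoliosis 212, wounds 42), the
Y-chromosome non-match exposure (0.16), and the mtDNA match LR (478).

```r
library(kinlr)
config <- system.file("extdata", "richard_case.json", package = "kinlr")
report <- run_case(config)
report
#> Identification case report
#> ==========================
#> Per-item likelihood ratios:
#>   radiocarbon    LR = 1.84          [conservative: biases LR down]
#>   age_sex        LR = 5.25          [conservative: biases LR down]
#>   scoliosis      LR = 212           [conservative: biases LR down]
#>   wounds         LR = 42            [conservative: biases LR down]
#>   y_chromosome   LR = 0.16          [conservative: biases LR down]
#>   mtdna          LR = 478           [conservative: biases LR down]
#>
#> Evidence subsets:
#>   all           (6 items)  LR = 6.58 million
#>       prior 0.025   -> posterior 0.9999941
#>       prior 0.5     -> posterior 0.99999985
#>   non_genetic   (4 items)  LR = 86,000
#>       prior 0.025   -> posterior 0.99955
#>       prior 0.5     -> posterior 0.999988
#>   genetic       (2 items)  LR = 76.5
#>       prior 0.025   -> posterior 0.6623
#>       prior 0.5     -> posterior 0.9871
#>   genetic_no_y  (1 items)  LR = 478
#>       prior 0.025   -> posterior 0.9246
#>       prior 0.5     -> posterior 0.9979
```

Reading the numbers: the genetic evidence alone is moderate (LR ≈ 76, i.e.
posterior ≈ 2/3 from a sceptical 1-in-40 prior) because the Y non-match
counts against identity; dropping the false-paternity-prone Y item raises
the genetic contribution to 478.  All six items together give LR ≈ 6.6
million, which overwhelms even the sceptical prior: the probability that
the remains are *not* the target is below 1 in 100,000
(`not_h1_probability(0.025, report$table$lr[1])` ≈ 5.9e-6).

The building blocks are exported individually:

```r
false_paternity_prob(r = 0.009, m = 19)   # 0.1578  (prints as 0.16)
match_probability(k = 0, n = 1831)        # 0.0010917  = 2/1832
mtdna_lr(p_match = 2/1832, p_no_mutation = 0.52)  # 476.32
cousin_terms(15, 17)                      # 14th cousins, twice removed (32 meioses)
```

A complete synthetic case with known truth:

```r
cfg <- sim_config(seed = 1, db_size = 200)
bundle <- make_case(cfg, under_h1 = TRUE)
run_case(bundle)   # genetic items computed from the simulated marker data
```

## Scope

No read mapping, variant calling, haplogroup prediction, radiocarbon
calibration or phenotype prediction: haplotypes, haplogroup labels and
externally derived LRs enter as data.  See the methods vignette
(`vignettes/identification-evidence.Rmd`) for the model assumptions, the
simulator's design and its limitations.
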