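{
  "version": 1,
  "items": [
    {
      "name": "radiocarbon",
      "form": "fixed_lr",
      "lr": 1.84,
      "category": "non_genetic",
      "conservative": "down",
      "notes": "Externally computed likelihood ratio from calibrated radiocarbon dating of the remains."
    },
    {
      "name": "age_sex",
      "form": "fixed_lr",
      "lr": 5.25,
      "category": "non_genetic",
      "conservative": "down",
      "notes": "Externally computed likelihood ratio for estimated age at death and sex."
    },
    {
      "name": "scoliosis",
      "form": "fixed_lr",
      "lr": 212,
      "category": "non_genetic",
      "conservative": "down",
      "notes": "Likelihood ratio for severe idiopathic scoliosis given the historical description of an uneven shoulder: share 0.90 of candidate conditions times 0.95 record-correctness, over the population probability of the skeletal finding (population rates held in external reference data; see scoliosis_lr())."
    },
    {
      "name": "wounds",
      "form": "fixed_lr",
      "lr": 42,
      "category": "non_genetic",
      "conservative": "down",
      "notes": "Externally computed likelihood ratio for the perimortem battle injuries."
    },
    {
      "name": "y_chromosome",
      "form": "fixed_lr",
      "lr": 0.16,
      "category": "genetic",
      "conservative": "down",
      "notes": "Observed Y non-match with the patrilinear relatives; LR equals the false-paternity exposure 1-(1-r)^19 at a conservative per-link rate (see y_lr()); the haplotype's population frequency cancels."
    },
    {
      "name": "mtdna",
      "form": "fixed_lr",
      "lr": 478,
      "category": "genetic",
      "conservative": "down",
      "notes": "Perfect control-region match with the 19-meiosis matrilineal relative: no-mutation probability 0.52 over a very conservative match probability of 2/1,832 from a zero-match British-Isles database of 1,831 plus the sampled relative (see mtdna_lr(), match_probability()). The second relative's near-match cancels conditionally (second_relative_lr())."
    }
  ],
  "priors": [0.025, 0.5]
}
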