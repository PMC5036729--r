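# icrdm

Cross-ratio intuitionistic fuzzy multicriteria decision analysis for R.

## The problem

Choosing among alternatives — the motivating application is selecting a
medical-waste disposal method — often rests on pairwise expert judgments
that carry *hesitation*: an expert may say "I prefer incineration to
autoclave with degree 5/8, and do not prefer it with degree 1/5", leaving
the rest undecided. Such a judgment is an intuitionistic fuzzy value
(IFV), a pair (ξ, η) with ξ + η ≤ 1. `icrdm` implements a complete
decision calculus for the cross-ratio subclass of IFVs, where both
components live strictly in (0, 1) and the right arithmetic is odds
arithmetic: under u = x/(1−x),

* the sum ⊕ adds membership odds (and combines non-membership odds
  harmonically),
* the product ⊗ — the ALRCR uninorm xy/(xy+(1−x)(1−y)) applied to both
  components — multiplies odds, with neutral element (0.5, 0.5),
* the weighted geometric aggregator **ICRWG**,
  ⊗ᵢ αᵢ^ωᵢ, is a componentwise weighted geometric mean of odds,
* values rank by the score S = √(ξ(1−η)) / (√(ξ(1−η)) + √((1−ξ)η)) with
  the accuracy H = ξη/((1−ξ)(1−η)) as tie-breaker.

On top sits a two-level AHP-style hierarchy: one intuitionistic
preference relation (IPR) per criterion rates all alternative pairs on a
bounded bipolar 0.1–0.9 scale (Saaty's 1–9 scale mapped through
r ↦ r/(1+r)); row-wise ICRWG means give local priorities; a weighted
ICRWG fusion across criteria gives overall priorities, scores and the
final ranking. It is aimed at decision analysts who want the algebra,
validation, and reporting machinery in one tested package.

## Worked example

The embedded case study rates five disposal methods — incineration (x1),
autoclave (x2), microwave (x3), sterilization (x4), other treatments
(x5) — against technical, economic and social/environmental criteria with
weights (0.4, 0.35, 0.25):

```r
library(icrdm)
res <- solve_decision(mwdms_problem())
res
#> Decision matrix (local priorities):
#>    technical        economic         social_environmental
#> x1 (0.6706, 0.1934) (0.7445, 0.1758) (0.6508, 0.2701)
#> x2 (0.4654, 0.3783) (0.4688, 0.3901) (0.5457, 0.3763)
#> x3 (0.2701, 0.6204) (0.3607, 0.5471) (0.4006, 0.4947)
#> x4 (0.2951, 0.5746) (0.2708, 0.6786) (0.3235, 0.6131)
#> x5 (0.4311, 0.3925) (0.3925, 0.5000) (0.3545, 0.5314)
#>
#> Overall priorities:
#>            priority  score accuracy
#> x1 (0.6930, 0.2042) 0.7479   0.5792
#> x2 (0.4867, 0.3819) 0.5533   0.5858
#> x3 (0.3321, 0.5640) 0.3827   0.6432
#> x4 (0.2933, 0.6218) 0.3344   0.6822
#> x5 (0.3980, 0.4642) 0.4663   0.5729
#>
#> Ranking (geometric score): x1 > x2 > x5 > x3 > x4
```

Each decision-matrix cell is the cross-ratio geometric mean of one IPR
row: x1's technical priority (0.6706, 0.1934) summarises how strongly x1
beat the field under that criterion. The overall priority fuses the three
cells of a row with the criterion weights; its score (position of the
value between the scale's worst (0.1, 0.9) and best (0.9, 0.1)) orders
the alternatives, and incineration wins despite its environmental
drawbacks.

The same problem ships as a file
(`system.file("extdata", "mwdms.json", package = "icrdm")`) for the I/O
path, and a CLI covers validation, ranking, scale conversion and random
relation generation:

```sh
Rscript inst/exec/icrdm demo mwdms
Rscript inst/exec/icrdm rank --problem inst/extdata/mwdms.json --format json
Rscript inst/exec/icrdm validate my_ipr.csv
Rscript inst/exec/icrdm scale convert --from saaty 3        # -> 0.75
Rscript inst/exec/icrdm gen-ipr --n 4 --seed 1
```

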