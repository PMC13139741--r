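# kanor

Kano-model analysis of paired functional/dysfunctional survey items in R.

## The problem

When designing a product or service — here, the motivating application is a
digital mental-health support platform for hospital nurses — not all user
needs are equal. Some features are taken for granted (their absence infuriates,
their presence goes unnoticed), others delight precisely because nobody
expected them. The Kano model separates these regimes. Each candidate feature
is asked about twice on a 5-point Likert scale (1 = I like it that way …
5 = I dislike it that way):

* functional form — *"If this feature was available, how would you feel?"*
* dysfunctional form — *"If this feature was NOT available, how would you feel?"*

The standard 5 × 5 Kano evaluation table maps each answer pair to one of six
categories: **M** must-be, **O** one-dimensional, **A** attractive,
**I** indifferent, **R** reverse, **Q** questionable. An item's final
attribute is its modal category across respondents. From the per-item
category counts two coefficients are computed:

```
SI  = (A + O) / (A + O + M + I)          satisfaction ("better"),  in [0, 1]
DSI = −(O + M) / (A + O + M + I)         importance  ("worse"),    in [−1, 0]
```

Plotting each item at (|DSI|, SI) and splitting the plane at the per-axis
means gives the importance–satisfaction matrix with four strategy quadrants:
I predominance (high/high), II improving, III secondary improving,
IV reserving. Boundary ties go to the high side.

`kanor` implements the complete pipeline — respondent screening
(logic-error and completion-time filters), pair classification, modal
attribute assignment, indices, quadrant matrix — plus Kendall sample-size
planning, Cronbach's alpha and Cohen's kappa for instrument development, and
a seeded synthetic-respondent generator so every stage is testable without
raw survey data.

## Worked example

The package ships an aggregated per-item frequency table from a
cross-sectional survey in which 1,571 tertiary-hospital nurses rated 26
candidate features of a digital mental-health platform:

```r
library(kanor)
fit <- kano(nurse_demand_frequencies())
fit
#> Kano needs analysis: 26 items
#> Attributes: M:8  O:8  A:7  I:3
#> Matrix origin: mean |DSI| = 0.43, mean SI = 0.49
```

Of the 26 needs, 8 are must-be, 8 one-dimensional, 7 attractive and 3
indifferent. `summary(fit)` prints the full per-item table; the first rows:

```
 item                                     label   M   O   A   I  R Q attribute   DSI   SI quadrant
    1            Intelligent emotion monitoring 282 235 725 322  2 5         A -0.33 0.61       II
    2           Professional psychology courses 235 672 246 413  3 2         O -0.58 0.59        I
    3 Professional psychology online counseling 258 626 229 453  4 1         O -0.56 0.55        I
```

Item 1 (intelligent emotion monitoring) is **attractive**: 725 of its 1,571
valid responses fall in category A. Its SI = (725+235)/1564 = 0.61 says
fulfilment raises satisfaction strongly; its DSI = −0.33 says its absence
hurts comparatively little — hence quadrant II (improving). The quadrant
memberships:

```r
fit$quadrants
#> $I   "2" "3" "4" "11" "15" "16" "19" "20"   (predominance)
#> $II  "1" "9" "12" "13" "14" "24" "26"       (improving)
#> $III "17" "22" "23"                         (secondary improving)
#> $IV  "5" "6" "7" "8" "10" "18" "21" "25"    (reserving)
```

`plot(fit)` draws the matrix with origin cross-hairs. `coef(fit)` returns
the full-precision SI/DSI per item, and `simulate(fit, nsim, seed, n)` draws
parametric-bootstrap respondent-level datasets from the fitted frequencies.

Respondent-level data work the same way: read a wide CSV with
`read_kano_survey(path, codebook)` (one row per respondent, two Likert
columns per item, named by a `kano_codebook()`), or generate one:

```r
d <- simulate_kano_survey(
  list(feature_a = kano_profile("M", purity = 0.7),
       feature_b = kano_profile("A", purity = 0.7)),
  n = 300, seed = 42, logic_error_rate = 0.05
)
kano(d)   # screens (3-minute rule + logic flags), then classifies
```

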