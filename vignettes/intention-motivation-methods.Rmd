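---
title: "Methods: TPB/SDT scoring, persona segmentation and the test battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TPB/SDT scoring, persona segmentation and the test battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intentgap)
```

## The measurement model

`intentgap` analyzes surveys that measure, for two topics (healthy and
sustainable grocery shopping), a participant's short-term intention and
longer-term motivation. All items are 5-point Likert questions coded on the
centered scale $\{-2, -1, 0, +1, +2\}$, and every construct score is the
arithmetic mean of its items, so all scores live on $[-2, +2]$.

Per topic the package computes nine construct scores:

* **TPB block** — attitude $A$, subjective norm $SN$, perceived behavioral
  control $PBC$ (three items each by default).
* **SDT block** — external, introjected, identified and intrinsic regulation
  ($R^{Ext}, R^{Intro}, R^{Id}, R^{Int}$; three items each by default).
* **Self-report** — intention $I$ and perceived behavior $B$, one item each;
  the behavior item offers an explicit "Don't know" option.

Two composites summarize the blocks:

$$BI = w_A A + w_{SN}\,SN + w_{PBC}\,PBC, \qquad
  RAI = 2R^{Int} + R^{Id} - R^{Intro} - 2R^{Ext}.$$

The RAI weights are fixed by the self-determination literature; with scores
on $[-2,+2]$ the RAI is bounded by $\pm 12$. The BI weights are free
parameters. Because the Pearson correlation is invariant under positive
scaling of the weight vector, only the *direction* of $(w_A, w_{SN},
w_{PBC})$ is identified; `calibrate_weights()` therefore reports one
representative of the scale class, chosen from an exhaustive grid
$w \in \{0, 0.1, \dots, 2\}^3 \setminus \{0\}$ by maximizing
$\mathrm{cor}(BI(w), I)$, with ties broken by smallest weight sum and then
lexicographically. A grid with one-decimal spacing was chosen over continuous
optimization so that reported weights are exactly reproducible and match the
granularity conventionally reported for this design; the achieved correlation
is flat near its maximum, so finer steps change the correlation only in the
third decimal. Non-negativity is imposed because the TPB posits
non-negative contributions of all three antecedents to intention.

### Missing data and "Don't know"

A *missing* answer and an explicit *"Don't know"* are different facts and are
kept distinct end to end. A record is **complete** iff every item is
non-missing ("Don't know" counts as an answer); incomplete records are
dropped once, up front. A construct with any missing item is undefined for
that participant, and a behavior score answered "Don't know" is undefined —
but only that score. Every test in the battery then uses pairwise deletion,
so "Don't know" behavior responders are excluded exactly from the behavior
analyses and nowhere else. With 144 completers of whom 6 answer "Don't know"
on the sustainability behavior item, the sustainability intention–action gap
test runs on $n = 138$ pairs ($df = 137$) while every health analysis keeps
$n = 144$ — reproducing the df bookkeeping such studies report.

## Personas

Dichotomizing $A$ (positive/negative), $SN$ and $PBC$ (high/low) yields
$2^3 = 8$ segments, indexed 1–8 with attitude varying slowest and the low-PBC
half being segments 3, 4, 7 and 8. Exact zeros are classified
negative/low by default (`zero_as_positive = FALSE`): the convention is a
genuine free choice — item-mean scores of exactly 0 are common on Likert
data and the published segment shares may be sensitive to it — so it is a
config switch and is recorded in the output metadata. Marginal tables use
pairwise inclusion (a participant undefined on one topic still counts for
the other); the joint 8×8 table uses participants defined on both.

## The test battery and multiplicity

`run_full_analysis()` runs 17 tests as **one** Benjamini–Hochberg family at
$q = 0.05$: six paired t-tests ($I_H$ vs $I_S$; $B_H$ vs $B_S$; the two
intention–action gaps; $BI_H$ vs $BI_S$; $RAI_H$ vs $RAI_S$), ten Pearson
correlations (the five descriptive pairs, the four composite pairs, and the
two calibration correlations $BI \sim I$), and one Wilcoxon signed-rank test
on $PBC_H$ vs $PBC_S$. Sorted p-values $p_{(i)}$ are compared to
$\alpha_{BH}(i) = i\,q/m$ and the step-up rule rejects all tests up to the
largest $i$ with $p_{(i)} \le i\,q/m$; for $m = 17$ the three-decimal
thresholds run from $0.003$ to $0.05$. Rejection always uses the unrounded
thresholds. Two caveats are printed with every report: the family membership
is a reconstruction (17 tests corrected together), and the two $BI \sim I$
rows are circular because the calibrated weights maximize that very
correlation.

Paired t-tests report three effect-size variants, all labeled:
$d_z = \bar d / s_d$, the pooled
$d = (\bar x - \bar y)/\sqrt{(s_x^2+s_y^2)/2}$, and $d_{t} = t/\sqrt{n}$.
All three are reported because published paired designs are frequently
ambiguous about which variant a printed Cohen's d is, and the variants can
disagree by a factor of two or more on correlated pairs; no single variant
reproduces every published d for this design, whereas $t/\sqrt{n}$ provably
reproduces the RAI contrast value ($0.39/\sqrt{144} = 0.03$).

The Wilcoxon implementation is in-package because the battery needs a
combination base R does not provide: a selectable zero policy (`discard`,
the classical treatment, or `pratt`, which ranks zeros and then drops their
ranks from the statistic and its null moments), an exact two-sided p by
enumeration of sign assignments whenever at most 12 nonzero differences
remain, and otherwise a normal approximation with tie correction and no
continuity correction. The exact branch uses a generating-function
convolution over (doubled, hence integral) midranks; the test suite checks
it against an independent brute-force $2^n$ enumeration and against
`wilcox.test` on the tie-free cases.

## The synthetic-cohort generator

The generator exists so the whole pipeline is testable at the study's own
scale without the deposited data. Its defaults **are** the study
conditions: 144 completers of 176 starters; self-report means/SDs
$I_H(1.38, 0.69)$, $B_H(0.4, 0.86)$, $I_S(0.77, 0.93)$, $B_S(-0.37, 1.03)$;
the ten published inter-score correlations; six "Don't know" behavior
responders (all on $B_S$ — the only placement consistent with the published
degrees of freedom); and starters who drop out after the first self-report
section.

### What is not published, and what was chosen

Construct-level means/SDs are not published; only the composite moments are.
The defaults were chosen once so the composite equations induce the
published values: health $A/SN/PBC$ means $1.2/0.7/-0.1$ give
$BI_H = 1.4(1.2) + 1.0(0.7) + 0.5(-0.1) = 2.33$; sustainability
$0.6/0.42/-0.5$ give $BI_S = 0.92$ (a clearly negative $PBC_S$ mean matches
the reported dominance of low perceived control for sustainability);
regulation means $0.3/0.18/1.1/0.9$ (health) and $0.2/0.16/1.0/0.8$
(sustainability) give RAI means $2.12$ and $2.04$. TPB construct SDs
($0.67$ health, $0.63$ sustainability, with within-block correlation $0.3$)
and independent regulations with SDs $0.8$ and $0.64$ induce composite SDs
$1.46/1.29/2.53/2.02$ against published $1.45/1.28/2.48/2.02$. Item noise
(SD $0.5$) represents within-construct item heterogeneity.

### Latent model, completion and calibration

Scores are generated as a truncated latent Gaussian: a multivariate normal
over the 18 base scores, clamped to $[-2,+2]$; items are the construct
latent plus independent noise, rounded to the nearest integer in
$\{-2..+2\}$; $I$ and $B$ are single discretized items. A latent-Gaussian
model was preferred over an ordinal copula for transparency; the published
information (means, SDs, correlations) does not identify item-level
distributions anyway.

Correlation targets naming a composite cannot be entries of the latent
matrix. Each such target $r(U, V)$ is *induced*: it is allocated across the
constituent constructs proportionally to the composite loadings
$a_j \sigma_j$, which reproduces the target exactly at the latent level.
Unspecified entries start at 0; the matrix is then completed to positive
definiteness by alternating projections (eigenvalue clipping at $10^{-6}$
alternated with restoring the specified cells). Plain one-shot clipping is
kept for the exported `complete_correlation_matrix()`, which also errors if
a specified entry moves by more than 0.02 — the contract for detecting
contradictory specifications. The alternating completion matters here
because the specified pairs form high-correlation cycles (e.g.
$I_H\!-\!B_H\!-\!B_S\!-\!I_S$) whose unspecified diagonals must move off 0
for any positive-definite completion to exist.

Clamping near the $+2$ boundary biases means (a latent $N(1.38, 0.69)$
loses about $0.22$ to the boundary) and discretization attenuates
correlations by roughly 10%. `calibrate_generator()` therefore runs a
seeded fixed-point Monte-Carlo loop (4 iterations, 40 000 latent draws
each): simulate, emit items, score, then move the latent means additively,
the SDs multiplicatively and the target-pair correlations multiplicatively
(clamped to $(-0.98, 0.98)$) toward the targets. The calibration is
deterministic given `(config, seed)` and stores realized-vs-target
diagnostics, including the measured SD attenuation factors. After
calibration, replicate-averaged observed score means sit within about
$0.02$ and the ten correlations within about $0.02$ of their targets at
$n = 144$.

### What the generator does and does not emulate

It reproduces score-level moments, the published correlation structure,
missingness counts and the completion funnel. It does **not** model
item-level response styles (acquiescence, straight-lining), demographic
composition, non-normal marginals beyond what truncation induces, or any
demographic dependence of "Don't know" answering (placement is uniform).
Pipeline tests passing on synthetic cohorts therefore validate the
*computational* chain — scoring, calibration, segmentation, the battery and
its bookkeeping — not distributional claims about real respondents; the
single-study statistics that depend on the actual joint distribution
(e.g. a specific $t$ or the exact low-PBC shares) are only checkable against
the deposited dataset, which the pipeline accepts as a delimited file.

## Numerical and design choices

* **Problem sizes.** The suite exercises moment recovery with 200 replicate
  cohorts of $n = 144$ and the acceptance script uses the same; oracle
  checks enumerate $2^n$ sign assignments up to $n = 12$ and use 500 random
  instances.
* **Degenerate inputs.** Zero-variance paired differences and constant
  correlation inputs are errors, not silent zeros; an all-zero difference
  vector is an error for the Wilcoxon test.
* **Ties.** Midranks everywhere; the exact signed-rank distribution doubles
  ranks to stay integral.
* **Determinism.** Every stochastic step flows from a single user seed via
  `withr::with_seed()`; `(cohort file, config, seed)` determine all report
  bytes exactly, and the test suite asserts byte identity.
* **Weight normalization.** Published weight triples for this design do not
  share a common normalization (the two topics' weights sum to different
  values), so the package treats weights as a scale class and reports the
  grid representative; only the direction is identified.

## Limitations

The BH family membership and the "Don't know" placement are principled
reconstructions, not published facts. Construct-level generator moments are
package choices constrained only through the composite equations. The
persona zero convention can shift published-style segment shares. And the
calibration correlations tested inside the BH family are circular by
construction; they are kept in the family for fidelity to the reporting
style of such studies, flagged in every report.
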