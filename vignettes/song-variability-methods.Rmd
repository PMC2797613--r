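---
title: "Quantifying song variability: transition entropy, CV phonology, and resampling inference"
author: "songvar package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying song variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songvar)
```

## The problem

Juvenile zebra finches refine their song by vocal practice during
sensorimotor learning (~35–90 days post-hatch). A natural question is
whether a bout of undirected singing ("practice") acutely changes how
variable the song is, both in its *syntax* (the order of syllables within
the motif) and in its *phonology* (the acoustic structure of individual
syllables). The experimental design this package serves is paired: each
bird is measured after two hours of non-singing (`NS-UD`) and after two
hours of undirected singing (`UD-UD`), and inference is about the within-bird
conditional difference.

`songvar` implements the full analysis chain on symbolic data: syllables
are labeled (`A = 1, B = 2, ...`) by the experimenter or by automated
segmentation, and the package takes over from the label files.

## Sequence variability: transition entropy and stereotypy

Song syntax is modeled as a first-order Markov chain over the syllable
repertoire. For leading syllable $A$ and outcome $B$,

$$p(A \to B) = \frac{F_{A \to B}}{\sum_i F_{A \to i}},$$

the number of times $A$ is followed by $B$ divided by the total outgoing
count of $A$. The **transition entropy** of a syllable is the Shannon
entropy of its outgoing distribution,

$$H_A = -\sum_i p_i \log_2 p_i, \qquad 0 \log 0 := 0,$$

which is 0 when the successor is fixed and maximal,
$H_{\max} = \log_2 n$, when all $n$ possible outcomes are equally likely.
Each syllable's entropy is normalized by $H_{\max}$ so that repertoire
size does not inflate the score, and the normalized entropies are averaged
into the **motif entropy** $\in [0, 1]$. **Stereotypy** is defined as
$1 -$ motif entropy: 1 means fixed syllable order. Tables conventionally
report stereotypy $\times 100$ so it sits on the same 0–100 scale as
similarity and accuracy scores.

Two estimation modes reflect two ways of collecting the data:

* **motif-based** (`MotifSet`, 20 investigator-segmented motifs): the end
  of each motif is informative, so the last syllable of every motif
  contributes a transition to a distinguished `END` outcome;
* **string-based** (`SyllableString`, the first ~300 automatically
  segmented syllables): there is no motif boundary information, so `END`
  transitions are excluded and the final symbol contributes nothing.

```{r}
ms <- motifSet(rep(list(c("A", "B", "C", "D", "E")), 20))
sv <- sequenceVariability(ms, includeEnd = TRUE)
sv
```

### Weighted entropy

Averaging normalized entropies lets a rarely sung syllable with extreme
entropy dominate the motif score. The **weighted** variant multiplies each
syllable's normalized entropy by $w_s = F_s / F_{\max}$ — its frequency as
a leading syllable relative to the most frequent syllable — before
averaging. When all syllables are equally frequent all $w_s = 1$ and the
weighted score equals the standard one exactly. Frequency is counted over
positions with an outgoing transition, so the weights and the transition
distributions use the same support.

### Numerical and design choices

* **Logarithm base.** Raw entropies are reported in bits (base 2,
  configurable); normalized and motif entropy are base-invariant, so the
  choice only affects the raw `H` column, which is always reported next to
  `Hmax`.
* **`END` in the normalization ceiling.** In motif mode the entropy
  numerator sums over `END` transitions, so the ceiling must count `END`
  as one additional outcome ($H_{\max} = \log_2(n + 1)$) or a syllable
  that uniformly precedes every syllable *and* the motif end would score a
  normalized entropy above 1. `legacyHmax = TRUE` reverts to
  $\log_2 n$ for sensitivity analysis; in the fixed-sequence and
  uniform-chain limits the two agree.
* **Syllables without outgoing transitions** (string mode only: a symbol
  whose sole occurrence ends the string) have an undefined distribution
  and are dropped from the average, with a warning.
* **Percent change** between conditions is
  $100\,(\mathrm{UD} - \mathrm{NS})/\mathrm{NS}$, so reduced stereotypy
  after singing shows up as a negative shift; a zero reference value is an
  error.
* **Degenerate inputs.** A repertoire of one syllable has $H_{\max} = 0$
  and is assigned normalized entropy 0 (the sequence is trivially fixed);
  floating-point overshoot of $H$ over $H_{\max}$ is clamped only within
  $10^{-12}$, anything larger is treated as inconsistent input.

## Phonological variability

For each selected syllable, 25 consecutive renditions are measured on
seven acoustic features (duration, amplitude, pitch, FM, Wiener entropy,
mean frequency, pitch goodness). `featureSummary()` reports mean, sample
SD ($n-1$ denominator; the convention for 25-rendition samples), SE, and
the **coefficient of variation** CV $= \mathrm{SD}/|\mathrm{mean}|$.
The magnitude is used because Wiener entropy lives on a nonpositive scale
and its variability is conventionally reported as a positive CV; for
positive features this is the ordinary SD/mean. A zero mean leaves the CV
undefined (`NA` with a warning).

Whether scores are aggregated per bird (`per_bird_then_group`) or across
all syllables (`per_syllable`) is an empirical question — which factor is
the independent unit — answered by the permutation ANOVA below.

All-vs-all **score batches** (20 motifs $\to 20^2 - 20 = 380$ scores; 30
one-second clips $\to 870$) are summarized by their off-diagonal mean and
naive SE, acknowledging that pairwise scores are not independent; identity
is similarity $\times$ accuracy $/ 100$, computed per syllable *before*
any averaging.

The **trajectory scorer** is a deliberately simplified feature-trajectory
analogue of spectrogram-based song comparison, not a replication of any
external tool: frames of (pitch, FM, Wiener entropy, pitch goodness) are
scaled by pooled per-feature median absolute deviations, the Euclidean
distance $d$ between scaled frames maps to a local score
$100\,e^{-d/\tau}$ with $\tau = 1/\ln 2$ calibrated so one scaled unit of
distance scores 50, accuracy is the mean local score over aligned 9 ms
frames, and similarity is the mean over 70 ms windows — each window either
compared in place (symmetric) or against its best-matching window at any
offset (asymmetric, "most similar elements independent of position"). All
three constants (`tau`, `windowMs`, frame period) are arguments.
`stabilizeSampleCount()` reproduces the empirical sample-size procedure:
grow the sample from 10 in steps of 5 until the mean scores stop changing
(default: two consecutive increments moving every mean by < 0.5 score
units — the tolerance is ours, chosen at the resolution at which published
scores are read).

## Resampling inference

**Sign-flip paired bootstrap.** The statistic is $M$, the group mean of
the per-bird conditional differences. Each iteration multiplies the
difference vector elementwise by independent random $\pm 1$ draws and
records the mean; 10,000 iterations build the null distribution of $M$
under direction-randomization. The two-tailed p-value counts null means at
or beyond the critical values ($M$ and its reflection across the null
mean), inclusively — inclusive counting is conservative and matches exact
test conventions. The reflection point is the null distribution's *true*
mean, exactly 0 by the symmetry of the sign flips: reflecting across the
jittery sample mean instead would decide by coin flip whether the null
atom at $-M$ is counted, and the p-value would then fail to converge to
the exhaustive $2^n$ enumeration that defines the test.

```{r}
d <- c(0.9, 1.6, 0.1, 1.2, 0.8, 1.4, 0.3, 1.1, 0.7, 1.0, 0.5)
pairedSignflipBootstrap(d, seed = 1)
```

**Absolute-deviation permutation ANOVA.** To decide the independent unit
(bird vs syllable) the one-way ANOVA statistic is computed from absolute
deviations rather than squares:
$\left[\sum_g n_g\,|\bar{x}_g - \bar{x}|\right] /
\left[\sum_g \sum_i |x_{gi} - \bar{x}_g|\right]$.
Group-size weighting of the between term mirrors the sums-of-squares
analogy; `weighted = FALSE` gives plain sums. The null permutes group
labels (direction has no meaning for $k$ groups), and the upper-tail
p-value is counted inclusively. Zero observed within-group variability
makes the statistic infinite; the p-value is then the share of
permutations that are equally degenerate.

**Wilcoxon cross-check.** Significance calls of the bootstrap are
cross-flagged with the standard two-tailed signed-rank test
(`stats::wilcox.test`), used only as a check at the same $\alpha$.

**Power analysis.** `powerSimulation()` estimates power by Monte Carlo:
draw `nProspective` differences from the observed vector (with
replacement; a Gaussian parametric option uses the observed mean and SD),
run the sign-flip test, repeat, and report the rejection fraction at
$\alpha$. The nonparametric default uses only the quantities the test
itself uses. Power responds to the three design factors — within-group
variability, between-condition difference, and the number of birds — and
supports the prospective question "would doubling the number of birds
help?".

## The synthetic generator: what it emulates and what it does not

`makeTransitionMatrix(n, epsilon)` builds the mixture chain: syllable $i$
goes to its cycle successor with probability $(1-\varepsilon) +
\varepsilon/n$ and anywhere (itself included) with $\varepsilon/n$. This
is the simplest one-parameter family spanning normalized entropy 0
($\varepsilon = 0$, a perfectly stereotyped motif cycle) to 1
($\varepsilon = 1$), and its row entropy has a closed form
(`chainEntropy()`), making it an exact oracle for the estimators.

`makePairedDataset()` emulates the paired design with the study's
dimensions as defaults, fixed once and not revisited: 11 birds (the
75-day cohort), 5 syllables, 20 motifs and 300-syllable strings per
condition, 25 renditions per syllable, condition epsilons 0.2 (`NS-UD`)
and 0.4 (`UD-UD`) giving the 0.2 practice-induced gap used in the recovery
studies, per-condition bird-level epsilon noise of SD 0.05 (chosen so that
between-bird scatter is comparable to, not dominant over, the condition
effect — inflating it emulates the noisy 65-day regime where power
collapses), NS-UD feature CVs at the published 75-day scale (pitch 0.074
etc.) and UD multipliers at the published UD/NS ratios.

What the generator does **not** emulate: real zebra-finch syntax is not
first-order stationary (motif onsets, introductory notes, higher-order
dependencies), syllable repertoires drift over development (merges and
splits), and acoustic features covary within a rendition while the
generator draws them independently. Passing recovery tests therefore shows
that the estimators and tests are correct *for data of the assumed form*,
not that real song satisfies these assumptions.

## Problem sizes in the test suite

The suite validates stochastic claims at sizes chosen to balance
Monte-Carlo resolution against runtime: exact sign-flip enumeration up to
$n = 12$ (4096 sign vectors), estimator consistency at string length
3,000 over $\varepsilon \in \{0, .25, .5, .75, 1\}$, type-I calibration
over 1,000 Gaussian-null datasets of 11 birds (2,000 flips each), and
end-to-end recovery over 200 replicate paired datasets with and without
the 0.2 epsilon gap. At these sizes the binomial Monte-Carlo error of each
checked rate is well below the asserted margins.

## Known limitations

* First-order chains only; no higher-order or hidden-state syntax models.
* The trajectory scorer is a simplified analogue — its absolute scores are
  not comparable to spectrogram-based tools, only its orderings.
* The naive SE over all-vs-all score batches ignores the dependence among
  pairs sharing an item.
* No multiple-testing correction is applied anywhere, matching the
  analysis design this package reproduces.
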