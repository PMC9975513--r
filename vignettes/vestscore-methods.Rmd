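---
title: "Scoring and phenotyping the audio-vestibular battery in sudden sensorineural hearing loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and phenotyping the audio-vestibular battery in sudden sensorineural hearing loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vestscore)
```

## The clinical problem

Sudden sensorineural hearing loss (SSNHL) — a loss of at least 30 dB over at
least three contiguous audiometric frequencies appearing within 72 hours —
is idiopathic in most patients, but the pattern of accompanying vestibular
damage carries two kinds of information. Prognostically, the more inner-ear
receptors are impaired, the worse the hearing outcome tends to be.
Mechanistically, particular combinations of cochlear and vestibular deficits
match the territories of the arteries feeding the inner ear, so a bedside
test battery can raise the suspicion of a labyrinthine ischemia, while
low-frequency loss with enhanced or 1-kHz-tuned otolith responses points
toward endolymphatic hydrops (Menière's disease).

`vestscore` implements the scoring rules, patient-level classifiers and
cohort-level statistics for this battery: pure-tone audiometry, cervical and
ocular vestibular-evoked myogenic potentials (cVEMP/oVEMP, indexing the
saccule and utricle), and the video head-impulse test (vHIT, indexing the
three semicircular canals). Because per-patient clinical data of this kind
are rarely redistributable, the package also ships a seeded synthetic-cohort
generator that emulates the three-subgroup study structure, so the entire
pipeline is testable end to end.

## Audiometric scoring

**PTA.** The pure-tone average is the mean of the bone-conduction thresholds
of the *four most impaired contiguous frequencies* on the 250–4,000 Hz grid
(`compute_pta()`). An anacusic ear is assigned 120 dB by convention. When two
contiguous windows tie, the higher-frequency window is used (SSNHL cohorts
are predominantly down-sloping or flat); `tie = "low"` flips this.

**Degree.** Mild (PTA ≤ 40 dB), moderate (40 < PTA ≤ 70), severe
(70 < PTA ≤ 90), profound/anacusis (PTA > 90); boundaries inclusive on the
milder side.

**Configuration.** The qualitative low-frequency / high-frequency / flat
typing has no universally fixed numeric rule; `classify_configuration()`
compares the mean air-conduction threshold of the 125–500 Hz band with the
2,000–8,000 Hz band and calls a configuration when one band dominates by at
least `delta` dB. The default `delta = 15` dB is a common audiological
convention and is exposed as an argument. Down-sloping audiograms are
`high_frequency` throughout.

**Eligibility.** `check_ssnhl_eligibility()` scans for ≥ 3 consecutive
frequencies with ≥ 30 dB loss. By default the loss is measured *relative to
the contralateral ear*: cohorts of this kind exclude prior hearing loss in
the affected ear, so the healthy ear is the best available premorbid
reference. An absolute-threshold mode (`mode = "absolute"`) is provided for
data where that assumption fails.

**Recovery.** From the admission exam's PTA window `W`,
`PTApost` and `PTAcontra` are recomputed *on the same frequencies* at the
6-month follow-up and on the (admission) contralateral ear. Recovery is
*complete* when `PTApost ≤ PTAcontra + 10` with a follow-up word-recognition
score above 50%, *partial* when the PTA improved by more than 10 dB without
returning within 10 dB of the unaffected ear (again WRS > 50%), and *none*
otherwise. The "within 10 dB" comparison is inclusive, and is made between
PTAs (a per-frequency reading is possible but under-determined by the
criterion). The percent recovery

$$\%\,\mathrm{recovery} = \frac{PTA_{pre} - PTA_{post}}{PTA_{pre} - PTA_{contra}} \times 100$$

is reported *unclipped* — values above 100 (over-recovery) or below 0
(deterioration) are informative for quality control — alongside a
`[0, 100]`-clipped version used in the trend analysis. When
`PTApre ≤ PTAcontra` there is no measurable deficit and the ratio is
undefined (`NA` with a warning). For an anacusic admission ear every
frequency is maximally impaired; the follow-up exam's own worst window
defines the comparison frequencies. Only the 6-month exam scores the
outcome; other timepoints are stored but not scored.

## Vestibular scoring

**Asymmetry ratio.** For each VEMP modality,

$$AR = \frac{A_{contra} - A_{ipsi}}{A_{contra} + A_{ipsi}} \times 100,$$

on the 500-Hz peak-to-peak amplitudes (the primary stimulus; 1-kHz cVEMP
amplitudes serve only the tuning call). An otolith receptor is *impaired*
when AR ≥ 33% (inclusive) or when responses are bilaterally absent; a
unilateral absent response flows through the AR = ±100 path rather than a
separate rule. AR ≤ −33% marks an *enhanced* response of the affected ear, a
hydrops signature; cVEMP *frequency tuning* is positive when the 1-kHz
amplitude is at least as large as the 500-Hz amplitude (difference ≥ 0 μV).
Both-zero amplitudes make the ratio undefined; callers must use the
bilateral-absence rule.

**Canals.** A semicircular canal is impaired when its VOR gain falls below
the canal-specific cut-off (0.8 horizontal, 0.7 anterior/posterior) *and*
corrective saccades are present — the conjunction matters: an isolated low
gain without saccades is classed spared. Gains exactly at the cut-off are
spared.

**Lesion patterns.** `build_lesion_pattern()` combines the five calls into
otolith (`none`/`S`/`U`/`S_U`), canal (subset label) and end-organ patterns
with the receptor count 0–5 that drives the prognosis analyses.

## Phenotyping

**Subgroups.** Menière's disease takes precedence (2015 diagnostic criteria
supplied as an input flag — they are not re-implemented — or
fluctuating/relapsing hearing loss with vestibular symptoms during
follow-up), then `ssnhl_vertigo` (vestibular symptoms simultaneous with the
loss), else `ssnhl_no_vertigo`.

**Arterial ("vascular") patterns**, evaluated in order IAA → CCA → VCA:

| Pattern | Hearing loss | Vestibular requirement |
|---|---|---|
| IAA (internal auditory a.) | severe/profound | all five receptors impaired (strict) |
| CCA (common cochlear a.) | severe/profound | saccule + PSC impaired; HSC, ASC spared |
| VCA (vestibulo-cochlear a.) | high-frequency | saccule + PSC impaired; HSC, ASC spared |

Three choices here were genuinely open. (1) The IAA definition is stated
once loosely ("both otolith and SC impairment") and once strictly (cVEMPs,
oVEMPs and all three canal gains impaired); the strict version is the
default and the loose one (`iaa_rule = "loose"`: both otolith organs plus at
least one canal) a switch. (2) CCA and VCA additionally require HSC and ASC
spared — not stated explicitly in the source criteria but implied by the
arterial anatomy and needed to keep the three labels mutually exclusive.
(3) The rule order encodes that a severe down-sloping loss with the
saccule+PSC pattern reads as CCA, not VCA. The utricle is free to vary in
CCA/VCA ("with or without concurrent abnormal oVEMPs"). A utricle + lateral
canal pattern with spared PSC (anterior vestibular artery territory) has no
published rule and stays `none`.

**Risk score.** Count of six cardiovascular risk-factor booleans
(hypertension, hypercholesterolemia, prior cardio/cerebrovascular disease,
diabetes, BMI > 25, smoking) plus one when any cardiovascular-disease
laboratory biomarker is out of range: 0–7.

## Cohort statistics

Tabulations report counts and column percentages rounded *half-up* to one
decimal — the printed style of clinical tables (`percent_of(39, 86)` is
45.3). Categorical comparisons use the uncorrected Pearson chi-square, or
Fisher's exact test for 2×2 tables with any expected count below 5; the
method is recorded. Group medians are compared with the tie-corrected
Kruskal–Wallis test, followed by Dunn's pairwise z-tests with Bonferroni
(default) or Holm adjustment. The receptor-count/recovery trend is the
Spearman correlation plus per-stratum means. The recovery regression is a
binomial GLM of dichotomized outcome on impairment flags; the outcome coding
is not fixed by the source criteria, so both *any recovery vs none*
(default) and *complete vs not* are available, and joint or single-predictor
modes. Constant predictors are dropped with a warning; suspected complete
separation (divergent estimates) is flagged and coefficients are withheld
rather than reported. α = 0.05 throughout.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions, not any particular
patient:

* **Subgroups** drawn with probabilities 0.291 / 0.314 / 0.395
  (no-vertigo / vertigo / MD).
* **Receptor impairment** drawn per subgroup from the configured
  prevalences. Headline values are taken from the reported subgroup
  fractions (saccule 74.1% and PSC 55.6% in the vertigo subgroup; ASC never
  impaired without vertigo); the remaining cells are back-filled so the
  prevalence-weighted marginals reproduce the overall cohort fractions
  (saccule 39/86, utricle 37/86, HSC 14/86, ASC 10/86, PSC 18/86).
* **VEMP amplitudes** are drawn to *respect the classifier boundaries*: an
  impaired otolith is bilaterally absent with probability 0.3, otherwise the
  contralesional amplitude comes from a lognormal and the ipsilesional one
  from AR ~ Uniform(33.5, 100) (absent above 95); spared receptors draw
  AR ~ Uniform(−28, 28), or Uniform(−95, −34) for the enhanced-response
  minority. The 0.5%-point margins at the ±33 cut-offs absorb the 2-decimal
  amplitude rounding, which is what makes the generator→scorer round trip
  exact. Gains follow the same logic around the 0.8/0.7 cut-offs, including
  a small mass of isolated low gain without saccades and saccades at normal
  gain (both spared).
* **Audiograms** are built from configuration-shaped templates scaled to a
  degree-specific target PTA (5-dB steps, Gaussian jitter), with the
  configuration's defining band forced ≥ 35 dB above the contralateral ear
  so every record passes the eligibility screen; profound ears are anacusic
  with probability 0.4.
* **Recovery** is `clip(75 − 12 × n_receptors + N(0, 20), 0, 100)` percent;
  base, penalty and noise chosen once to produce the reported strong
  negative receptor-count trend with realistic scatter. The 6-month
  thresholds interpolate between admission and contralateral values at that
  fraction, so re-scoring recovers the latent percentage up to whole-dB
  rounding.
* **Draw order** is fixed per patient (subgroup → lesion flags → amplitudes
  → gains → audiogram → recovery → covariates), so extending `n_patients`
  never perturbs earlier patients, and a fixed seed gives a bit-identical
  CSV.

Latent truth (`subgroup`, `lat_*`, `lat_pct_recovery`) is stored in
dedicated columns, clearly synthetic provenance rather than observable
clinical data.

What the generator does *not* emulate: correlations between receptors
beyond the subgroup structure (flags are conditionally independent given
subgroup — the published pattern bar-plots suggest mild dependence),
association between lesion pattern and audiogram shape within subgroup,
measurement drift between admission and follow-up on the healthy ear, and
any waveform/trace-level realism. Passing tests therefore demonstrate the
*scoring and statistical machinery*, not distributional fidelity to any
real cohort.

```{r}
scored <- score_cohort(generate_cohort(cohort_config(n_patients = 300,
                                                     seed = 42)))
recovery_trend(scored)$strata
```

## Numerical choices and degenerate inputs

* PTA window ties break toward high frequencies (configurable).
* Percentages round half-up (with a 1e-9 guard against binary
  representation error); R's default half-to-even would print 12.4 where a
  clinical table prints 12.5.
* AR with both amplitudes zero, recovery without measurable deficit, a
  single receptor-count stratum, and degenerate contingency margins are all
  signalled (`NA` + warning, or an error naming the problem), never
  silently imputed.
* Thresholds are validated to [−10, 120] dB, gains to [0, 1.5], WRS to
  [0, 100] at construction and again at CSV ingest; malformed cells are
  collected and reported together.

## Problem sizes

The test-suite simulations use cohorts of 200–5,000 patients: 5,000 for
prevalence parameter recovery (3 binomial SE), 2,000 for the null trend and
regression parameter recovery, 500 for the negative recovery trend, and
smaller cohorts for pipeline smoke tests — sizes at which the checked
binomial/rank statistics have comfortable power.

## Limitations

Raw signal processing is out of scope by design: VEMP peak picking, vHIT
trace analysis and MRI reading happen upstream, and this package consumes
their outputs (amplitudes, gains + saccade flags, Fazekas grade 0–3).
Menière's criteria arrive as a boolean. The vascular labels are
*instrumental patterns consistent with* arterial territories, not verified
infarcts; venous patterns and the anterior-vestibular-artery territory have
no rule. With ~10²-patient cohorts, Fisher/chi-square and Kruskal–Wallis
are the honest tools; the logistic regression with several sparse binary
predictors can separate, and the package flags rather than "fixes" that.
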