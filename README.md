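# vestscore

Audio-vestibular scoring and phenotyping for sudden sensorineural hearing
loss (SSNHL) cohorts.

Patients with SSNHL routinely receive a full vestibular work-up alongside
audiometry: cervical and ocular vestibular-evoked myogenic potentials
(cVEMP/oVEMP, probing the saccule and utricle) and the video head-impulse
test (vHIT, probing the three semicircular canals). The pattern of combined
cochlear and vestibular damage predicts hearing recovery and can flag an
underlying labyrinthine ischemia or early endolymphatic hydrops.
`vestscore` is for clinical researchers who need those scoring rules,
classifiers and cohort statistics as reproducible, tested code.

## What it computes

**Scoring** (per patient)

* PTA as the mean bone-conduction threshold of the four most impaired
  contiguous frequencies; 120 dB for anacusis. Degree: mild ≤ 40 <
  moderate ≤ 70 < severe ≤ 90 < profound. Configuration
  (low-/high-frequency/flat) by a 15-dB band-mean criterion.
* SSNHL eligibility: ≥ 30 dB loss at ≥ 3 consecutive frequencies.
* VEMP asymmetry ratio `AR = (A_contra − A_ipsi)/(A_contra + A_ipsi) × 100`;
  otolith impaired when AR ≥ 33% or responses bilaterally absent; enhanced
  when AR ≤ −33%; cVEMP frequency tuning positive when the 1-kHz amplitude
  ≥ the 500-Hz amplitude.
* Canal impairment: VOR gain < 0.8 (HSC) / 0.7 (ASC, PSC) *with* corrective
  saccades.
* Hearing recovery at 6 months: complete / partial / none, and
  `% recovery = (PTA_pre − PTA_post)/(PTA_pre − PTA_contra) × 100` on the
  admission PTA window.

**Phenotyping**: clinical-course subgroup (SSNHL without vertigo, SSNHL +
vertigo, Menière's disease), arterial lesion patterns
(VCA / CCA / IAA / none), cardiovascular risk score 0–7.

**Cohort statistics**: contingency tables with clinical-style percentages
(half-up, 1 decimal), Pearson chi-square / Fisher exact, Kruskal–Wallis with
Dunn–Bonferroni post-hoc, receptor-count vs percent-recovery Spearman trend,
logistic regression of recovery on impairment flags.

**Synthetic cohorts**: a seeded generator reproducing the three-subgroup
study structure (configurable prevalences, hearing-loss mixtures, recovery
model), boundary-consistent with the classifiers so generated data re-score
to their latent truth exactly.

## Worked example

```r
library(vestscore)

# PTA of a down-sloping audiogram: the 500-4000 Hz window wins
ex <- audiogram(bc = c(`250` = 30, `500` = 40, `1000` = 50,
                       `2000` = 60, `4000` = 70))
compute_pta(ex)
#> [1] 55
#> attr(,"window")
#> [1] "500"  "1000" "2000" "4000"
classify_degree(55)
#> [1] "moderate"

asymmetry_ratio(8, 4)   # contralesional 8 uV, ipsilesional 4 uV
#> [1] 33.33333            # >= 33: the otolith is called impaired

# A published-style case: high-frequency loss, absent ipsilesional cVEMP,
# selective PSC impairment (gain 0.42 with saccades)
score_cohort(make_worked_example("vca"))[
  , c("degree", "configuration", "cvemp_ar", "ovemp_ar",
      "n_receptors", "vascular_pattern")]
#>   degree   configuration  cvemp_ar ovemp_ar n_receptors vascular_pattern
#> 1 moderate high_frequency      100       29           2 VCA

# End to end on a simulated 300-patient cohort
res <- run_pipeline(cohort_config(n_patients = 300, seed = 42))
res$report$trend$strata
#>   n_receptors   n mean_pct
#> 1           0  64 71.64784
#> 2           1 115 61.82521
#> 3           2  69 50.77592
#> 4           3  32 37.45840
#> 5           4  18 30.42743
#> 6           5   2 11.26598
```

The strata table is the package's core prognostic readout: mean percent
hearing recovery falls steadily with the number of impaired vestibular
receptors (here from ~72% with an intact labyrinth to ~11% with all five
receptors damaged; `res$report$trend$rho` is −0.54, p < 2e-16 on this
cohort). The `VCA` label marks the combination — high-frequency loss,
saccular and posterior-canal impairment with the other canals spared —
consistent with ischemia of the vestibulo-cochlear artery territory.

A thin CLI wraps the same functions:

```sh
vestscore simulate  --n 500 --seed 42 --out cohort.csv
vestscore phenotype --in cohort.csv --out phenotypes.csv
vestscore analyze   --in cohort.csv --out report/
vestscore fixtures  --out fixtures.csv   # the three worked-example patients
```

See `vignettes/vestscore-methods.Rmd` for the full account of the rules,
the generator's design and its limitations.

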