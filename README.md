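# ichnometry

Biometric inference from fossil human footprints.

Ichnology reads the biology of extinct trackmakers from the traces they
left. For human footprints, a handful of well-calibrated allometric
relations turn simple landmark measurements — digit-tip to heel-baseline
lengths, ball and heel widths, the arch angle — into estimates of the
producer's stature, body mass and age class, while multivariate shape
analysis of the same measurements groups the footprints into *morphotypes*
(sets of prints attributable to one producer) and yields a minimum number
of individuals (MNI) for the assemblage.

`ichnometry` implements this pipeline for palaeoanthropologists and
ichnologists working with measurement tables rather than raw 3D scans. It
ships the published measurement tables of the Upper Palaeolithic trackway
record of the Bàsura cave (Toirano, Italy) as packaged fixtures and
reproduces that study's per-footprint and per-morphotype results.

## The models

* **Stature from foot length.** S = FL / R with R = 0.1541, the
  foot-length/stature ratio calibrated on terminal Upper Palaeolithic
  adults from the Italian peninsula. A cross-check from kneeling traces
  uses the percutaneous tibial length: S = 101.85 + 1.81·PCTL ± 3.73 cm
  (males), S = 77.86 + 2.36·PCTL ± 2.94 cm (females).
* **Body mass from foot length.** Three calibrations, routed by size
  class: m = 2.2897·e^(0.126·FL) kg (children), m = 4.71 + 1.82·FL kg
  (adults 154–185 cm), m = −71.142 + 5.259·FL kg (children/adolescents
  averaging 147.44 cm, admissible for FL > 13.53 cm).
* **Age from foot growth.** Point age by interpolation between the
  juvenile anchors FL(1 yr) = 13.07 ± 1.59 cm and FL(13 yr) = 24.4 ±
  2.96 cm, binned into the report classes `<3`, `5-6`, `8-11`,
  `>14 - adult`; arch-angle development bands (21°–43° males, 26°–47°
  females over ages 3–4 to 9–11) annotate consistency.
* **Morphotypes / MNI.** Nine anatomical lengths and widths per footprint
  are log-transformed; missing cells are completed by iterative PCA
  imputation; footprints are grouped by Ward clustering on a unit-free
  log-measurement distance, with the tree cut at a calibrated fraction of
  its height. The number of groups is the MNI under the
  one-producer-per-morphotype assumption.
* **Sex.** A deliberately conservative rule table: only the largest
  adult-class group with a stout profile (mean foot index ≥ 0.40) and an
  observed arch angle earns a `probable_male` call; every call is flagged
  low-confidence.

## Worked example

```r
library(ichnometry)

t3  <- load_basura_fixtures("table3")     # 26 best-preserved footprints
asg <- published_morphotypes(t3)
prof <- profile_individuals(t3, asg)
prof
#> Biometric profile: 5 producer group(s)
#>   group 1 (n=4): stature 87.93 ± 3.20 cm, age <3, sex indeterminate
#>   group 2 (n=3): stature 110.32 ± 0.00 cm, age 5-6, sex indeterminate
#>   group 3 (n=8): stature 135.19 ± 3.33 cm, age 8-11, sex indeterminate
#>   group 4 (n=7): stature 147.96 ± 2.75 cm, age >14 - adult, sex indeterminate
#>   group 5 (n=4): stature 166.99 ± 2.93 cm, age >14 - adult, sex probable_male
```

Five producers: a small child (~88 cm), an older child (~110 cm), a
pre-adolescent (~135 cm), a sub-adult/adult (~148 cm) and an adult male
(~167 cm). The same partition emerges without the published labels, from
the measurements alone:

```r
t4 <- load_basura_fixtures("table4")      # the nine PCA variables, 23 prints
asg2 <- group_morphotypes(t4)             # Ward on log measurements
minimum_individuals(asg2)
#> [1] 5
```

The tibia cross-check for the tallest group:

```r
stature_from_tibia(35, "male")$stature    # 165.2, within ±3.73 of 166.99
```

`run_pipeline("basura-fixture", out_dir = "out")` writes the per-footprint
and per-group CSV reports, the PCA exports and a JSON run manifest; the
same pipeline is scriptable from a shell via `exec/footprint-profile`.

Synthetic trackways with known ground truth support parameter-recovery
experiments:

```r
rec <- recovery_experiment(5, scenario = track_scenario(5, noise_cv = 0.03),
                           n_reps = 100, seed = 2024, stature_cv = 0,
                           ages = c(2, 4, 6.5, 10, 20))
rec$mni_accuracy
#> [1] 1
```

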