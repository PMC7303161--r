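# rvkinergy

Quantification of right-ventricular (RV) blood-flow kinetic energy and
tricuspid through-plane flow from 4D flow cardiovascular MR, with an
analytic flow phantom and synthetic-cohort machinery for validation.

RV diastolic dysfunction — stiffening and impaired relaxation of the right
ventricle — matters prognostically in pulmonary hypertension, pulmonary
embolism and heart failure, yet routine imaging has no reliable measure of
it. 4D flow CMR acquires a time-resolved three-directional velocity field
over the whole heart; from it this package computes, per cardiac phase,
the intracavity kinetic energy

> KE = ½ · ρ_blood · V_voxel · v_voxel²  (ρ_blood = 1.06 g/cm³; erg → µJ × 0.1)

summed over a time-resolved RV cavity mesh built from short-axis
endocardial contours, normalised to end-diastolic volume (KEi_EDV, µJ/ml),
and condensed into six physiological parameters: global, systolic,
diastolic, minimum, peak E-wave, peak A-wave and the E/A peak ratio — the
candidate marker of RV diastolic function. Alongside, tricuspid inflow is
quantified by retrospective valve tracking: through-plane velocity on a
plane that follows the annulus perpendicular to inflow, with myocardial
background correction, giving tricuspid stroke volume and E/A inflow
velocities. Cohort-level machinery reproduces the standard association
analysis (Spearman correlations with age, sex t-tests, Kruskal–Wallis with
Dunn letters over age groups, forward-conditional regression, Lin's
concordance and coefficient of variability for observer reproducibility).

Because no subject-level data of this kind are publicly deposited, the
package ships a first-class synthetic-data module: a solid-of-revolution
flow phantom with a three-peak velocity program and closed-form KE truth,
volumetrically closed so that valve-plane stroke volume must equal the
cine volume change, and Gaussian-copula cohort simulation with programmed
age effects. See the methods vignette
(`vignettes/rv-kinetic-energy.Rmd`) for the model, conventions and
limitations.

## Worked example

Run the full single-subject pipeline on the default healthy-range phantom
(EDV 150 ml, ESV 60 ml, 30 phases, 3 mm voxels, VENC 150 cm/s):

```r
library(rvkinergy)
res <- run_subject(list(phantom = list(), seed = 1))
#> [rvkinergy] phantom generated: EDV 150.0 ml, ESV 60.0 ml, 30 phases
#> [rvkinergy] cine volumes: EDV 149.9 ml, ESV 60.0 ml, EF 60.0% (ES phase 12)
#> [rvkinergy] RV masks: 2152..5388 voxels per phase
#> [rvkinergy] KE: global 31.73, peak E 74.88, peak A 63.69 uJ/ml (E/A 1.176)
#> [rvkinergy] TV flow: SV 91.7 ml, peak E 49.5 / peak A 37.7 cm/s

res$ke_parameters
#> <ke_parameters> (uJ/ml)
#>   global 31.73 | systolic 43.53 | diastolic 23.86 | min 0.00
#>   peak E 74.88 | peak A 63.69 | E/A ratio 1.176

res$tv_flow
#> <tv_flow_curve> TV SV 91.7 ml; peak E 49.5 cm/s, peak A 37.7 cm/s, E/A 1.312
```

Reading the numbers: the cine-derived ejection fraction is 60% with
end-systole at phase 12, as programmed. The tricuspid stroke volume
(91.7 ml) agrees with the cine volume change (89.9 ml) to 2% — the
phantom is volumetrically closed, so this gap measures pipeline error,
not physiology. The peak inflow velocities recover the programmed
50/38 cm/s program at the 30 ms phase sampling, and the KEi_EDV E/A ratio
of 1.176 matches the phantom's closed-form truth for these settings (the
phantom's KEi_EDV magnitudes are higher than typical in vivo values
because a uniform-speed cavity has no slow-flow interior). To target a
specific E/A ratio, calibrate the A-wave speed:

```r
spec <- calibrate_phantom_ea(phantom_spec(), 1.51)   # healthy-cohort mean
```

Cohort-level analysis on a synthetic 53-subject cohort with programmed
age effects:

```r
rep <- run_cohort(list(cohort = list(n_subjects = 53), seed = 3,
                       out_dir = "cohort_out"))
rep$correlations          # Spearman r and p per metric vs age
rep$regression$selected   # forward-conditional multivariate model
```

which writes the four standard tables (descriptives, correlations,
regression, age groups) as CSV plus a JSON report.

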