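# rtplanscore

Computational back-end for a knowledge-model tutoring system for
lung/mediastinum IMRT treatment planning, written for medical-physics
educators and researchers who want a scriptable, clinical-data-free
environment to score plans, predict achievable organ sparing, and reason
about beam geometry.

A trainee (or a script) produces a plan; the package answers three
questions the tutoring loop keeps asking:

1. **How good is this plan?**  A DVH engine computes the standard metrics
   — Dx%, VxGy, mean/max/min dose, the conformity index
   CI = V(50% isodose)/V(PTV), the Paddick conformation number
   CN = TV<sub>PIV</sub>² / (TV × PIV), max-dose location — and an
   18-metric rubric awards up to 164 points (target 75, lung 35, heart 22,
   esophagus 12, cord 20), normalized to a percentage score
   100 × raw / 164.
2. **What should be achievable?**  A knowledge-based model predicts each
   OAR's achievable DVH from anatomy: distance-to-target-histogram (DTH)
   principal components plus OAR/PTV/overlap volumes and the out-of-field
   fraction, mapped to DVH principal components by least squares.
3. **Where should beams go?**  Coplanar gantry angles are ranked by an
   efficiency index — attenuated fluence reaching the PTV divided by
   weighted, attenuation-weighted OAR path lengths — and a bouquet of 7–11
   beams is picked greedily under a forced angular separation.

Because no clinical data ships with the package, a parametric thorax
phantom (body/lungs/heart/esophagus/cord/PTV/GTV/cord+3 mm) and a
simplified beam-dose synthesizer generate everything the models and tests
need, including cohorts spanning an easy-to-hard case spectrum.  DICOM-RT
(RTDOSE/RTSTRUCT) adapters and a bit-exact native `.rtcase` format handle
I/O.

## Worked example

```r
library(rtplanscore)

case    <- make_thorax_phantom(reference_case_specs()$benchmark)
profile <- rank_beams(case, beam_config(max_ptv_rays = 1500))
bouquet <- select_bouquet(profile, n_beams = 9)
bouquet
#> <beam_bouquet: 9 beams at >=20 deg separation: 345, 175, 5, 195, 155, 325, 25, 215, 135>

case$dose <- synthesize_plan_dose(case, bouquet)
score_plan(case, plan_label = "synthesized")
#> <score_report case 'benchmark' plan 'synthesized': raw 88.08 / 164 (53.71%)>

dvh <- compute_dvh(case$dose, case$structures$lungs, structure = "lungs")
volume_at_dose(dvh, 20)   # lung V20 of this plan: 23.0 (%)
```

The bouquet favours anterior/posterior-oblique angles that cross little
lung on the way to the mediastinal target; the synthesized 9-beam plan
earns 88.08 of 164 points (53.71%), losing most of its deficit on the cord
maxima, conformity (CN95) and heart dose — exactly the metrics a trainee
would iterate on next.  The
lung V20 of 23.0% sits between the rubric's full-credit (20%) and
zero-credit (37%) thresholds.

Score arithmetic on published-style score tables is bundled for
validation: `percentage_score(89.54)` → 54.60, and averaging the bundled
five-trainee tables reproduces their study summaries (initial 21.6%, final
51.8%, mean improvement 12.6 raw points).

## Layout

- `R/` — containers & I/O (`geometry.R`, `rtcase.R`, `dicom.R`), DVH
  engine (`dvh.R`, `rasterize.R`, `distance.R`), scoring (`scoring.R`),
  DVH prediction (`kbp.R`), beam selection (`beams.R`), synthetic data
  (`phantom.R`, `dose_synth.R`, `cohort.R`), reporting and CLI
  (`report.R`, `cli.R`)
- `src/` — exact anisotropic Euclidean distance transform and ray marching
  (Rcpp)
- `inst/extdata/` — default rubric and alias YAMLs, bundled study score
  tables
- `vignettes/rtplanscore-methods.Rmd` — models, assumptions, parameters
  and design decisions
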