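# kneemark

Automated anatomical landmarking and morphometry for 3D surface meshes of
the distal femur and proximal tibia.

Landmark-based knee morphometry (implant sizing, meniscal allograft
matching, morphological risk-factor analysis) needs 23 named points — the
posterior/distal condyle extremes, trochlear and epicondylar points, notch
constructions, tibial eminences, plateau rims — placed on bone+cartilage
surface meshes, and 15 linear sizes derived from them. Manual annotation is
slow and operator-dependent. `kneemark` automates it with a template-based
pipeline:

1. **Dense correspondence.** A template mesh is rigidly aligned (ICP with a
   point-to-plane polish) and then elastically deformed onto every subject,
   minimizing
   `Σᵢ wᵢ‖vᵢ + dᵢ − cᵢ‖² + α Σ₍ᵢⱼ₎∈E ‖dᵢ − dⱼ‖²`
   over a per-vertex displacement field `d` with a decreasing stiffness
   schedule, distance/normal compatibility gating and a symmetric data
   term. The deformed template imposes its topology on each target, so
   vertex *i* marks the same anatomical spot on every knee. A second pass
   re-registers the cohort **mean shape** to all subjects.
2. **Landmark propagation.** Expert annotations are carried through the
   correspondences onto the mean shape, pooled with equal observer
   weighting (repeats averaged first), snapped to mean-shape vertices, and
   propagated back to each subject — in leave-one-out fashion when
   validating, so a subject's automated landmarks never see its own manual
   labels.
3. **Extremum refinement.** Landmarks defined as locally extreme positions
   (most anterior/posterior, medial/lateral, proximal/distal) are moved to
   the most extreme mesh vertex within a bounded geodesic radius of the
   propagated seed.
4. **Morphometry.** Measurements are axis projections `|aₐₓ − bₐₓ|` in a
   reference frame whose x axis is the femoral posterior condylar line
   (FMCP–FLCP) projected into the axial plane, z the scanner table
   direction, y = z × x.
5. **Agreement statistics.** Intra-/inter-observer and manual-vs-automated
   errors, quartile summaries with the 1.5·IQR outlier rule, ICC(A,1) from
   the two-way ANOVA mean squares (mixed/random label), Bland–Altman
   limits (bias ± 1.96 SD), and success-rate-at-tolerance curves.

Because no clinical data ship with the package, a synthetic phantom module
generates condyle-like surfaces (ellipsoid + Gaussian lobes, shaft-cropped)
with analytic ground-truth landmarks and closed-form measurements, plus
simulated expert panels with tangent-plane annotation noise — enough to
rehearse and validate the entire pipeline end to end.

## Worked example

Generate a femur-like phantom and inspect its analytic truth:

```r
library(kneemark)
ph <- generate_phantom(phantom_spec("femur_like"))
print(ph$mesh)
#> triangle_mesh 'femur_like': 2039 vertices, 4000 faces, mean edge 2.643 mm
round(ph$truth$measurements, 1)
#>   AP MFC   AP LFC AP notch      fML   ML MFC   ML LFC ML notch      PCL
#>     69.9     69.9     20.4     80.8     24.1     24.1      9.3     33.6
#>   PD MFC   PD LFC
#>     39.7     39.7
```

The anteroposterior condyle sizes (~70 mm), femoral width (~81 mm) and
posterior condylar line (~34 mm) are stylized but knee-scaled millimetre
values. Run the full synthetic rehearsal — 6 deformed subjects, simulated
three-observer panel, two-pass correspondence, leave-one-out automated
annotation, full agreement report:

```r
rs <- phantom_rehearsal(n_subjects = 6, seed = 42)
print(rs$report)
#> agreement_report
#>   landmark mean error (mm) by comparison:
#>     INTER   1.76 (SD 0.85)
#>     INTRA   0.95 (SD 0.49)
#>     METHOD  1.78 (SD 0.83)
#>   measurement mean |difference| (mm) by comparison:
#>     INTER   0.88 (SD 0.92)
#>     INTRA   0.47 (SD 0.44)
#>     METHOD  0.95 (SD 0.77)
#>   method ICC range: 0.011 - 0.951
mean(rs$truth_landmark_errors$error)
#> [1] 1.296078
```

Reading this: repeats of one simulated observer scatter ~0.95 mm around
their mean (INTRA); different observers differ ~1.76 mm from the panel mean
(INTER); the automated landmarks differ ~1.78 mm from the expert mean
(METHOD) while sitting 1.30 mm from the generator's analytic truth.
Automated measurements agree with the expert mean to 0.95 mm on average.
Low ICCs for individual measurements on this cohort reflect its small
between-subject variance (phantoms deformed by only 2 mm RMS), not poor
absolute agreement — read them next to the mean differences.

A thin command-line front end wraps the same functions:

```sh
inst/cli/kneemark phantoms  --bone femur_like --n-subjects 6 --seed 42 --out phantoms/
inst/cli/kneemark register  --template phantoms/template.ply --target phantoms/subject01.ply --out reg/
inst/cli/kneemark measure   --landmarks phantoms/subject01_observers.csv --out measurements.csv
inst/cli/kneemark rehearsal --seed 42 --out rehearsal/
```

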