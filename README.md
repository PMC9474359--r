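# etmorph

Eustachian tube (ET) morphometry from named 3D cranial landmarks.

The orientation and length of the Eustachian tube are anatomical correlates
of middle-ear function: in adults, more horizontal and shorter tubes
accompany chronic middle-ear disease such as acquired cholesteatoma. On CT
the tube is summarised by two landmarks — the pharyngeal orifice at the
torus tubarius and the tympanic orifice at the middle-ear end — measured
against a cephalometric reference plane:

- **ET length** = ‖PO − TO‖, the 3D chord between the orifices (mm);
- **ET angle** = arcsin |n · d̂|, the angle between the orifice segment
  (unit direction d̂) and the reference plane with unit normal n (degrees,
  0–90).

Classical planes — Reid's standard plane (right infraorbital margin + both
upper margins of the external auditory canals) and the Frankfort plane (left
infraorbital margin + the same EAC anchors) — require the orbits, which
temporal-bone cone-beam CT protocols exclude. The **mandibular-fossa plane**
keeps the EAC anchors and replaces the infraorbital margin with the right
mandibular fossa, a small landmark near the middle ear that limited-window
scans reliably capture. `etmorph` implements all three planes, the per-ear
measurement, a synthetic-anatomy cohort generator with retained ground
truth, a minimal oblique multiplanar reformation (MPR) engine for voxel
phantoms, and the cohort-comparison statistics (unpaired t tests from raw
or summary data, Fisher's exact test, sample-size calculation).

All coordinates are world millimetres in the LPS frame (+x patient-left,
+y posterior, +z superior); every reader and writer assumes it. Angles are
stored at full precision; the 1-decimal rounding of clinical tables is
presentation-only.

## Worked example

Measure one subject from explicit landmarks (mm, LPS), then compare two
simulated cohorts:

```r
library(etmorph)

lm <- landmark_set("subj01", list(
  MF_R = c(-52, -8, 0), EAC_R = c(-60, 0, 0), EAC_L = c(60, 0, 0),
  PO_R = c(-20, -19, -16), TO_R = c(-47, -2, 1),
  PO_L = c(22, -21, -15),  TO_L = c(47, -2, 1)))
measure_cohort(list(lm), "KC_MFP")
#>   subject_id  side  plane angle_deg length_mm
#> 1     subj01 right KC_MFP  28.04928  36.15245
#> 2     subj01  left KC_MFP  27.00083  35.24202

ci <- generate_cohort("normal_ci", 30, 1)       # normal middle ears, CBCT
ch <- generate_cohort("cholesteatoma", 30, 1)   # middle-ear dysfunction
compare_cohorts(measure_cohort(cohort_landmark_sets(ci), "KC_MFP"),
                measure_cohort(cohort_landmark_sets(ch), "KC_MFP"),
                cohort_demographics(ci), cohort_demographics(ch),
                label_a = "cochlear implant", label_b = "cholesteatoma")
#> Cohort comparison (KC_MFP plane): cochlear implant (n=60 ears) vs cholesteatoma (n=60 ears)
#>   ET angle    33.3 (5.6) vs  28.1 (4.7) deg  p = 0.0001 (Student), 0.0001 (Welch)
#>   ET length   32.0 (2.3) vs  26.1 (5.0) mm   p = 0.0001 (Student), 0.0001 (Welch)
#>   age         63.5 (20.9) vs  42.2 (14.0) yr   p = 0.0001 (Student), 0.0001 (Welch)
#>   females    15/30 vs 8/30  p = 0.11 (Fisher)
#>   note: more than 3 tests run; no multiplicity correction applied
```

Each row reads mean (SD) per group. The cholesteatoma cohort shows the
expected more horizontal (smaller-angle) and shorter tubes; per-ear angle
and length are the measured quantities, with ears as the unit of analysis
(n = 60 ears from 30 subjects per cohort).

## Analysis workflow

Numbered drivers under `analysis/` run the full study sequence over the
package functions and write their tables to `results/`:

1. `01_simulate_cohorts.R` — generate the three shipped cohorts
   (`normal_sinus`, `normal_ci`, `cholesteatoma`; 30 subjects each).
2. `02_measure_planes.R` — measure with Reid's vs the mandibular-fossa
   plane; show the small systematic angle offset and the exact
   plane-independence of length.
3. `03_interrater_noise.R` — repeat-measurement simulation with 0.5 mm
   landmark placement jitter on a 10-subject subsample.
4. `04_phantom_mpr.R` — rasterize a subject into a 0.3 mm voxel phantom,
   reformat the mandibular-fossa plane, recover landmarks from the volume,
   and compare volume-derived with coordinate-derived measurements.
5. `05_cohort_comparison.R` — sample-size calculation and the
   cholesteatoma vs cochlear-implant comparison report.

Run them in order from the repository root:
`for f in analysis/0*.R; do Rscript "$f"; done`

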