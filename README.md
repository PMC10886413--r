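# skate3d

Markerless 3D motion capture for treadmill skate skiing, with the
marker-based reference computation and the agreement statistics needed to
validate it — for biomechanists and coaches who want joint kinematics
from two ordinary video cameras instead of a marker system.

Two cameras film a skier at 100 Hz; a pose-estimation model (e.g. a
DeepLabCut network) turns each view into per-frame 2D keypoints with
confidences. `skate3d` takes it from there:

* **DLT calibration** — each camera is the 11-parameter direct linear
  transformation
  `u = (L1·X + L2·Y + L3·Z + L4) / (L9·X + L10·Y + L11·Z + 1)` (and the
  analogous `v` row), fitted by conditioned linear least squares from ≥ 6
  digitized reference points (a 2 m calibration cube gives eight).
* **Reconstruction** — 12 Hz zero-phase Butterworth on pixels →
  per-frame multi-camera triangulation → 6 Hz on the 3D trajectories;
  low-confidence frames are excluded, never interpolated.
* **Reference kinematics** — joint centers from lateral/medial and
  anterior/posterior marker midpoints, hip via the Bell inter-ASIS
  regression, static-trial correction of the toe-marker mounting offset.
* **Cycles and angles** — right-pole-strike segmentation (every strike
  for G1, every second for G3), time normalization to 101 samples, and
  the five joint vector angles (elbow, shoulder, hip, knee, ankle) via
  the numerically stable cross/dot arctangent.
* **Agreement** — Bland–Altman bias/SD with both interval conventions
  (classical `bias ± 1.96·SD` and the t-based CI of the bias), RMSE,
  Pearson r with interpretation bands, and ICC(A,1) with its F-based
  confidence interval.
* **Synthetic sessions** — a deterministic skier simulator (ground-truth
  joints, pole strikes, cameras, markers, controlled noise) so that every
  stage of the pipeline can be checked against an oracle.

## Worked example

Simulate one G3 session (15 cycles at 1.2 s, two cameras, realistic
noise), write it to disk as keypoint CSVs + marker TRC + calibration
points, and run the full comparison:

```r
library(skate3d)

cfg <- sim_config(technique = "G3", seed = 42)
dir <- file.path(tempdir(), "session")
end_to_end_fixture(cfg, dir)
res <- run_pipeline(file.path(dir, "run.yaml"))
print(res$report)
#> Agreement report (G3): 10 cycles x 101 samples pooled
#>
#> Joint centers and toe placements [mm]:
#>     point technique bias  sd       loa
#>     wrist        G3 16.9 6.0 16.5/17.2
#>     elbow        G3 17.7 6.3 17.3/18.1
#>  shoulder        G3 13.8 5.9 13.5/14.2
#>       hip        G3 21.6 6.0 21.3/22.0
#>      knee        G3 13.8 6.2 13.4/14.2
#>     ankle        G3 20.5 8.9 20.0/21.0
#>       toe        G3 16.9 7.8 16.4/17.4
#>
#> Joint vector angles [deg]:
#>     angle technique  bias   sd rmse    r    r_band  icc  icc_band
#>     elbow        G3 -1.02 8.51 8.56 0.97 very high 0.97 excellent
#>  shoulder        G3 -0.33 3.64 3.65 0.96 very high 0.96 excellent
#>       hip        G3  0.49 3.22 3.25 0.97 very high 0.95 excellent
#>      knee        G3  0.09 1.95 1.95 1.00 very high 1.00 excellent
#>     ankle        G3  0.17 2.55 2.55 0.97 very high 0.97 excellent
```

Reading the tables: the joint-center rows are pooled 3D Euclidean
distances in mm (magnitudes — the "bias" is a mean distance, not a
signed error), with the t-based 95% interval of that mean under `loa`;
it hugs the mean because ~1000 cycle-samples are pooled, while the
classical `bias ± 1.96·SD` limits (also in the report object) stay about
±12 mm wide. The angle rows show that with 2 px keypoint error and a
20 mm soft-tissue artifact, both systems see the same movement to within
a few degrees — elbow worst (fast-swinging short segments), knee best —
with very-high correlations and excellent absolute agreement.
`plot(res$report)` draws the per-cycle mean ± SD difference curves.

A thin command-line wrapper covers the same flow
(`inst/scripts/skate3d simulate|calibrate|reconstruct|run-all`).

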