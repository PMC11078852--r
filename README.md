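# polypsize

Quantitative polyp **size** (longest length) and **location** (distance to an
anatomical landmark) from pairs of monocular endoscopic images whose camera
poses are known from an electromagnetic tracking sensor mounted on the
endoscope.

Visual size estimation during endoscopy is unreliable because apparent size
depends on the unknown camera-to-lesion distance, yet the 5 mm and 10 mm
thresholds drive resection and surveillance decisions. With a tracked
endoscope, two frames of the same polyp form a calibrated stereo pair:

1. segmentation masks are cleaned and traced into sub-pixel border contours;
2. border points are matched across the two views with **shape-context
   descriptors** (log-polar histograms, 5 radial x 12 angular bins, matched
   by exact optimal assignment under the chi-squared distance) — robust on
   texture-poor tissue where feature matching fails;
3. each matched pair is back-projected and **triangulated** (midpoint of the
   common perpendicular of the two rays, residual in mm) into real-scale 3D
   tracker coordinates;
4. a **planar ellipse** is fitted to the 3D border (direct least-squares
   conic fit after plane projection); its full major axis is the reported
   longest length and the distance from its centre to a tracked landmark
   (e.g. the oesophago-gastric junction) is the location;
5. estimates from all motion-compliant frame pairs are pooled with
   **quartile-based outlier rejection** on the reconstructed centres
   (Tukey fence, Q3 + 1.5 IQR), and averaged.

Image pairs are gated on capture recommendations — relative translation
between 3 and 30 mm, relative rotation below 30 degrees, and no near
forward-backward motion — with per-rule diagnostics (`check_pair()`).

The package also provides a ground-truthed **synthetic scene simulator**
(polyp borders of known size, endoscope-like pose sets, rendered masks and
contours, configurable tracker/pixel noise) and the **agreement statistics**
used for test-retest validation: two-way mixed-effects ICC (absolute
agreement, single measure), Bland–Altman limits of agreement in units and
percent, RMSD / median-absolute-difference summaries, and the Fisher-z
correlation sample-size calculation.

## Worked example

Simulate a 12 x 7 mm polyp viewed from five tracked poses with realistic
noise (0.3 mm / 0.3 deg tracker noise, 0.5 px contour noise), then measure
it with the full pipeline:

```r
library(polypsize)

polyp <- make_polyp(major_mm = 12, minor_mm = 7, centre = c(15, -10, 70),
                    normal = c(0.2, -0.1, 1), theta_deg = 35)
poses <- make_pose_set(polyp, n_views = 5, seed = 11)
scene <- synthetic_scene(polyp, poses, landmark = c(0, 0, 250), seed = 12)
r     <- render_views(scene)

frames <- Map(function(ct, p) list(contour = ct, pose = p),
              r$contours, r$noisy_poses)
m <- measure_polyp(frames, r$rig, r$landmark)
print(m)
#> Polyp measurement: size 11.70 mm, landmark distance 179.27 mm (10/10 pairs used)

head(m$per_pair[, c("pair", "size_mm", "location_mm", "median_residual_mm")], 4)
#>       pair size_mm location_mm median_residual_mm
#>  (f01,f02)  11.699     179.547              0.248
#>  (f01,f03)  11.109     177.733              0.423
#>  (f01,f04)  11.059     177.534              0.474
#>  (f01,f05)  11.853     180.037              0.277

r$truth$size_mm        # 12    (generating major axis, mm)
r$truth$location_mm    # 180.9 (true centre-to-landmark distance, mm)
```

The final size (11.70 mm) is the mean over the ten frame pairs that passed
motion gating and centre-based outlier rejection; per-pair rows show each
pair's estimate and its median triangulation residual in mm (a quality
diagnostic — well-matched noiseless pairs have residuals near zero).

For planning a validation study, the sample-size rule for detecting an
anticipated correlation of 0.7 (two-tailed alpha 0.05, power 0.8, 10%
attrition inflation):

```r
sample_size_correlation(0.7, alpha = 0.05, power = 0.8, inflation = 0.10)
#> [1] 15
```

## Command line

A thin CLI over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "polypsize.R", package = "polypsize"))')
Rscript "$CLI" simulate --out scene/ --seed 1          # masks/, poses.csv, rig.yaml, ...
Rscript "$CLI" measure  --scene scene/ --out report.json
Rscript "$CLI" stats    --csv paired.csv --out stats.json --plots plots/
```

Every run writes a manifest (config hash, seed, input hashes, package
version) sufficient to reproduce its outputs.

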