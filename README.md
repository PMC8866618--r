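# MarkerVis

Passive paramagnetic markers make guidewires visible under MRI guidance:
each iron-oxide nanoparticle (IONP) marker distorts the local field and
punches a signal void — a susceptibility artifact — into the magnitude
image.  Interventionalists and device designers need to know how artifact
size and visibility scale with echo time (TE), sequence type (GRE vs
bSSFP) and IONP load, and whether the markers can be found automatically.
`MarkerVis` implements that analysis end to end for a pulsatile flow
phantom at 3-T-like contrast, driven by a built-in synthetic phantom
generator so every stage is testable without scanner data.

The package provides, as S4 classes and camelCase functions:

* **Simulation** — point-dipole off-resonance
  (`Δf = K·m·(3cos²θ−1)/r³`) with intravoxel dephasing
  (`|mean exp(i·2π·Δf·TE)|` over an 8×8×3 sub-grid), bSSFP banding
  (`|cos(π·Δf·TR)|`), pulsatile blood signal, Rician noise, saturation
  ramp; acquisition presets a–h with TE/TR from 2.48/4.6 to 6.49/12.1 ms
  (GRE) and 1.47/2.9 to 4.85/9.6 ms (bSSFP).
* **Quantification** — discard the first 5 of 30 frames, pair marker to
  reference frames by blood-ROI intensity, subtract, threshold at agar
  mean + 3·SD, segment, measure mean artifact width perpendicular to the
  wire and blood-/agar-artifact CNR
  (`CNR = Δmean / SD(noise ROI)`), exclude contaminated frames.
* **Detection** — Gaussian likelihood-map labels (σ = (1,1) px,
  element-wise mean, [0,1] normalisation), a compiled U-Net heatmap
  regressor (MSE, Adam, lr 1e-4), 8-connected local maxima, and a
  TP/FP sweep over thresholds 0.1–0.9 (step 0.05) with a 2-voxel match
  tolerance.
* **Statistics** — exact two-tailed Wilcoxon signed-rank (sign-flip null,
  mid-ranked ties), median/IQR tables and boxplot-ready width data.

## Worked example

Simulate the baseline dataset (GRE preset "a", 6.25 mg/mL five-marker
wire, 30 frames each for reference and marker series) and quantify it:

```r
library(MarkerVis)

phantom <- PhantomSpec()
acq     <- acquisitionPreset("a")       # GRE, TE/TR 2.48/4.6 ms
wire    <- GuidewireSpec(ionpConcentration = 6.25)

ref  <- simulateSeries(phantom, NULL, acq, 30, seed = 1)
mark <- simulateSeries(phantom, wire, acq, 30, seed = 2)
quantifyDataset(mark, ref)
#> ArtifactQuant: 25 frames (0 excluded)
#>   median width 5.9 mm (IQR 5.4-6.1)
```

25 frames survive the discard step; the median artifact width of ~6 mm at
the shortest TE and lowest concentration sits at the small end of the
useful range, and it grows monotonically along the TE presets a→d and with
concentration (try `runExperimentGrid(presets = c("a","d"),
concentrations = c(6.25, 50))` — the grid writes per-frame CSVs and JSON
summaries).

Train the detector at desk scale and score it:

```r
att <- artifactAttenuation(phantom, wire, acq)   # reused across series
tr <- simulateSeries(phantom, wire, acq, 30, seed = 101, attenuation = att)
va <- simulateSeries(phantom, wire, acq, 10, seed = 102, attenuation = att)
ev <- simulateSeries(phantom, wire, acq, 10, seed = 103, attenuation = att)

cfg <- deskDetectionConfig(seed = 7)             # 60 epochs, ~2 min CPU
dtr <- detectionDataset(tr, cfg)
dva <- detectionDataset(va, cfg)
model <- trainDetector(dtr$images, dtr$labels, dva$images, dva$labels, cfg)
sweepEvaluate(model, ev, config = cfg)
#> DetectionMetrics over 170 (frame, threshold) pairs
#>   correctly detected: median 5.0 (IQR 5.0-5.0)
#>   false positives:    median 0.0 (IQR 0.0-0.0)
```

All five markers are recovered at essentially every threshold with no
false positives — the detection ceiling expected on baseline-condition
images.

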