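# pyloruskit

Automatic location of the stomach/small-intestine boundary (the pylorus)
in wireless capsule-endoscopy frame sequences.

A capsule endoscope produces an 8-hour video of 40,000+ small RGB
frames; segmenting it by organ is the first step of almost any automated
review, and the pylorus is the cut that matters most. `pyloruskit`
implements a locator built on three components:

1. **Color-saliency valid region (VROF).** Each frame is converted to
   CIE Lab and scored per pixel as
   `S = (a − a_u)³ + |b − b_u|^1.5` against the image chroma means; the
   positive set is the valid tissue region. Disturbances — overexposed
   reflections, shadows, air bubbles, pooled fluid — fall below the
   frame's mean redness and are excluded before any statistic is taken.
2. **Monitor–Judge temporal model.** The Monitor splits the sequence
   into 100-frame windows, samples every 5th frame, and tracks the
   window-pair chroma dissimilarity `DC_k = ‖M_k − M_{k+1}‖` against its
   running mean MDC. A pair is suspicious when
   `DC_k / MDC > 0.2 + 0.3·t`, with `t` counting prior false alarms.
   Only suspicious pairs are examined further, and the run stops at the
   first accepted boundary — frames beyond it are never decoded.
3. **Fused color-texture descriptor + RBF-SVM Judge.** Each judged frame
   is described by 36 values: four orientation-averaged co-occurrence
   statistics (contrast, correlation, energy, homogeneity) of the
   phase-congruency maximum-moment map — intestinal villi texture lights
   up there — plus 16-bin hue and saturation histograms over the valid
   region. A radial-basis support-vector classifier labels frames
   stomach/intestine, and the minimum-misclassification step split of
   the label sequence gives the boundary (or a rejection, which raises
   the Monitor's threshold).

A seeded synthetic generator emulates the two tissue appearances, the
color shift at a known boundary frame, and all four disturbance kinds,
so the full pipeline is developed and tested without clinical data.

## Worked example

```r
library(pyloruskit)

# train the Judge on synthetic descriptors (50 frames per organ class)
appearance <- synthetic_config(n_frames = 10, boundary_frame = 5, seed = 404)
tr <- ctvp_training_set(50, appearance, seed = 2024)
model <- train_judge(tr$features, tr$labels)

# a 2,000-frame video with the pylorus at frame 973
cfg <- synthetic_config(n_frames = 2000, boundary_frame = 973, seed = 42)
video <- generate_video(cfg)
res <- locate_pylorus(video$frames, model)
res[c("boundary_frame", "triggered_pair", "n_judge_calls", "t_final")]
#> $boundary_frame
#> [1] 975
#> $triggered_pair
#> [1] 9
#> $n_judge_calls
#> [1] 6
#> $t_final
#> [1] 5
video$frames$counter$max_index
#> [1] 995
```

The estimate lands 2 frames from the truth (within one 5-frame sampling
stride, the locator's resolution); the boundary was found in window pair
9 after 6 Judge consultations (the first few calibrate the escalation
counter on the stationary opening of the video, 5 were rejected); and
the highest frame ever decoded was 995 of 2,000 — the second half of
the video was never read.

A thin command-line front end over the same functions lives in
`inst/cli/pyloruskit.R` (`simulate`, `vrof`, `features`, `train`,
`locate`, `eval`).

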