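# hdemgid

Motion-intention identification from high-density surface EMG (HD-EMG).
The package is aimed at researchers in myoelectric control and
neuro-rehabilitation who want a tested, reproducible implementation of a
map-based identification pipeline: from multichannel monopolar recordings
with synchronized torque, through spatial activation maps, to classified
task and effort level — together with the robustness analyses (muscle
fatigue, electrode-gel drying) that decide whether such an interface is
usable outside the lab.

## What it computes

On non-overlapping 250 ms windows, each muscle's electrode grid is
summarized by an activation map `HM[i,j] = RMS(sEMG[i,j])`. Three feature
sets are compared, each concatenated over the five monitored muscles
(biceps brachii, triceps brachii, anconeus, brachioradialis, pronator
teres):

| feature set | definition | length |
|---|---|---|
| `I` | `log10(mean(HM))` per muscle | 5 |
| `I+CG` | `I` plus the map's center of gravity `sum(HM[i,j]*(i,j)) / sum(HM)` | 15 |
| `Diff` | `log10(RMS(sEMG[i,j] - sEMG[i+1,j]))`, a single bipolar channel | 5 |

Windows enter the analysis only when the measured torque stays inside a
level-specific band (±5 %MVC at the 10 %MVC target, ±10 %MVC at 30 and
50 %MVC); 20 epochs per contraction and 60 rest epochs form the balanced
observation pools. A linear discriminant classifier (pooled ridge
covariance, uniform priors) is evaluated over 1000 random balanced 50/50
splits, reporting per-class accuracy, sensitivity, precision and
specificity. Three protocol drivers reproduce the experimental designs:
short-term identification (5- or 13-class), the time-effect comparison
(train early, validate late), and the fatigue analysis over quintiles of
an endurance contraction. Preprocessing (channel screening, zero-phase
15–350 Hz Butterworth, adaptive LMS power-line cancellation), paired-t /
repeated-measures ANOVA comparisons with Greenhouse–Geisser handling, and
a ground-truth synthetic session generator complete the pipeline.

## Worked example

```r
library(hdemgid)

# a small deterministic session: 4 tasks x 3 levels + 4 endurance
# recordings on an 84-channel montage, with known ground truth
sess <- make_fixture("separable", seed = 3)
sess$session
#> HD-EMG session 'fix_separable': 16 recordings (12 submaximal, 4 endurance)

res <- run_short_term(sess, feature_set = "I+CG", scheme = "task5",
                      n_iter = 50, seed = 7)
res
#> Protocol 'short_term' (feature set I+CG, 50 iterations, seed 7)
#>   macro: Acc 1.000  S 1.000  P 1.000  SP 1.000
```

The macro indices are means over the 50 iterations of the per-class
one-vs-rest accuracy, sensitivity, precision and specificity; on this
deliberately well-separated fixture the classifier is perfect. More
interesting are the diagnostic fixtures: on `spatial_only` (classes share
identical regional intensity and differ only in where the source sits)
the `I` features classify at chance while `I+CG` recovers the tasks; on
`fatigue_drift` the per-quintile sensitivity of `Diff` decays along the
endurance contraction while `I+CG` resists:

```r
fat <- make_fixture("fatigue_drift", seed = 5)
run_fatigue(fat, "Diff", n_iter = 200, seed = 9)
#> Protocol 'fatigue' (feature set Diff, 200 iterations, seed 9)
#>            Acc     S     P    SP
#> 0-20%TDC  1.000 1.000 1.000 1.000
#> 20-40%TDC 1.000 1.000 1.000 1.000
#> 40-60%TDC 0.998 0.995 0.996 0.999
#> 60-80%TDC 0.994 0.985 0.987 0.996
#> 80-100%TDC 0.990 0.974 0.978 0.993
```

A thin command-line wrapper is installed at `inst/scripts/hdemg`
(`hdemg simulate | epochs | evaluate | protocol ...`).

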