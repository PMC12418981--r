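# pflowr

Point-light displays — scenes reduced to a few moving dots — let human
observers perceive structure from motion alone, including material
properties of fluids such as viscosity. Building such displays is hard for
formless media: liquids have no landmarks to attach lights to. `pflowr`
implements a motion-extraction algorithm designed for exactly that case,
together with everything needed to study it: a Lucas–Kanade baseline
tracker, point-light rendering, ground-truth synthetic scenes (including a
divergence-free "fluid" proxy), flow-accuracy scoring, and the analysis
pipeline of a viscosity-rating experiment driven by a synthetic observer.

The package is aimed at vision scientists and computational
psychophysicists who need trackable motion subsets from video, stimulus
generation for rating experiments, or a reference split-plot analysis
pipeline.

## The algorithm

The *p-flow* (pseudo-flow) is the subset of optical flow recovered by
tracking spatiotemporal image-gradient vectors
`g = (gx, gy, gt) = (∂I/∂x, ∂I/∂y, ∂I/∂t)`.
A single gradient vector constrains image motion through brightness
constancy, `gx·vx + gy·vy + gt = 0`; the one component it pins down is the
normal flow

```
v_n = −gt · (gx, gy) / (gx² + gy²)
```

The acceptance rule is self-referential: a vector reflects real flow —
rather than noise — iff *the same vector is found again at the position it
itself implies* in the next frame transition (angle between 3-vectors
≤ 10°, relative magnitude within 0.3, by default). Vectors matched over at
least `m_min = 3` consecutive transitions become dot tracks. Two
refinements sharpen the rule: matching stays referenced to the track's
seed vector (so inconsistent candidates accumulate position error and die
out), and after each match the position is refined along the
brightness-constancy constraint line to wherever the reference vector is
decisively re-found — resolving the aperture-ambiguous tangential
component where texture permits, while pure 1-D gratings remain exact
normal flow. See the methods vignette (`vignettes/pflow-methods.Rmd`) for
the full account.

## Worked example

```r
library(pflowr)

## a textured scene translating at (1, 0) px/frame, preprocessed the way
## stimulus movies are (decolorize + 3x3 box blur)
scene  <- translate_scene(make_texture(64, 64, 1.5, rng_seed = 1),
                          v = c(1, 0), T = 12)
stack  <- decolorize_and_blur(scene$stack)

tracks_p <- extract_pflow(stack)              # gradient-vector tracking
tracks_l <- track_lk(scene$stack, n_max = 100) # Lucas-Kanade baseline
matched  <- match_dot_counts(tracks_p, tracks_l, rng_seed = 1)

endpoint_error(matched$a, scene)
#> <flow_error_summary> n=356, mean EPE 0.328 px, median 0.213 px, mean angular 11.66 deg, coverage 0.77
endpoint_error(matched$b, scene)
#> <flow_error_summary> n=383, mean EPE 0.000 px, median 0.000 px, mean angular 0.00 deg, coverage 0.89

movie <- render_dots(matched$a, render_spec(64, 64), T = 12)
write_movie(movie, "pflow_dots/")              # numbered PNG sequence
```

Both extractors recover the shift (the p-flow's mean endpoint error of
0.33 px includes its normal-flow steps on ambiguous local structure; LK,
given ideal band-limited translation, is essentially exact). On a drifting
grating the dissociation reverses: LK finds no valid windows at all, while
the p-flow reports the motion component along the grating's gradient axis
— the aperture problem made visible.

The experiment side simulates rating sessions and analyzes them with the
design's statistics:

```r
trials <- simulate_experiment(observer_model(), n_per_group = 20, rng_seed = 7)
analyze_experiment(trials)$anova$sd_error
#> Split-plot ANOVA (between: group, within: stimulus)
#>          effect        ss df1 df2        F         p   eta2
#>           group 2106.8837   2  57 112.5000 1.626e-20 0.2048
#>        stimulus  129.6172   9 513   1.0090 4.319e-01 0.0126
#>  group:stimulus  190.3076  18 513   0.7404 7.697e-01 0.0185
#>
#> Tukey post hoc (between factor):
#>    group1   group2      diff      q     p_adj
#>        lk original  4.560762 21.080 1.121e-11
#>        lk    pflow  2.728950 12.610 1.754e-11
#>  original    pflow -1.831812  8.465 4.517e-07
```

The synthetic observer rates all displays with the same accuracy but
algorithm-dependent precision (error SDs 6 / 8 / 11 for original, p-flow
and LK displays); the ANOVA on the SD of the rating error recovers that
ordering, while the ANOVA on the mean error stays null — precision, not
accuracy, separates the algorithms.

A thin command-line front end over the same functions lives in
`inst/cli/pflowr-cli.R` (subcommands `extract`, `lk`, `render`, `synth`,
`eval`, `simulate`, `analyze`).

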