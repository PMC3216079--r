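# stainseg

Quantifies muscle damage from photographs of color-stained cross-sectional
slices, for anatomical and surgical-approach studies in which damaged
muscle tissue is painted yellow and intact tissue blue at the midsubstance
cross-sectional surface area (MCSA) — the plane that bisects the muscle
fibers perpendicular to their direction, so that the damaged share of the
plane equals the share of disrupted fibers.

At its core is a per-channel RGB color-class rule: each stain class is
modelled by channel means μ_c and sample standard deviations s_c pooled
from small training patches (10 patches of 10 × 10 pixels per class by
default), and a pixel belongs to a class when every channel lies in
[μ_c − k·s_c, μ_c + k·s_c] with k = 1.7. The damage percentage is

    α = 100 · n_yellow / (n_yellow + n_blue)

over the colored pixels of a bounding box around the cross-section. Around
that core the package provides:

* a **synthetic slice generator** (`generate_slice_image()`,
  `generate_training_regions()`) producing elliptical cross-sections with a
  contiguous damaged sector of known area fraction, Gaussian color noise,
  and exact ground-truth labels;
* **reliability**: `simulate_raters()` re-runs the semi-automatic region
  choice per assessor and `icc_single_rater()` computes ICC(2,1) (two-way
  random effects, absolute agreement, single measure);
* **group statistics**: medians/ranges, joint and pairwise Kruskal–Wallis
  tests, Bonferroni-adjusted thresholds, and frequency tables for
  dichotomous outcomes (`summarize_groups()`, `kruskal_wallis()`,
  `bonferroni_threshold()`, `tabulate_dichotomous()`);
* **power**: exact noncentral-t power and smallest-n search for a two-group
  comparison of mean damage (`t_test_power()`, `sample_size_for_power()`).

## Worked example

Simulate a stained slice with a 35% damaged sector and measure it back:

```r
library(stainseg)

fx <- generate_slice_image(simulation_params(true_fraction = 0.35,
                                             noise_sd = 8, seed = 1))
fx
#> <slice_fixture> 320x320 px, stained 61292 px, damaged fraction 0.3500

rs  <- generate_training_regions(fx, n_regions = 10, region_size = 10, seed = 2)
seg <- segment_slice(fx$image, rs, fx$bbox)
seg
#> <segmentation_result> damage 34.49% (yellow 16053 / colored 46543 px;
#>   31457 uncolored, 0 both-class)
seg$models$yellow
#> <color_class_model> yellow: mean (199.9, 180.0, 39.8), sd (8.08, 7.93, 8.06),
#>   k = 1.7, n = 1000 px
```

The measured 34.49% sits half a point from the 35.0% ground truth; the
uncolored count is the QC tally of pixels (background plus noise-excluded
stain) outside both class boxes, which drop out of the denominator.

Study-level statistics on the packaged per-hip damage table (five hips per
surgical approach):

```r
tab <- load_damage_table(stainseg_fixture("table1.csv"))
summarize_groups(tab)
#>               approach n median min max
#> 1 Lateral transgluteal 5     22   6  40
#> 2         MIS anterior 5      0   0  35
#> 3    MIS anterolateral 5     18   6  27
#> 4       MIS 2-incision 5     26  14  40
#> 5        MIS posterior 5     18   0  22

kruskal_wallis(tab)
#> $statistic 7.436  $df 4  $p_value 0.115

t_test_power(n_per_group = 5, delta = 18, sd = 8.5)
#> [1] 0.8336222
sample_size_for_power(0.80, delta = 18, sd = 8.5)
#> [1] 5
```

So the five approaches do not separate at the 0.05 level (p = 0.115), and
the a-priori design of 5 hips per group indeed carries 83% power to detect
an 18-point difference in mean damage at a common SD of 8.5.

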