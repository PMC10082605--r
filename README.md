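# fibrotype

Automated typing of skin tissue — normal, keloid scar, and scar-adjacent —
from label-free multiphoton microscopy images of the extracellular matrix.

Keloid scars grow beyond the original wound margin, and delineating the scar
and its boundary region matters for treatment planning. Second harmonic
generation (SHG) images fibrillar collagen and two-photon excited
fluorescence (TPEF) images elastin without staining, so the two main fibrous
components of the dermis can be quantified directly. `fibrotype` implements
the full analysis chain for such paired channel images:

1. **Feature extraction** — 28 features per sample, 14 per channel:
   - *morphology* (4): fiber density (Otsu foreground fraction); alignment
     (the concentration `k` of a semicircular von Mises distribution
     `f(θ; μ, k) = exp(k cos 2(θ − μ)) / (π I₀(k))` fitted by least squares
     to the FFT-power radial-sum orientation distribution); mean traced
     fiber width and length (threshold → skeletonize → prune branch points →
     trace segments, a transparent stand-in for curvelet-based fiber
     extraction);
   - *histogram texture* (6): mean intensity, standard deviation, smoothness
     `1 − 1/(1 + (σ/(L−1))²)`, skewness, uniformity `Σ p²`, entropy
     `−Σ p log₂ p`;
   - *co-occurrence texture* (4): Haralick contrast, correlation, energy,
     homogeneity of the symmetric, direction-summed gray-level co-occurrence
     matrix at distance 1.
   Features from the 2–3 imaged regions of a sample are averaged.
2. **Feature ranking** — minimum-redundancy maximum-relevance (MRMR):
   greedy selection maximizing
   `I(x_j; c) − (1/|S|) Σ_{x_i ∈ S} I(x_j; x_i)` with plug-in mutual
   information on equal-frequency-binned features.
3. **Incremental subset evaluation** — nested subsets S₁ ⊂ … ⊂ S₂₈ from the
   ranking, each scored by repeated leave-one-out (LOO) cross-validation of
   a one-vs-rest linear SGD classifier (modified-huber loss, elastic-net
   penalty, constant learning rate), with per-fold standardization and no
   information leakage.
4. **Reporting** — accuracy-versus-subset-size sweep, confusion matrix, and
   one-vs-rest ROC/AUC from the held-out probabilities.

Because clinical multiphoton images cannot be redistributed, the package
ships a seeded synthetic fiber-image simulator that reproduces the study
design (16 scar + 10 normal tissue sections, adjacent regions from 8 scar
specimens, 2–3 regions each) and the qualitative class differences: long
continuous fibers in normal skin, short discrete disordered fibers in scar,
highly ordered fibers in adjacent tissue. Every stage is therefore testable
end to end without any download.

## Worked example

A reduced cohort (4 + 4 + 3 samples, 128 px images, geometry scaled down)
runs in under a minute:

```r
library(fibrotype)

scale_p <- function(p, f = 4) {
  p$n_fibers <- max(4L, as.integer(p$n_fibers / f))
  p$length_mean <- p$length_mean / f; p$length_sd <- p$length_sd / f; p
}
presets <- lapply(fiber_class_presets(), function(ch) lapply(ch, scale_p))

design <- cohort_design(n_scar_sections = 4, n_normal_sections = 4,
                        n_adjacent_specimens = 3, image_size = 128,
                        presets = presets, master_seed = 11)
features <- cohort_feature_table(generate_cohort(design))
features[1:4, 1:5]
#> # A tibble: 4 × 5
#>   sample_id class_label C_density C_length C_width
#>   <chr>     <chr>           <dbl>    <dbl>   <dbl>
#> 1 scar_01   scar            0.115     14.7    2.71
#> 2 scar_02   scar            0.116     15.4    2.77
#> 3 scar_03   scar            0.117     14.6    2.68
#> 4 scar_04   scar            0.122     14.8    2.68

ranking <- mrmr_rank(discretize(features, bins = 4))
head(tidy(ranking), 3)
#> # A tibble: 3 × 4
#>    rank feature       criterion_value relevance_bits
#>   <int> <chr>                   <dbl>          <dbl>
#> 1     1 C_energy               1.39             1.39
#> 2     2 C_correlation          0.0927           1.14
#> 3     3 E_alignment            0.149            1.32

report <- pipeline_evaluate(features, ranking,
                            pipeline_config(repeats = 2, master_seed = 11,
                                            sgd = sgd_config(max_epochs = 100)))
report
#> <tissue_report> best subset n = 3; LOO accuracy 1.000
#>   AUC: adjacent=1.000, normal=1.000, scar=1.000

group_difference_test(features, "E_length", "scar", "normal")
#> [1] 0.02857143
```

The ranking table mirrors the feature-importance layout of the published
analysis (`relevance_bits` is each feature's mutual information with the
tissue label; `criterion_value` is the relevance-minus-redundancy objective
at the step the feature was selected). The LOO accuracy of 1.0 and per-class
AUCs of 1.0 say that on this synthetic cohort the classes are perfectly
separable — the simulator's class contrasts are deliberately strong; the
Mann–Whitney p-value shows elastin fiber length alone separates scar from
normal samples.

`autoplot()` methods draw the accuracy-versus-subset-size sweep
(`autoplot(report$sweep)`) and the one-vs-rest ROC curves
(`autoplot(report$roc)`).

A command-line interface with `simulate` / `extract` / `rank` / `evaluate` /
`run` subcommands is installed at `exec/fibrotype` inside the package
directory; staged execution with a fixed `--seed` is byte-identical to a
one-shot `run`.

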