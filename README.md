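# sarcomri

Quantitative MRI biomarkers of thigh muscle quantity and quality for
sarcopenia research — built around a fully synthetic, ground-truth-known
digital thigh phantom, so that every stage of the analysis is verifiable
by parameter recovery without any patient data.

## The problem

Sarcopenia — the age-related loss of skeletal muscle mass and strength —
is diagnosed clinically, but muscle *quality* degrades before muscle
*quantity* does. Quantitative MRI of the thigh can measure both:

- **Muscle quantity** from a T1-weighted volume: absolute muscle volume
  (L), muscle/fat and muscle/bone volume ratios, and the *macroscopic
  fatty infiltration* — the relative volume of fat enclosed in the
  morphologically closed muscle envelope, excluding bone.
- **Muscle quality** from voxel-wise parameter maps, averaged per
  subject over the muscle:
  - **PDFF**, the proton density fat fraction `F/(W+F)`, fitted from a
    six-echo chemical-shift series with the single-peak magnitude model
    `S(TE) = |W + F·exp(i·2π·Δf·TE)|·exp(−TE/T2*)` (Δf = 434 Hz at 3 T);
  - **T2\***, the effective transverse relaxation time from the same fit;
  - **ADC**, the conventional apparent diffusion coefficient — the
    log-linear slope of `S(b)` over all b-values (0–1200 s/mm²);
  - **D**, the perfusion-insensitive tissue diffusion coefficient — the
    log-linear slope restricted to b ≥ 200 s/mm² (IVIM framework, since
    `S(b) = S0·[f·exp(−b·D*) + (1−f)·exp(−b·D)]`).

These eight biomarkers are then related to clinical variables
(cineanthropometric, functional, respiratory) with a normality-gated
battery: Shapiro–Wilk decides Pearson vs Spearman per variable, and
Student's t vs Mann–Whitney U for the activity-group (IPAQ) comparison,
with significance stars and an |r| > 0.4 reporting filter.

Because no public dataset accompanies this kind of study, the package
ships a **synthetic data module**: a two-leg concentric-cylinder thigh
phantom (T1w + multi-echo + DWI series with Rician noise and exact
voxel-level ground truth) and a multivariate-Gaussian cohort simulator
reproducing published marginal means/SDs and correlation structure.

## Worked example

```r
library(sarcomri)

# a phantom designed to the reference cohort means
phantom <- build_phantom(phantom_spec())
phantom$truth_summary["macro_infiltration"]
#> macro_infiltration
#>          0.3400606

# full per-subject pipeline: segment, close, fit maps, summarise
row <- compute_imaging_biomarkers(phantom, subject_id = "phantom01")
as.data.frame(row[, c("pdff", "t2star_ms", "adc_e3mm2s", "macro_infiltration")])
#>        pdff t2star_ms adc_e3mm2s macro_infiltration
#> 1 0.1299694  31.61352   1.049307          0.3394071
```

The designed ground truth (PDFF 0.13, T2* 31.6 ms, ADC 1.05·10⁻³ mm²/s,
infiltration 0.34) is recovered end-to-end to well within 1%.

A synthetic cohort study, statistics included:

```r
study <- run_cohort_study(cohort_spec(n_subjects = 26, seed = 9))
study$ipaq_comparison
#> <group_comparison> student_t
#>   statistic: -2.6776  p: 0.01316
#>  low: 0.957 ± 0.071 (n = 8)
#>  moderate: 1.06 ± 0.094 (n = 18)
autoplot(study$reports)   # Tables-style correlation heatmap
```

A thin command-line front end is included at `inst/cli/sarcomri`
(subcommands `phantom`, `pipeline`, `cohort-study`, `report`).

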