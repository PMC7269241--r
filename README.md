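# mracpet

Simulation pipeline for studying how errors from atlas-based MR attenuation
correction (MRAC) of brain FDG-PET propagate into an automated
Alzheimer's-discrimination score.

## The problem

On PET/MR scanners the attenuation map must be derived from MR images
instead of a CT scan. Atlas-based MRAC misestimates attenuation — mostly
around skull bone — and that error propagates *multiplicatively* into the
reconstructed uptake values. For dementia work-ups the practical question
is not the raw percent error but whether it moves an automated diagnostic
score across its decision cutoff.

This package implements that question as a fully synthetic, desk-scale
simulation study:

1. **Error maps.** Voxel-wise ratio fields `PET_MRAC / PET_CTAC` on a
   common template grid — either computed from measured reconstruction
   pairs (`compute_error_map()`, `normalize_error_map()`) or sampled from a
   calibrated generative model (`sample_error_field()`) whose across-map
   statistics match measured levels: whole-brain mean −1.37 % (between-map
   SD 1.98 %), with AD-related voxels less underestimated (−0.86 %) than
   the rest of the brain (−1.59 %).
2. **Cohort.** A template-space phantom cohort emulating the study
   composition: 48 normal controls, 59 AD, 96 MCI (33 of whom convert to
   AD within 24 months), plus a 60-subject normal reference database with
   an age-dependent uptake decline.
3. **Scoring.** A PALZ-style chain: 12 mm Gaussian smoothing, intensity
   normalization to an AD-preserved mask, voxel-wise age-regression
   t-statistics against the reference database,

   ```
   t_v = (a_v + b_v·age − u_v) / (s_v · sqrt(1 + 1/n + (age − ā)² / Sxx)),
   ```

   the **AD t-sum** (sum of t over AD-related voxels) and the **PET
   score** `log2(AD t-sum / 11089 + 1)`, where 11089 is the 95 %
   prediction limit of the AD t-sum in healthy controls (so a t-sum at
   that limit maps to PET score 1.0, the AD-vs-normal cutoff).
4. **Cross simulation.** Every subject × every error map — 203 × 47 = 9541
   simulated scores plus 203 baselines — rescored from intensity
   normalization onward (`run_cross_simulation()`).
5. **Evaluation.** Diagnostic accuracy / sensitivity / specificity with
   Wilson 95 % CIs at cutoffs 1.0 (AD vs NC) and 0.79 (MCI conversion),
   per-map ranking with average/worst/best, Bland–Altman agreement for the
   best and worst maps, and a Welch test comparing the two acquisition
   institutions.

## Worked example

```r
library(mracpet)
res <- run_study(study_config(seed = 1), quiet = TRUE)

res$regional$summary
#>   region  mean_pct   sd_pct
#> 1  brain -1.109145 1.947135
#> 2     ad -0.678344 1.944023
#> 3  nonad -1.291251 1.958983

res$manifest$n_simulated_rows
#> [1] 9541

res$diffs$overall$mean
#> [1] -0.2641085

sum(res$diffs$per_map$mean_diff < 0)
#> [1] 40
```

Reading: the 47 synthetic error maps underestimate whole-brain uptake by
1.11 % on average (the generative level is −1.37 %; one 47-map draw
scatters with SE ≈ 0.29 %), AD-related voxels are less underestimated than
the rest, and because the scoring renormalizes each image to the
AD-preserved mask, that *contrast* shifts PET scores downward for 40 of
the 47 maps — attenuation-correction error biases the score toward
"less AD-like", the underestimation direction.

The same chain, step by step with narrative output and CSV tables under
`results/`:

```sh
Rscript analysis/01_generate_cohorts.R
Rscript analysis/02_reference_model.R
Rscript analysis/03_cross_simulation.R
Rscript analysis/04_evaluate.R
```

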