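# clsmr — connectome-based lesion-symptom mapping

`clsmr` relates lesion-induced white-matter *disconnection* to symptoms.
Instead of asking which lesioned voxels predict a deficit, it intersects
each patient's lesion mask with a streamline tractography atlas, scores
every ROI–ROI connection of a gray-matter parcellation with a
**disconnection severity** — the percentage of the connection's streamlines
interrupted by the lesion ("End" criterion: a streamline belongs to a
connection iff its two endpoints terminate in the two parcels) — and fits,
for each connection independently, the general linear model

```
symptom = a + b * severity + error
```

one-tailed in the direction "more disconnection, worse symptom", with
family-wise error over all connections controlled by **maximal-statistic
permutation**: the symptom vector is permuted across patients B times, the
maximum edge statistic is recorded each time, and each edge's corrected
p-value is `(1 + #{max >= t_edge}) / (B + 1)` (defaults B = 5000,
corrected alpha = 0.05, connections tested only if damaged in >= 7
patients).

The package targets a Go/NoGo inhibitory-control setting with three
symptoms per patient:

* **performance index** `(100 - FA%) / mean hit RT` — speed *and* accuracy;
* **d′ / criterion** with the log-linear (add 0.5 to every cell) correction;
* **N2 and P3 global-field-power amplitudes**: GFP is the spatial standard
  deviation of the scalp field; each component's amplitude is the mean
  individual GFP over the period of interest (grand-average GFP peak
  latency ± 40 ms).

Because the patient data behind such analyses cannot be shared, `clsmr`
ships a synthetic study generator (`make_study()`): phantom brain,
streamline atlas, unilateral lesion cohort with clinically realistic
volumes (0.001–1.72 % of brain volume, log-uniform), Go/NoGo sessions and
stimulus-locked EEG epochs whose degradation is causally driven by the
generated disconnection severities of known "true" connections. Every
stage of the pipeline is validated against this ground truth.

Intended users: researchers doing lesion-network or CLSM analyses who want
a tested, scriptable, dependency-light implementation of the disconnectome
+ permutation-GLM chain, and methodologists who need a ground-truthed
sandbox for lesion-symptom inference.

## Worked example

A small high-signal synthetic study, run end to end:

```r
library(clsmr)
cfg <- study_config(grid_dims = c(40, 40, 40), n_parcels = 14,
                    n_connections = 60, streamlines_per_connection = 8,
                    n_patients = 40, volume_pct_range = c(0.5, 3),
                    n_go = 120, n_nogo = 120, n_channels = 16,
                    srate_hz = 256, n_epoch_trials = 24,
                    n_true_edges = 2, rt_effect = 3, fa_effect = 0.004,
                    erp_effect = 0.01,
                    noise_sd = c(rt_ms = 5, fa = 0.01, erp_uv = 1),
                    n_permutations = 1000, seed = 2026)
run <- run_pipeline(cfg, out_dir = "run1")
print(run)
#> <clsm_run>
#>   performance_index   52 connections, 6 significant at alpha=0.05
#>   n2_gfp              52 connections, 6 significant at alpha=0.05
#>   p3_gfp              52 connections, 5 significant at alpha=0.05
run$study$truth$true_edges
#> [1] "1-2" "2-4"
summary(run$fits$performance_index)
#> CLSM summary for performance_index (alpha = 0.05, B = 1000)
#>   connection statistic      p_fwer significant
#> 1        1-2  9.530508 0.000999001        TRUE
#> 2        2-4  7.476685 0.000999001        TRUE
#> 3        2-6  4.747857 0.003996004        TRUE
#> 4        2-7  4.423027 0.007992008        TRUE
#> ... 48 more edges
```

Both planted connections (`1-2`, `2-4`) top the table at the minimum
attainable p-value `1/(B+1)`. The additional significant edges are
connections whose severities are correlated with the planted ones because
the same lesions damage them — in a lesioned connectome these are genuine
associations, not procedural false positives. Labeled reporting at the
stricter display threshold:

```r
significant_edges(run$fits$p3_gfp, run$study$index,
                  run$study$atlas$parcel_table, alpha = 0.01)
#>   connection   name_a   name_b statistic      p_fwer
#> 1        1-2 L_ctx_01 L_ctx_02 10.177029 0.000999001
#> 2        2-4 L_ctx_02 L_ctx_04  8.419198 0.000999001
#> 3        2-6 L_ctx_02 L_sub_01  5.334933 0.001998002
#> 4       2-10 L_ctx_02 R_ctx_03  4.478601 0.007992008
#> 5        2-7 L_ctx_02 L_sub_02  4.348796 0.008991009
```

The ERP branch fixes the component windows on the grand average
(`run$symptoms$poi`): here the N2 period of interest is 262.3–342.3 ms
(peak 302.3 ms) and the P3's is 360.0–440.0 ms (peak 400.0 ms) — peak
± 40 ms, applied unchanged to every individual GFP. Behavioral summaries
look like a plausible stroke cohort (first rows of
`run$symptoms$behavior_table`):

```
  patient_id fa_pct mean_hit_rt_ms performance_index dprime
1       P001  14.17          427.3            0.2009  3.304
2       P002  25.00          514.3            0.1458  2.913
3       P003  23.33          553.3            0.1386  2.965
```

`run_pipeline()` writes all intermediate TSVs, the coverage map as NIfTI,
and a `manifest.json`; `rerun_from_manifest("run1/manifest.json")`
reproduces the matrices, statistics and p-values bit-identically.

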