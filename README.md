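# sepalert

Screening analytics for a two-minute tablet task that probes the **spatial
execution process (SEP)**: how an older adult plans and executes a simple
spatial-navigation task, not merely whether they finish it. In the paradigm
a participant steers an inert sphere with a virtual steering wheel to
eliminate four target cubes (left, right, bottom, top) within 120 s; the
top cube lies behind a transverse obstacle that must be crossed. The tablet
records the sphere centre at 60 Hz plus the cube-elimination order, and
eight *digital biomarkers* summarise the trial in two domains:

| time domain | distance domain |
|---|---|
| METRtotal = Te / T (total execution-time rate) | MEDtotal = Σ dᵢ (total path length, px) |
| METfirst — time to the first elimination | MEEfirst — path / shortest-path ratio of the first leg |
| ETcrossing = Te − Tcrossing (time after first crossing the obstacle) | EDcrossing — distance covered after the crossing |
| ETabove — time spent above the obstacle midline | EDabove — distance covered while above |

with dᵢ = √((x_{i+1}−x_i)² + (y_{i+1}−y_i)²) the inter-sample step
distance and Tcrossing the first sample time at which the sphere's y
exceeds the obstacle midline. Downstream, the screening pipeline mirrors a
case–control study of normal-cognition (NC) elderly vs patients with MCI
due to Alzheimer's disease: Kruskal–Wallis rank-sum comparison of every
variable, forward ("step-up") logistic selection over the eight
biomarkers, and ROC/AUC evaluation of MMSE, each retained marker and their
fitted combination — overall and in the basic-education (>9 years)
subgroup.

Because raw patient trajectories are not public, the package also ships
the two synthetic layers used to exercise and validate everything:

* a **trial simulator** (`simulate_trial()`) — an inertial, damped sphere
  steered toward waypoints with angular noise, obstacle avoidance,
  optional detours and above-obstacle dwell — producing logs in the same
  JSONL dialect the extractor reads;
* a **cohort generator** (`sample_cohort()`) — per-group marginals
  calibrated *exactly* to published median/quartile summaries via
  two-piece (split) log-normal / discrete-normal quantile fits, joined by
  a Gaussian copula, with packaged presets `table4_cohort_spec()` (full
  46 + 46 cohort) and `table5_cohort_spec()` (basic-education subgroup).

## Worked example

```r
library(sepalert)

tab <- sample_cohort(table4_cohort_spec(), seed = 42)   # 46 NC + 46 MCI
rep <- sep_analyze(tab, subgroup_education = 9)
print(rep)
```

```
<screening_report> NC n=46, MCI n=46; 12 comparisons (no multiplicity correction)
        variable                         nc                          mci               test statistic  p_value
             age       67.00 (61.00, 78.00)         69.00 (65.00, 78.75)   Kruskal-Wallis H     0.648 4.21e-01
            mmse       29.00 (28.00, 29.00)         27.00 (24.00, 29.00)   Kruskal-Wallis H     6.901 8.61e-03
    med_total_px 8370.11 (7185.52, 9816.40) 10430.54 (9200.66, 11842.87)   Kruskal-Wallis H    13.356 2.58e-04
   et_crossing_s       23.27 (17.92, 33.25)         34.68 (27.54, 47.84)   Kruskal-Wallis H    16.236 5.59e-05
             ...
Step-up selection: et_crossing_s + med_total_px
AUCs:
  mmse            0.656
  et_crossing_s   0.744
  med_total_px    0.721
  combination     0.819
```

Each comparison row is `median (P25, P75)` per group with the two-group
Kruskal–Wallis H and its chi-square(1) p-value (sex uses Pearson
chi-square on the 2×2 counts). The selection line lists the markers that
entered the forward logistic model (entry p < 0.05, likelihood-ratio
test), and the AUC block gives the midrank area under the ROC curve for
each score, oriented so that higher always means "more MCI-like" (MMSE is
negated). At n = 46 + 46 the selected subset varies with the seed — that
sampling variability is exactly what the small-sample design implies.

Trial-level workflow:

```r
lg <- simulate_trial(agent_profile(), seed = 1)   # one synthetic 60 Hz trial
extract_biomarkers(lg)                            # the eight SEP biomarkers
write_trajectory_log(lg, "trial.jsonl")           # JSONL round-trip I/O
```

A command-line front-end (`inst/cli/sepalert`) wires the same four
workflows for shell use:

```sh
sepalert simulate-cohort --preset table4 --seed 5 --out cohort.csv
sepalert simulate-trials --n 20 --seed 1 --out logs/
sepalert extract --logs logs/ --out markers.csv
sepalert analyze --cohort cohort.csv --subgroup-education 9 --out report/
```

Every run writes a `manifest.json` (seed, options, version, input
checksums) and refuses to overwrite outputs without `--force`.

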